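# Independent oracles used to check the package implementation. These are
# deliberately written with different algorithms (plain string handling,
# per-event loops) than the code paths they verify.

# Reverse complement via explicit character mapping.
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# All canonical k-mers of a sequence by brute-force substring enumeration,
# skipping k-mers containing non-ACGT characters.
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  keep <- grepl("^[ACGT]+$", kmers)
  kmers <- kmers[keep]
  rc <- vapply(kmers, oracle_revcomp, character(1), USE.NAMES = FALSE)
  pmin(kmers, rc)
}

# Canonical k-mer counts as a named integer vector.
oracle_kmer_counts <- function(seqs, k, min_count = 1) {
  tab <- table(unlist(lapply(seqs, oracle_canonical_kmers, k = k)))
  tab <- tab[tab >= min_count]
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

# Replay a truth-variant table by applying events one at a time, from the
# highest position downward, on an exploded character vector.
oracle_replay <- function(sequence, truth) {
  chars <- strsplit(sequence, "")[[1]]
  truth <- truth[order(truth$position, decreasing = TRUE), ]
  for (i in seq_len(nrow(truth))) {
    p <- truth$position[i]  # 0-based
    if (truth$type[i] == "snp") {
      chars[p + 1] <- truth$alt_base[i]
    } else if (truth$type[i] == "del") {
      chars <- chars[-((p + 1):(p + nchar(truth$ref_base[i])))]
    } else {
      chars <- append(chars, strsplit(truth$alt_base[i], "")[[1]], after = p)
    }
  }
  paste(chars, collapse = "")
}

# Plain per-site mismatch proportion over non-N sites.
oracle_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca != "N" & cb != "N"
  sum(ca[ok] != cb[ok]) / sum(ok)
}
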