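# Internal helpers shared across modules. All randomness flows through
# with_seed()/derive_seed() so that a single integer seed fully determines
# every output of the package.

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed derivation; result always in [1, 2^31 - 2] so it is
# a valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) * 48271 + as.double(offset) * 9973) %% 2147483647
  as.integer(s %% 2147483645) + 1L
}

# Uniform random DNA string of length n (assumes caller seeded the RNG).
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Raw-byte codes for A/C/G/T used by the vectorised mutators below.
.base_raw <- charToRaw("ACGT")

# Substitute each selected position with a uniformly chosen *different* base.
# seq_raw: raw vector; idx: 1-based positions (assumes seeded RNG).
substitute_bases <- function(seq_raw, idx) {
  if (length(idx) == 0) return(seq_raw)
  code <- match(seq_raw[idx], .base_raw) - 1L
  new_code <- (code + sample.int(3L, length(idx), replace = TRUE)) %% 4L
  seq_raw[idx] <- .base_raw[new_code + 1L]
  seq_raw
}

# Inject per-base substitution errors at `rate` into a character vector of
# sequences; vectorised through one concatenated raw buffer.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  big <- charToRaw(paste(seqs, collapse = ""))
  idx <- which(runif(length(big)) < rate)
  big <- substitute_bases(big, idx)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  substring(rawToChar(big), starts, ends)
}

# Constant Phred+33 quality character for a given substitution error rate.
quality_char <- function(error_rate) {
  q <- if (error_rate <= 0) 40L else min(40L, as.integer(round(-10 * log10(error_rate))))
  rawToChar(as.raw(q + 33L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce the many accepted read inputs (character vector, tibble with a
# sequence column, file path) to a named character vector of sequences.
as_sequences <- function(x, arg = "reads") {
  if (is.character(x) && length(x) == 1 && file.exists(x) && !grepl("^[ACGTNacgtn]+$", x)) {
    rec <- read_sequences(x)
    return(setNames(rec$sequence, rec$id))
  }
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x))
      abort(sprintf("`%s` data frame must have a `sequence` column", arg))
    ids <- if ("read_id" %in% names(x)) x$read_id else if ("id" %in% names(x)) x$id
    else sprintf("seq%d", seq_len(nrow(x)))
    return(setNames(x$sequence, ids))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
    return(x)
  }
  abort(sprintf("cannot interpret `%s` as sequences", arg))
}
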