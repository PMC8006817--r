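test_that("canonical k-mer counting matches hand-enumerated toy cases", {
  # ACGT at k=3: ACG and CGT both canonicalize to ACG
  res <- count_kmers("ACGT", k = 3, min_count = 1)
  expect_equal(res$kmer, "ACG")
  expect_equal(res$count, 2L)
  # every 3-mer of ANGT spans the N and is skipped
  expect_equal(nrow(count_kmers("ANGT", k = 3, min_count = 1)), 0)
  expect_error(count_kmers("ACGT", k = 4), "odd")
  expect_error(count_kmers(character(0), k = 3), "empty")
})

test_that("counting agrees with the brute-force substring oracle", {
  set.seed(1)
  seqs <- replicate(20, paste(sample(c("A", "C", "G", "T", "N"), 80,
                                     replace = TRUE,
                                     prob = c(.24, .24, .24, .24, .04)),
                              collapse = ""))
  for (k in c(3L, 11L, 21L)) {
    got <- count_kmers(seqs, k = k, min_count = 1)
    want <- oracle_kmer_counts(seqs, k = k)
    expect_equal(setNames(got$count, got$kmer), want[order(names(want))])
  }
})

test_that("min_count filtering removes error k-mers: retained k-mers occur in the genome", {
  fx <- clean_trio()
  genome_kmers <- unique(oracle_canonical_kmers(
    substr(fx$pair$maternal$sequence, 1, 5000), 21))
  reads <- substring(substr(fx$pair$maternal$sequence, 1, 5000),
                     seq(1, 4800, by = 40), seq(1, 4800, by = 40) + 199)
  counted <- count_kmers(reads, k = 21, min_count = 2)
  expect_gt(nrow(counted), 0)
  expect_true(all(counted$kmer %in% genome_kmers))
})

test_that("marker sets are the symmetric difference of parental counts", {
  m <- count_kmers("ACGT", k = 3, min_count = 1)
  p <- count_kmers("ACTT", k = 3, min_count = 1)
  mk <- build_marker_sets(m, p)
  expect_setequal(mk$maternal, "ACG")
  expect_setequal(mk$paternal, c("ACT", "AAG"))
  # identical inputs give empty sets
  mk0 <- build_marker_sets(m, m)
  expect_length(mk0$maternal, 0)
  expect_length(mk0$paternal, 0)
  expect_error(build_marker_sets(m, count_kmers("ACGTT", k = 5, min_count = 1)),
               "same `k`")
})

test_that("marker density approximates the per-site marker probability", {
  fx <- clean_trio()
  # with exact-count SNP placement, P(a site yields a parent-specific k-mer)
  # is ~ 1 - (1 - d)^k
  d <- 0.03; k <- 21; L <- 5e4
  expected <- L * (1 - (1 - d)^k)
  for (side in c("maternal", "paternal")) {
    got <- length(fx$markers[[side]])
    expect_gt(got, 0.8 * expected)
    expect_lt(got, 1.2 * expected)
  }
})

test_that("marker sets from reads equal brute-force genome enumeration (error-free)", {
  fx <- clean_trio()
  # error-free reads tiling each genome end to end (alternate strands), so
  # every genome k-mer is observed; counting must then reproduce the
  # brute-force enumeration of genome k-mers exactly
  tile <- function(g) {
    L <- nchar(g)
    starts <- unique(c(seq(1, L - 199, by = 100), L - 199))
    reads <- substring(g, starts, starts + 199)
    flip <- seq_along(reads) %% 2 == 0
    reads[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
    reads
  }
  cm <- count_kmers(tile(fx$pair$maternal$sequence), k = 21, min_count = 1)
  cp <- count_kmers(tile(fx$pair$paternal$sequence), k = 21, min_count = 1)
  mk <- build_marker_sets(cm, cp)
  gm <- unique(oracle_canonical_kmers(fx$pair$maternal$sequence, 21))
  gp <- unique(oracle_canonical_kmers(fx$pair$paternal$sequence, 21))
  expect_setequal(cm$kmer, gm)
  expect_setequal(mk$maternal, setdiff(gm, gp))
  expect_setequal(mk$paternal, setdiff(gp, gm))
})

test_that("classification follows the score comparison and tie rules", {
  mk <- structure(list(k = 3L, min_count = 1L,
                       maternal = c("ACG"), paternal = c("ACT", "AAG")),
                  class = "marker_sets")
  cls <- classify_reads(c(r1 = "ACGACG", r2 = "ACTTACTT", r3 = "CCCCCC",
                          r4 = "AC"), mk)
  expect_equal(cls$assigned, c("maternal", "paternal", "unknown", "unknown"))
  expect_equal(cls$c_mat, c(2L, 0L, 0L, 0L))
  expect_equal(cls$c_pat[2], 4L)
  # tie goes to unknown: one maternal and one paternal hit
  tie <- classify_reads(c(t = "ACGAAG"), mk)
  expect_equal(tie$c_mat, tie$c_pat)
  expect_equal(tie$assigned, "unknown")
})

test_that("normalization divides scores by marker-set size", {
  mk <- structure(list(k = 3L, min_count = 1L,
                       maternal = "ACG",
                       paternal = c("ACT", "AAG", "CCC", "GGA")),
                  class = "marker_sets")
  # 1 maternal hit vs 2 paternal hits: raw favors paternal,
  # normalized favors maternal (1/1 > 2/4)
  read <- c(x = "AACGATACTTT")
  raw <- classify_reads(read, mk)
  norm <- classify_reads(read, mk, normalize = TRUE)
  expect_equal(raw$assigned, "paternal")
  expect_equal(norm$assigned, "maternal")
})

test_that("error-free reads are classified to their truth haplotype", {
  fx <- clean_trio()
  expect_equal(fx$classification$assigned, fx$long_reads$truth$haplotype)
})

test_that("binning partitions the input and swapping parents swaps labels", {
  fx <- clean_trio()
  res <- bin_reads(fx$long_reads$reads, fx$markers)
  expect_equal(sum(res$summary$n_reads), nrow(fx$long_reads$reads))
  expect_equal(sum(res$summary$pct_reads), 100)
  swapped <- structure(list(k = fx$markers$k, min_count = fx$markers$min_count,
                            maternal = fx$markers$paternal,
                            paternal = fx$markers$maternal),
                       class = "marker_sets")
  cls2 <- classify_reads(fx$long_reads$reads, swapped)
  relabel <- c(maternal = "paternal", paternal = "maternal",
               unknown = "unknown")
  expect_equal(cls2$assigned, unname(relabel[fx$classification$assigned]))
  expect_equal(cls2$c_mat, fx$classification$c_pat)
})

test_that("empty marker sets send every read to unknown", {
  fx <- clean_trio()
  empty <- structure(list(k = 21L, min_count = 2L, maternal = character(0),
                          paternal = character(0)), class = "marker_sets")
  res <- bin_reads(head(fx$long_reads$reads, 5), empty)
  expect_equal(res$summary$n_reads[res$summary$bin == "unknown"], 5L)
})

test_that("bin_reads writes the three bins, table and summary to disk", {
  fx <- clean_trio()
  out <- file.path(tempfile(), "bins")
  res <- bin_reads(fx$long_reads$reads, fx$markers, outdir = out)
  expect_true(all(file.exists(file.path(out, c("maternal.fastq",
                                               "paternal.fastq",
                                               "unknown.fastq",
                                               "classification.tsv",
                                               "summary.json")))))
  written <- sum(vapply(c("maternal", "paternal", "unknown"), function(b)
    nrow(read_sequences(file.path(out, paste0(b, ".fastq")))), numeric(1)))
  expect_equal(written, nrow(fx$long_reads$reads))
  tab <- read.delim(file.path(out, "classification.tsv"))
  expect_equal(tab$assigned, res$classification$assigned)
})
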