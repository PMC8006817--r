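#' Count canonical k-mers in a set of reads
#'
#' Counts every k-mer of length `k` over its canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement), skipping
#' any k-mer spanning a non-ACGT character, and discards k-mers whose final
#' count falls below `min_count` (sequencing-error filtering).
#'
#' @param reads Sequences: a character vector, a tibble with a `sequence`
#'   column (e.g. a `short_read_set`), or a FASTA/FASTQ path.
#' @param k Odd k-mer length, at most 31 (values below ~11 are only useful
#'   for toy examples). Even k is rejected because a k-mer can then equal its
#'   own reverse complement, making the canonical form ambiguous as a
#'   strand-insensitive marker.
#' @param min_count Minimum occurrence count for a k-mer to be retained.
#' @return A tibble of class `kmer_counts` with columns `kmer` (canonical)
#'   and `count`, sorted by k-mer; attributes `k` and `min_count`.
#' @export
#' @examples
#' count_kmers("ACGT", k = 3, min_count = 1)
count_kmers <- function(reads, k = 21L, min_count = 2L) {
  seqs <- as_sequences(reads)
  if (length(seqs) == 0 || all(!nzchar(seqs)))
    abort("empty read input: nothing to count")
  k <- as.integer(k)
  if (k %% 2L == 0L) abort("`k` must be odd (canonical-form ambiguity)")
  if (k < 3L || k > 31L) abort("`k` must lie in [3, 31]")
  res <- cpp_count_kmers(unname(seqs), k, as.integer(min_count))
  out <- tibble(kmer = res$kmer, count = res$count)
  attr(out, "k") <- k
  attr(out, "min_count") <- as.integer(min_count)
  class(out) <- c("kmer_counts", class(out))
  out
}

#' Build parent-specific marker k-mer sets
#'
#' A maternal marker is a k-mer present in the maternal counts and absent
#' from the (already count-filtered) paternal counts, and symmetrically for
#' paternal markers. The two marker collections are disjoint by
#' construction.
#'
#' @param counts_mat,counts_pat `kmer_counts` for the two parents, with
#'   equal `k`.
#' @return An object of class `marker_sets`: a list with `k`, `min_count`,
#'   `maternal` and `paternal` (character vectors of canonical k-mers).
#' @export
#' @examples
#' m <- count_kmers("ACGT", k = 3, min_count = 1)
#' p <- count_kmers("ACTT", k = 3, min_count = 1)
#' build_marker_sets(m, p)
build_marker_sets <- function(counts_mat, counts_pat) {
  k1 <- attr(counts_mat, "k"); k2 <- attr(counts_pat, "k")
  if (is.null(k1) || is.null(k2) || k1 != k2)
    abort("parental k-mer counts must share the same `k`")
  structure(list(
    k = k1,
    min_count = attr(counts_mat, "min_count"),
    maternal = setdiff(counts_mat$kmer, counts_pat$kmer),
    paternal = setdiff(counts_pat$kmer, counts_mat$kmer)),
    class = "marker_sets")
}

#' @export
print.marker_sets <- function(x, ...) {
  cat(sprintf("<marker_sets> k = %d, min_count = %s\n", x$k,
              x$min_count %||% "?"))
  cat(sprintf("  maternal markers: %d\n  paternal markers: %d\n",
              length(x$maternal), length(x$paternal)))
  invisible(x)
}

#' Classify reads into parental haplotype bins
#'
#' For each read, counts the read k-mer positions whose canonical k-mer is a
#' maternal marker (`c_mat`) or a paternal marker (`c_pat`). The read is
#' assigned to the side with the strictly greater score; when both scores
#' are zero or tied it goes to `unknown`. With `normalize = TRUE` scores are
#' the marker hit counts divided by the respective marker-set size, which
#' compensates for asymmetric parental marker density.
#'
#' @param reads Sequences (see [count_kmers()] for accepted forms). Reads
#'   shorter than `k` get `c_mat = c_pat = 0` and are assigned `unknown`.
#' @param markers A `marker_sets` object.
#' @param normalize Divide marker hit counts by marker-set size before
#'   comparing. Default off.
#' @return A tibble of class `classification_table` with columns `read_id`,
#'   `assigned` (`maternal`/`paternal`/`unknown`), `c_mat`, `c_pat`,
#'   `length`.
#' @export
classify_reads <- function(reads, markers, normalize = FALSE) {
  stopifnot(inherits(markers, "marker_sets"))
  seqs <- as_sequences(reads)
  res <- cpp_classify_reads(unname(seqs), markers$maternal, markers$paternal,
                            markers$k)
  s_mat <- as.numeric(res$c_mat)
  s_pat <- as.numeric(res$c_pat)
  if (isTRUE(normalize)) {
    s_mat <- if (length(markers$maternal)) s_mat / length(markers$maternal) else 0
    s_pat <- if (length(markers$paternal)) s_pat / length(markers$paternal) else 0
  }
  assigned <- dplyr::case_when(
    s_mat > s_pat ~ "maternal",
    s_pat > s_mat ~ "paternal",
    .default = "unknown")
  out <- tibble(read_id = names(seqs), assigned = assigned,
                c_mat = res$c_mat, c_pat = res$c_pat,
                length = nchar(unname(seqs)))
  class(out) <- c("classification_table", class(out))
  out
}

#' Bin F1 long reads into maternal, paternal and unknown sets
#'
#' Runs [classify_reads()] and partitions the input into the three haplotype
#' bins. When `outdir` is given, writes three FASTQ bin files
#' (`maternal.fastq`, `paternal.fastq`, `unknown.fastq`), the classification
#' table (`classification.tsv`) and a machine-readable summary
#' (`summary.json`).
#'
#' @inheritParams classify_reads
#' @param outdir Optional output directory; must be writable (checked before
#'   any processing).
#' @return A list of class `bin_result`: `classification` (the
#'   [classify_reads()] tibble) and `summary`, a tibble with one row per bin
#'   (`bin`, `n_reads`, `n_bases`, `pct_reads`, `pct_bases`).
#' @export
bin_reads <- function(reads, markers, normalize = FALSE, outdir = NULL) {
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outdir) || file.access(outdir, 2L) != 0L)
      abort(sprintf("output directory not writable: %s", outdir))
  }
  recs <- if (is.data.frame(reads)) reads else NULL
  cls <- classify_reads(reads, markers, normalize = normalize)
  bins <- c("maternal", "paternal", "unknown")
  summary <- cls %>%
    mutate(assigned = factor(.data$assigned, levels = bins)) %>%
    group_by(bin = .data$assigned, .drop = FALSE) %>%
    summarise(n_reads = dplyr::n(), n_bases = sum(.data$length), .groups = "drop") %>%
    mutate(bin = as.character(.data$bin),
           pct_reads = 100 * .data$n_reads / max(sum(.data$n_reads), 1),
           pct_bases = 100 * .data$n_bases / max(sum(.data$n_bases), 1))
  if (!is.null(outdir)) {
    seqs <- as_sequences(reads)
    qual <- if (!is.null(recs) && "quality" %in% names(recs)) recs$quality
            else strrep("I", nchar(unname(seqs)))
    all_recs <- tibble(id = names(seqs), sequence = unname(seqs), quality = qual)
    for (b in bins)
      write_sequences(all_recs[cls$assigned == b, ],
                      file.path(outdir, paste0(b, ".fastq")))
    write.table(cls, file.path(outdir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(k = markers$k, normalize = isTRUE(normalize), bins = summary),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(classification = cls, summary = summary), class = "bin_result")
}

#' @export
print.bin_result <- function(x, ...) {
  cat("<bin_result>\n")
  print(x$summary)
  invisible(x)
}
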