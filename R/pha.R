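BIN_LEVELS <- c("maternal", "paternal", "unknown")

#' Load a binning as a per-read assignment table
#'
#' Accepts either the three haplotype bin files of one cross (FASTA/FASTQ)
#' or a classification table (a `classification_table` tibble, a
#' `bin_result`, or a TSV path with columns `read_id`, `assigned`,
#' `length`). Read ids must be unique across the three bins.
#'
#' @param maternal,paternal,unknown Paths to the three bin files (or
#'   tibbles of records with `id`/`sequence` columns).
#' @param table Alternative input: a classification table or TSV path.
#' @return A tibble with columns `read_id`, `bin`, `length`.
#' @export
load_bins <- function(maternal = NULL, paternal = NULL, unknown = NULL,
                      table = NULL) {
  if (!is.null(table)) {
    if (inherits(table, "bin_result")) table <- table$classification
    if (is.character(table)) table <- read.delim(table, stringsAsFactors = FALSE)
    tab <- as_tibble(table)
    if (!all(c("read_id", "assigned", "length") %in% names(tab)))
      abort("classification table needs columns read_id, assigned, length")
    out <- tibble(read_id = tab$read_id, bin = tab$assigned,
                  length = tab$length)
  } else {
    one <- function(x, bin) {
      if (is.null(x)) return(tibble(read_id = character(), bin = character(),
                                    length = integer()))
      rec <- if (is.character(x)) read_sequences(x) else as_tibble(x)
      tibble(read_id = rec$id, bin = bin, length = nchar(rec$sequence))
    }
    out <- bind_rows(one(maternal, "maternal"), one(paternal, "paternal"),
                     one(unknown, "unknown"))
  }
  if (!all(out$bin %in% BIN_LEVELS))
    abort("bins must be maternal/paternal/unknown")
  dup <- unique(out$read_id[duplicated(out$read_id)])
  if (length(dup))
    abort(sprintf("read id present in more than one bin: %s%s",
                  dup[1], if (length(dup) > 1) sprintf(" (+%d more)", length(dup) - 1) else ""))
  out
}

#' Compare two binnings of the same reads (Phased Haplotype Analysis)
#'
#' Builds the full 3x3 reference-vs-replacement confusion matrix over the
#' maternal/paternal/unknown bins. Correctly sorted reads are those assigned
#' to the same bin in both crosses (the matrix diagonal); discordant reads
#' are broken down into the six direction subtypes (maternal-to-paternal,
#' maternal-to-unknown, ...).
#'
#' @param reference,replacement Per-read assignment tables from
#'   [load_bins()] (or `bin_result` / `classification_table` objects).
#' @param mode `"strict"` requires identical read-id sets; `"lenient"`
#'   intersects them and records how many ids were dropped.
#' @return An object of class `concordance_report`: a list with `confusion`
#'   (3x3 integer matrix, reference bins in rows), `correct_reads`,
#'   `incorrect_by_subtype` (tibble `from`, `to`, `n`), `incorrect_reads`
#'   (tibble `read_id`, `from`, `to`, `length`), `total_bases_incorrect`,
#'   `total_bases`, `n_reads`, `n_dropped`.
#' @export
compare_classifications <- function(reference, replacement,
                                    mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  as_map <- function(x) {
    if (inherits(x, "bin_result") || inherits(x, "classification_table") ||
        (is.data.frame(x) && "assigned" %in% names(x)))
      load_bins(table = x)
    else as_tibble(x)
  }
  ref <- as_map(reference); alt <- as_map(replacement)
  shared <- intersect(ref$read_id, alt$read_id)
  if (length(shared) == 0) abort("no shared read ids between the two binnings")
  n_dropped <- (nrow(ref) - length(shared)) + (nrow(alt) - length(shared))
  if (mode == "strict" && n_dropped > 0)
    abort("read-id sets differ between the two binnings (use mode = \"lenient\")")
  if (mode == "lenient" && n_dropped > 0)
    warn(sprintf("%d read ids not shared between the crosses were dropped", n_dropped))
  ref <- ref[match(shared, ref$read_id), ]
  alt <- alt[match(shared, alt$read_id), ]
  f <- function(x) factor(x, levels = BIN_LEVELS)
  confusion <- table(reference = f(ref$bin), replacement = f(alt$bin))
  confusion <- matrix(as.integer(confusion), 3, 3,
                      dimnames = list(reference = BIN_LEVELS,
                                      replacement = BIN_LEVELS))
  wrong <- ref$bin != alt$bin
  incorrect <- tibble(read_id = shared[wrong], from = ref$bin[wrong],
                      to = alt$bin[wrong], length = ref$length[wrong])
  subtype <- tidyr::expand_grid(from = BIN_LEVELS, to = BIN_LEVELS) %>%
    filter(.data$from != .data$to) %>%
    left_join(count(incorrect, .data$from, .data$to), by = c("from", "to")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(list(
    confusion = confusion,
    correct_reads = sum(diag(confusion)),
    incorrect_by_subtype = subtype,
    incorrect_reads = incorrect,
    total_bases_incorrect = sum(as.numeric(incorrect$length)),
    total_bases = sum(as.numeric(ref$length)),
    all_lengths = ref$length,
    n_reads = length(shared),
    n_dropped = n_dropped),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d reads, %d correct (%.2f%%)\n",
              x$n_reads, x$correct_reads, 100 * x$correct_reads / x$n_reads))
  print(x$confusion)
  invisible(x)
}

#' @describeIn compare_classifications Confusion matrix as a long tibble
#'   (`reference`, `replacement`, `n`).
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @export
tidy.concordance_report <- function(x, ...) {
  as_tibble(as.data.frame.table(x$confusion, responseName = "n",
                                stringsAsFactors = FALSE))
}

#' @describeIn compare_classifications One-row summary: read counts,
#'   discordance fraction and incorrect-base fraction.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble(n_reads = x$n_reads,
         correct_reads = x$correct_reads,
         incorrect_reads = x$n_reads - x$correct_reads,
         discordance = 1 - x$correct_reads / x$n_reads,
         total_bases = x$total_bases,
         incorrect_base_fraction = x$total_bases_incorrect / x$total_bases,
         n_dropped = x$n_dropped)
}

#' Length profile of discordant reads
#'
#' Summarises how short the discordant reads of a [compare_classifications()]
#' report are: the fraction of discordant reads below a length threshold and
#' the fraction of all bases carried by discordant reads. With no discordant
#' reads both fractions are defined as 0.
#'
#' @param report A `concordance_report`.
#' @param threshold Length threshold in bp (default 10000); must be > 0.
#' @return A one-row tibble: `threshold`, `n_incorrect`, `n_below_threshold`,
#'   `fraction_below`, `incorrect_base_fraction`, plus `all_below_fraction`,
#'   the below-threshold fraction among *all* reads, for comparison.
#' @export
length_profile <- function(report, threshold = 10000) {
  stopifnot(inherits(report, "concordance_report"))
  if (threshold <= 0) abort("`threshold` must be > 0")
  lens <- report$incorrect_reads$length
  tibble(
    threshold = threshold,
    n_incorrect = length(lens),
    n_below_threshold = sum(lens < threshold),
    fraction_below = if (length(lens)) mean(lens < threshold) else 0,
    incorrect_base_fraction = if (report$total_bases > 0)
      report$total_bases_incorrect / report$total_bases else 0,
    all_below_fraction = mean(report$all_lengths < threshold))
}

#' @export
autoplot.concordance_report <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$replacement, y = .data$reference, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), colour = "grey20") +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "replacement-cross bin", y = "reference-cross bin",
         fill = "reads") +
    theme_minimal()
}
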