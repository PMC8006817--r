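#' Pseudo-haploidize per-site diploid calls
#'
#' Collapses a diploid sample to a haploid consensus in reference
#' coordinates: homozygous sites keep their base, heterozygous sites get one
#' allele chosen uniformly at random (seeded), and missing sites become `N`.
#' This mirrors the random-base consensus approach commonly used to build
#' pseudo-haploid sequences from diploid mappings.
#'
#' @param allele1,allele2 The two allele strings (equal length; `N` or `-`
#'   marks a missing call), or a data frame with columns `allele1`,
#'   `allele2` of single-character calls as the first argument.
#' @param seed Integer seed for the random allele choice.
#' @param ref_length Optional expected length; a mismatch is an error.
#' @return The haploid consensus as a single string over `{A,C,G,T,N}`.
#' @export
#' @examples
#' pseudo_haploidize("ACGT", "ACTT", seed = 1)
pseudo_haploidize <- function(allele1, allele2 = NULL, seed = 1L,
                              ref_length = NULL) {
  if (is.data.frame(allele1)) {
    stopifnot(all(c("allele1", "allele2") %in% names(allele1)))
    allele2 <- paste(allele1$allele2, collapse = "")
    allele1 <- paste(allele1$allele1, collapse = "")
  }
  if (nchar(allele1) != nchar(allele2))
    abort("the two allele strings differ in length")
  if (!is.null(ref_length) && nchar(allele1) != ref_length)
    abort(sprintf("allele length %d does not match reference length %d",
                  nchar(allele1), ref_length))
  a1 <- charToRaw(toupper(allele1))
  a2 <- charToRaw(toupper(allele2))
  valid <- .base_raw
  miss <- !(a1 %in% valid) | !(a2 %in% valid)
  out <- a1
  het <- which(a1 != a2 & !miss)
  with_seed(derive_seed(seed, 601L), {
    take2 <- het[runif(length(het)) < 0.5]
    out[take2] <- a2[take2]
  })
  out[miss] <- charToRaw("N")
  rawToChar(out)
}

#' Windowed uncorrected p-distance of a sample against a reference
#'
#' Tiles the reference into fixed-size windows (final window may be short)
#' and, per window, counts the sites where both sequences are non-N
#' (`n_compared`) and the compared sites that differ (`n_diff`). The
#' uncorrected p-distance is `n_diff / n_compared`; windows with fewer than
#' `min_sites` compared sites get a missing `p`.
#'
#' @param sample An `individual_genome` / `parent_genome`, a plain string,
#'   or a list with `sample_id`, `species_group`, `sequence`/`consensus`.
#'   Must have the same length as the reference.
#' @param reference The reference sequence (string or genome object).
#' @param window_size Window width in bp (default 100000, i.e. 100-kb
#'   windows); must be >= 1.
#' @param min_sites Minimum compared sites for a defined `p` (default 1000).
#' @param sample_id,group Optional overrides for the track labels; `group`
#'   is `"ingroup"` or `"outgroup"` relative to the reference species.
#' @return A tibble of class `window_track` with columns `sample_id`,
#'   `group`, `chrom`, `start`, `end` (0-based half-open), `n_compared`,
#'   `n_diff`, `p`.
#' @export
#' @examples
#' window_pdistance("ACGTACGTAC", "ACGTACGTAT", window_size = 5, min_sites = 1)
window_pdistance <- function(sample, reference, window_size = 100000,
                             min_sites = 1000, sample_id = NULL,
                             group = NA_character_) {
  if (window_size < 1) abort("`window_size` must be >= 1")
  get_seq <- function(x) {
    if (is.character(x) && length(x) == 1) return(toupper(x))
    s <- x$consensus %||% x$sequence
    if (is.null(s)) abort("cannot extract a sequence")
    toupper(s)
  }
  s <- get_seq(sample); r <- get_seq(reference)
  if (nchar(s) != nchar(r))
    abort(sprintf("sample length %d != reference length %d", nchar(s), nchar(r)))
  sample_id <- sample_id %||% (if (is.list(sample)) sample$sample_id else NULL) %||% "sample"
  group <- if (!is.na(group)) group
           else (if (is.list(sample)) sample$species_group %||% NA_character_ else NA_character_)
  chrom <- (if (is.list(reference)) reference$chrom_id else NULL) %||% "chr1"
  L <- nchar(r)
  sr <- charToRaw(s); rr <- charToRaw(r)
  nmark <- charToRaw("N")
  compared <- sr != nmark & rr != nmark
  diffs <- compared & (sr != rr)
  win <- (seq_len(L) - 1) %/% window_size
  n_compared <- as.integer(rowsum(as.integer(compared), win))
  n_diff <- as.integer(rowsum(as.integer(diffs), win))
  wids <- sort(unique(win))
  out <- tibble(
    sample_id = sample_id, group = group, chrom = chrom,
    start = wids * window_size,
    end = pmin((wids + 1) * window_size, L),
    n_compared = n_compared, n_diff = n_diff,
    p = ifelse(n_compared >= min_sites, n_diff / pmax(n_compared, 1L),
               NA_real_))
  class(out) <- c("window_track", class(out))
  out
}

#' Detect separation flips between in-group and out-group distance tracks
#'
#' Given per-window p-distance tracks for at least one in-group and one
#' out-group sample on the same window grid, flags every window where the
#' minimum defined out-group p-distance drops to or below the maximum
#' defined in-group p-distance — the overlap ("flip") signature of
#' mis-phased or introgressed sequence. Windows where either group has no
#' defined value are skipped and counted separately.
#'
#' @param tracks A single tibble of stacked [window_pdistance()] tracks with
#'   a `group` column, or a list of tracks; alternatively pass in-group
#'   tracks here and out-group tracks as `outgroup`.
#' @param outgroup Optional out-group tracks when `tracks` holds only the
#'   in-group.
#' @return A tibble of class `flip_report`, one row per evaluated window:
#'   `chrom`, `start`, `end`, `max_ingroup_p`, `min_outgroup_p`, `flagged`.
#'   Attribute `n_skipped` counts windows with an entirely missing group.
#' @export
detect_flips <- function(tracks, outgroup = NULL) {
  bind_any <- function(x, grp = NULL) {
    if (is.data.frame(x)) x <- list(x)
    out <- bind_rows(x)
    if (!is.null(grp)) out$group <- grp
    out
  }
  all_tracks <- if (is.null(outgroup)) bind_any(tracks)
                else bind_rows(bind_any(tracks, "ingroup"),
                               bind_any(outgroup, "outgroup"))
  if (!"group" %in% names(all_tracks) || anyNA(all_tracks$group))
    abort("tracks must carry a `group` of \"ingroup\" or \"outgroup\"")
  if (!all(all_tracks$group %in% c("ingroup", "outgroup")))
    abort("`group` must be \"ingroup\" or \"outgroup\"")
  if (!all(c("ingroup", "outgroup") %in% all_tracks$group))
    abort("need at least one ingroup and one outgroup track")
  grids <- all_tracks %>% group_by(.data$sample_id) %>%
    summarise(g = paste(.data$chrom, .data$start, .data$end, collapse = ";"),
              .groups = "drop")
  if (length(unique(grids$g)) != 1)
    abort("all tracks must share the same window grid")
  per <- all_tracks %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(
      max_ingroup_p = suppressWarnings(max(.data$p[.data$group == "ingroup"],
                                           na.rm = TRUE)),
      min_outgroup_p = suppressWarnings(min(.data$p[.data$group == "outgroup"],
                                            na.rm = TRUE)),
      .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  skipped <- !is.finite(per$max_ingroup_p) | !is.finite(per$min_outgroup_p)
  out <- per %>% filter(!skipped) %>%
    mutate(flagged = .data$min_outgroup_p <= .data$max_ingroup_p)
  class(out) <- c("flip_report", class(out))
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' @export
print.flip_report <- function(x, ...) {
  cat(sprintf("<flip_report> %d windows evaluated, %d flagged, %d skipped\n",
              nrow(x), sum(x$flagged), attr(x, "n_skipped") %||% 0L))
  if (any(x$flagged)) print(as_tibble(x)[x$flagged, ])
  invisible(x)
}

#' Plot per-window p-distance traces with flagged windows highlighted
#'
#' @param tracks Stacked [window_pdistance()] tracks (tibble or list).
#' @param flips Optional [detect_flips()] report; flagged windows are shaded.
#' @return A ggplot object (one panel per chromosome).
#' @export
plot_tracks <- function(tracks, flips = NULL) {
  if (!is.data.frame(tracks)) tracks <- bind_rows(tracks)
  d <- filter(tracks, !is.na(.data$p))
  gg <- ggplot(d, aes(x = (.data$start + .data$end) / 2, y = .data$p,
                      colour = .data$group, group = .data$sample_id)) +
    geom_line(alpha = 0.8) +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (bp)", y = "uncorrected p-distance",
         colour = "group") +
    theme_minimal()
  if (!is.null(flips) && any(flips$flagged)) {
    fl <- flips[flips$flagged, ]
    gg <- gg + geom_rect(
      data = fl,
      aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.15)
  }
  gg
}

#' @export
autoplot.window_track <- function(object, ...) plot_tracks(object, ...)

#' Windowed p-distance tracks for a sample sheet of consensus FASTAs
#'
#' File-based front end to [window_pdistance()]: reads a reference FASTA and
#' a sample sheet (TSV with columns `sample_id`, `group`, `path`; `group`
#' is `ingroup` or `outgroup`) of reference-coordinate consensus FASTAs,
#' and returns the stacked window tracks.
#'
#' @param samples Sample sheet path or tibble (`sample_id`, `group`, `path`).
#' @param reference Reference FASTA path (first record used) or sequence.
#' @inheritParams window_pdistance
#' @return Stacked `window_track` tibble suitable for [detect_flips()].
#' @export
window_pdistance_files <- function(samples, reference, window_size = 100000,
                                   min_sites = 1000) {
  if (is.character(samples)) samples <- read.delim(samples, stringsAsFactors = FALSE)
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "group", "path") %in% names(samples)))
    abort("sample sheet needs columns sample_id, group, path")
  ref <- if (file.exists(reference)) read_sequences(reference)$sequence[1]
         else reference
  purrr::pmap(samples, function(sample_id, group, path, ...) {
    window_pdistance(read_sequences(path)$sequence[1], ref,
                     window_size = window_size, min_sites = min_sites,
                     sample_id = sample_id, group = group)
  }) %>% bind_rows()
}
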