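#' Run a replacement-cross phasing experiment
#'
#' Quantifies how trio binning degrades when the short-read data of one or
#' both biological parents is replaced by data from a within-species
#' individual at a given divergence. For each seed, one synthetic trio is
#' generated and binned with its biological parents (the reference cross);
#' then, for every divergence level and replacement mode, marker sets are
#' rebuilt with the replacement individual's short reads, the same F1 long
#' reads are re-binned, and the two binnings are compared with
#' [compare_classifications()].
#'
#' A level of 0 reuses the biological parent's own reads (the degenerate
#' replacement), so its discordance is exactly zero.
#'
#' @param config A named list (or YAML file path) overriding any of:
#'   `genome_length`, `d_between`, `indel_rate`, `levels` (d_within values),
#'   `replace` (subset of `"maternal"`, `"paternal"`, `"both"`), `seeds`,
#'   `k`, `min_count`, `normalize`, `threshold`, and the read-simulation
#'   parameters of [sim_config()]. Defaults run a desk-scale study:
#'   200 kb genome, levels 0.001/0.005/0.01, three seeds, all three
#'   replacement modes. Unlike [sim_config()]'s assembly-grade defaults, the
#'   experiment simulates raw-subread-like long reads (15% error, wide
#'   log-normal lengths, minimum 300 bp): reads carrying only a handful of
#'   intact marker k-mers are the ones a replacement cross can flip, and
#'   they only exist in this noisy, short-tailed regime.
#' @return A tibble of class `replacement_experiment`, one row per
#'   (seed, level, mode): `seed`, `d_within`, `replace`, `n_reads`,
#'   `discordance`, `bin_skew` (|maternal% - paternal%| in the replacement
#'   binning), `n_incorrect`, `fraction_below` and `all_below_fraction`
#'   (below-threshold fractions among discordant and all reads),
#'   `incorrect_base_fraction`.
#' @export
#' @examples
#' \donttest{
#' res <- run_replacement_experiment(list(genome_length = 15e4,
#'   long_read_mean_len = 8000, levels = 0.005, seeds = 1,
#'   replace = "maternal"))
#' res$discordance
#' }
run_replacement_experiment <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    genome_length = 2e5, d_between = 0.03, indel_rate = 1e-4,
    levels = c(0.001, 0.005, 0.01),
    replace = c("maternal", "paternal", "both"),
    seeds = c(1L, 2L, 3L),
    k = 21L, min_count = 2L, normalize = FALSE, threshold = 10000,
    long_read_coverage = 60, long_read_mean_len = 15000,
    long_read_min_len = 300, long_read_error = 0.15, long_read_sdlog = 1.0,
    short_read_coverage = 30, short_read_len = 150, short_read_error = 0.01)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown experiment config keys: %s",
                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  cfg$replace <- match.arg(cfg$replace, c("maternal", "paternal", "both"),
                           several.ok = TRUE)
  if (any(cfg$levels >= cfg$d_between))
    abort("every replacement level must satisfy d_within < d_between")

  rows <- list()
  for (seed in cfg$seeds) {
    sc <- sim_config(
      genome_length = cfg$genome_length, d_between = cfg$d_between,
      indel_rate = cfg$indel_rate,
      long_read_coverage = cfg$long_read_coverage,
      long_read_mean_len = cfg$long_read_mean_len,
      long_read_min_len = cfg$long_read_min_len,
      long_read_error = cfg$long_read_error,
      long_read_sdlog = cfg$long_read_sdlog,
      short_read_coverage = cfg$short_read_coverage,
      short_read_len = cfg$short_read_len,
      short_read_error = cfg$short_read_error,
      seed = seed)
    pair <- simulate_parent_genomes(sc)
    lr <- simulate_long_reads(pair, cfg = sc)
    counts_bio <- list(
      maternal = count_kmers(simulate_short_reads(pair$maternal, sc,
                                                  seed = derive_seed(seed, 1L)),
                             cfg$k, cfg$min_count),
      paternal = count_kmers(simulate_short_reads(pair$paternal, sc,
                                                  seed = derive_seed(seed, 2L)),
                             cfg$k, cfg$min_count))
    ref_markers <- build_marker_sets(counts_bio$maternal, counts_bio$paternal)
    ref_cls <- classify_reads(lr$reads, ref_markers, normalize = cfg$normalize)

    for (li in seq_along(cfg$levels)) {
      level <- cfg$levels[li]
      counts_rep <- counts_bio
      if (level > 0) {
        for (side in c("maternal", "paternal")) {
          if (!any(cfg$replace %in% c(side, "both"))) next
          ind <- simulate_individual(pair[[side]], level,
                                     seed = derive_seed(seed, 10L * li +
                                                          (side == "paternal")),
                                     sample_id = paste0(side, "_rep"))
          counts_rep[[side]] <- count_kmers(
            simulate_short_reads(ind, sc,
                                 seed = derive_seed(seed, 100L * li +
                                                      (side == "paternal"))),
            cfg$k, cfg$min_count)
        }
      }
      for (mode in cfg$replace) {
        cm <- if (mode %in% c("maternal", "both")) counts_rep$maternal
              else counts_bio$maternal
        cp <- if (mode %in% c("paternal", "both")) counts_rep$paternal
              else counts_bio$paternal
        alt_cls <- classify_reads(lr$reads, build_marker_sets(cm, cp),
                                  normalize = cfg$normalize)
        rep <- compare_classifications(ref_cls, alt_cls)
        lp <- length_profile(rep, cfg$threshold)
        rows[[length(rows) + 1L]] <- tibble(
          seed = seed, d_within = level, replace = mode,
          n_reads = rep$n_reads,
          discordance = 1 - rep$correct_reads / rep$n_reads,
          bin_skew = abs(mean(alt_cls$assigned == "maternal") -
                           mean(alt_cls$assigned == "paternal")) * 100,
          n_incorrect = lp$n_incorrect,
          fraction_below = lp$fraction_below,
          all_below_fraction = lp$all_below_fraction,
          incorrect_base_fraction = lp$incorrect_base_fraction)
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("replacement_experiment", class(out))
  out
}

#' @export
autoplot.replacement_experiment <- function(object, ...) {
  d <- object %>%
    group_by(.data$d_within, .data$replace) %>%
    summarise(discordance = median(.data$discordance), .groups = "drop")
  ggplot(d, aes(x = .data$d_within, y = .data$discordance,
                colour = .data$replace)) +
    geom_line() + geom_point() +
    labs(x = "replacement divergence (d_within)",
         y = "median discordance fraction", colour = "parent replaced") +
    theme_minimal()
}
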