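#' Simulation configuration for a synthetic trio
#'
#' Bundles every parameter of the synthetic trio generator. The defaults
#' emulate the study conditions of an interspecies F1 cross: parental genomes
#' at 3% nucleotide divergence (97% aligned identity), parental paired
#' short reads at 40-fold coverage with 2x150 bp reads, and F1 long reads at
#' 20-fold coverage with a log-normal length distribution (mean 15 kb,
#' minimum 1 kb). A single integer `seed` fully determines all generated
#' output.
#'
#' @param genome_length Haploid genome length in bp (single chromosome).
#' @param d_between Aligned-site nucleotide divergence between the two
#'   parental species, as a fraction. Realised as an exact count
#'   `round(d_between * genome_length)` of uniformly placed SNPs.
#' @param indel_rate Indel events per ancestral bp between the parental
#'   lineages (geometric lengths, mean 3 bp, capped at 50 bp).
#' @param d_within SNP-only divergence of a within-species replacement
#'   individual from its parental genome, as a fraction.
#' @param long_read_coverage,long_read_mean_len,long_read_min_len,long_read_error
#'   F1 long-read fold coverage, mean and minimum read length (bp), and
#'   per-base substitution error rate.
#' @param long_read_sdlog Standard deviation of log read length for the
#'   log-normal length model. The default 0.5 gives a narrow, assembly-grade
#'   length distribution; ~1.0 approximates the wide subread length spread
#'   of raw long-read data.
#' @param short_read_coverage,short_read_len,short_read_error Parental paired
#'   short-read fold coverage, read length (bp) and per-base substitution
#'   error rate. Insert size is ~300 bp (sd 25).
#' @param seed Integer seed determining all generated output.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2e5, seed = 42)
#' cfg$d_between
sim_config <- function(genome_length = 1e6,
                       d_between = 0.03,
                       indel_rate = 1e-4,
                       d_within = 0.005,
                       long_read_coverage = 20,
                       long_read_mean_len = 15000,
                       long_read_min_len = 1000,
                       long_read_error = 0.01,
                       long_read_sdlog = 0.5,
                       short_read_coverage = 40,
                       short_read_len = 150,
                       short_read_error = 0.01,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    d_between = d_between, indel_rate = indel_rate, d_within = d_within,
    long_read_coverage = long_read_coverage,
    long_read_mean_len = long_read_mean_len,
    long_read_min_len = long_read_min_len,
    long_read_error = long_read_error,
    long_read_sdlog = long_read_sdlog,
    short_read_coverage = short_read_coverage,
    short_read_len = short_read_len,
    short_read_error = short_read_error,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c("d_between", "indel_rate", "d_within", "long_read_error",
             "short_read_error")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      abort(sprintf("`%s` must lie in [0, 1], got %g", r, cfg[[r]]))
  if (cfg$genome_length < 10 * cfg$long_read_mean_len)
    abort("genome_length must be at least 10 x long_read_mean_len")
  # per-site indel probability ~ indel_rate; beyond this the aligned
  # coordinate bookkeeping is meaningless
  if (cfg$d_between + cfg$indel_rate > 0.5)
    abort("d_between + indel_rate > 0.5 is not supported")
  if (cfg$long_read_sdlog <= 0)
    abort("`long_read_sdlog` must be positive")
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    abort("`seed` must be a single integer")
  invisible(cfg)
}
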