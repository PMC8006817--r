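# Shared desk-scale fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  defaults <- list(genome_length = 5e4, long_read_mean_len = 4000,
                   long_read_min_len = 500, long_read_coverage = 6,
                   short_read_coverage = 15, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Full-scale study trio (1 Mb, 40x short reads at 1% error, 20x long reads
# at 1% error, k = 21), built once and shared by the acceptance tests.
study_trio <- function() {
  if (is.null(.fixture_env$study)) {
    t0 <- Sys.time()
    cfg <- sim_config(genome_length = 1e6, d_between = 0.03,
                      short_read_coverage = 40, short_read_error = 0.01,
                      long_read_coverage = 20, long_read_error = 0.01,
                      seed = 101)
    pair <- simulate_parent_genomes(cfg)
    lr <- simulate_long_reads(pair, cfg = cfg)
    markers <- build_marker_sets(
      count_kmers(simulate_short_reads(pair$maternal, cfg, seed = 102),
                  k = 21, min_count = 2),
      count_kmers(simulate_short_reads(pair$paternal, cfg, seed = 103),
                  k = 21, min_count = 2))
    binres <- bin_reads(lr$reads, markers)
    .fixture_env$study <- list(
      cfg = cfg, pair = pair, long_reads = lr, markers = markers,
      bin = binres, elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  }
  .fixture_env$study
}

# Default replacement-cross experiment, shared by the degradation and
# length-bias acceptance tests.
study_experiment <- function() {
  if (is.null(.fixture_env$experiment))
    .fixture_env$experiment <- run_replacement_experiment()
  .fixture_env$experiment
}

# Error-free small trio with marker sets and classification, used by several
# triobin and pha tests.
clean_trio <- function() {
  if (is.null(.fixture_env$clean)) {
    cfg <- small_cfg(long_read_error = 0, short_read_error = 0, indel_rate = 0)
    pair <- simulate_parent_genomes(cfg)
    lr <- simulate_long_reads(pair, cfg = cfg)
    counts <- list(
      maternal = count_kmers(simulate_short_reads(pair$maternal, cfg, seed = 1),
                             k = 21, min_count = 2),
      paternal = count_kmers(simulate_short_reads(pair$paternal, cfg, seed = 2),
                             k = 21, min_count = 2))
    markers <- build_marker_sets(counts$maternal, counts$paternal)
    cls <- classify_reads(lr$reads, markers)
    .fixture_env$clean <- list(cfg = cfg, pair = pair, long_reads = lr,
                               counts = counts, markers = markers,
                               classification = cls)
  }
  .fixture_env$clean
}
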