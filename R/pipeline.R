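pipeline_defaults <- function() {
  list(
    global = list(seed = 1L, outdir = "triophase_out", log_level = "info"),
    simulate = list(genome_length = 2e5, d_between = 0.03, indel_rate = 1e-4,
                    d_within = 0.005,
                    long_read_coverage = 15, long_read_mean_len = 15000,
                    long_read_min_len = 1000, long_read_error = 0.01,
                    long_read_sdlog = 0.5,
                    short_read_coverage = 30, short_read_len = 150,
                    short_read_error = 0.01),
    bin = list(k = 21L, min_count = 2L, normalize = FALSE),
    pha = list(threshold = 10000, mode = "strict", d_within = 0.005,
               replace = "both"),
    pdist = list(window_size = 20000, min_sites = 1000,
                 n_ingroup = 3L, n_outgroup = 3L, d_ingroup = 0.005,
                 d_outgroup = 0.005, figure = TRUE))
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_defaults()
  if (length(setdiff(names(config), names(defaults))))
    abort(sprintf("unknown config section(s): %s",
                  paste(setdiff(names(config), names(defaults)), collapse = ", ")))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      abort(sprintf("unknown key(s) in section `%s`: %s", sec,
                    paste(bad, collapse = ", ")))
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], config[[sec]])
  }
  defaults
}

#' Run the full synthetic phasing pipeline
#'
#' Executes, in dependency order: `simulate` (synthetic trio: parental
#' genomes, F1 long reads with truth labels, parental short reads), `bin`
#' (marker k-mer construction and long-read binning), `pha` (a replacement
#' cross at the configured divergence compared against the reference
#' binning), and `pdist` (a panel of in-group/out-group individuals, window
#' p-distance tracks against the maternal reference, flip detection). Every
#' stage writes its outputs under `outdir` and the resolved configuration is
#' saved beside them (`config.yaml`); identical config + seed reproduces
#' byte-identical primary outputs.
#'
#' @param config Nested named list (sections `global`, `simulate`, `bin`,
#'   `pha`, `pdist`) or a YAML file path. Unknown keys are rejected.
#' @param stages Which stages to run (default all, in order).
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "bin", "pha", "pdist")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  outdir <- cfg$global$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create outdir %s", outdir))
  logf <- file.path(outdir, "pipeline.log")
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (!identical(cfg$global$log_level, "quiet")) message(line)
  }
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  seed <- cfg$global$seed
  sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
  res <- list(config = cfg)

  log_msg("stage simulate: L=%g d_between=%g seed=%d",
          sc$genome_length, sc$d_between, seed)
  pair <- simulate_parent_genomes(sc)
  lr <- simulate_long_reads(pair, cfg = sc)
  sr <- list(
    maternal = simulate_short_reads(pair$maternal, sc, seed = derive_seed(seed, 1L)),
    paternal = simulate_short_reads(pair$paternal, sc, seed = derive_seed(seed, 2L)))
  res$simulate <- list(pair = pair, long_reads = lr, short_reads = sr)
  if ("simulate" %in% stages) {
    write_sequences(tibble(id = "maternal chr1", sequence = pair$maternal$sequence),
                    file.path(outdir, "maternal.fasta"))
    write_sequences(tibble(id = "paternal chr1", sequence = pair$paternal$sequence),
                    file.path(outdir, "paternal.fasta"))
    write_sequences(dplyr::rename(lr$reads, id = "read_id"),
                    file.path(outdir, "f1_long_reads.fastq"))
    write.table(lr$truth, file.path(outdir, "f1_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (side in names(sr))
      write_sequences(
        with(sr[[side]], tibble(id = paste0(read_id, "/", mate),
                                sequence = sequence, quality = quality)),
        file.path(outdir, paste0(side, "_short_reads.fastq")))
    write.table(pair$truth_variants, file.path(outdir, "truth_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (any(c("bin", "pha") %in% stages)) {
    log_msg("stage bin: k=%d min_count=%d", cfg$bin$k, cfg$bin$min_count)
    counts <- lapply(sr, count_kmers, k = cfg$bin$k, min_count = cfg$bin$min_count)
    markers <- build_marker_sets(counts$maternal, counts$paternal)
    bin_out <- if ("bin" %in% stages) file.path(outdir, "bins") else NULL
    binres <- bin_reads(lr$reads, markers, normalize = cfg$bin$normalize,
                        outdir = bin_out)
    res$bin <- binres
    log_msg("binned %d reads: %s", nrow(binres$classification),
            paste(sprintf("%s %.2f%%", binres$summary$bin,
                          binres$summary$pct_reads), collapse = ", "))
  }

  if ("pha" %in% stages) {
    log_msg("stage pha: replacement d_within=%g (%s)", cfg$pha$d_within,
            cfg$pha$replace)
    cr <- counts
    for (side in c("maternal", "paternal")) {
      if (!cfg$pha$replace %in% c(side, "both")) next
      ind <- simulate_individual(pair[[side]], cfg$pha$d_within,
                                 seed = derive_seed(seed, 31L + (side == "paternal")),
                                 sample_id = paste0(side, "_rep"))
      cr[[side]] <- count_kmers(
        simulate_short_reads(ind, sc, seed = derive_seed(seed, 41L + (side == "paternal"))),
        cfg$bin$k, cfg$bin$min_count)
    }
    alt <- classify_reads(lr$reads, build_marker_sets(cr$maternal, cr$paternal),
                          normalize = cfg$bin$normalize)
    report <- compare_classifications(binres$classification, alt,
                                      mode = cfg$pha$mode)
    lp <- length_profile(report, cfg$pha$threshold)
    res$pha <- list(report = report, length_profile = lp)
    jsonlite::write_json(
      list(summary = glance(report), subtypes = report$incorrect_by_subtype,
           length_profile = lp),
      file.path(outdir, "pha_report.json"), auto_unbox = TRUE, digits = NA)
    write.table(tidy(report), file.path(outdir, "pha_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("pha: %d/%d concordant", report$correct_reads, report$n_reads)
  }

  if ("pdist" %in% stages) {
    log_msg("stage pdist: window=%d panel %d+%d", cfg$pdist$window_size,
            cfg$pdist$n_ingroup, cfg$pdist$n_outgroup)
    # out-group consensus must live in reference (maternal) coordinates, as
    # mapped-and-realigned consensus sequences would: apply only the SNP
    # events of the truth table to the maternal backbone
    snp_truth <- pair$truth_variants[pair$truth_variants$type == "snp", ]
    pat_aligned <- list(
      species_id = pair$paternal$species_id, chrom_id = pair$paternal$chrom_id,
      sequence = apply_truth_variants(pair$maternal$sequence, snp_truth))
    panel <- c(
      lapply(seq_len(cfg$pdist$n_ingroup), function(i)
        simulate_individual(pair$maternal, cfg$pdist$d_ingroup,
                            seed = derive_seed(seed, 50L + i),
                            sample_id = sprintf("ingroup_%d", i))),
      lapply(seq_len(cfg$pdist$n_outgroup), function(i)
        simulate_individual(pat_aligned, cfg$pdist$d_outgroup,
                            seed = derive_seed(seed, 70L + i),
                            sample_id = sprintf("outgroup_%d", i))))
    groups <- rep(c("ingroup", "outgroup"),
                  c(cfg$pdist$n_ingroup, cfg$pdist$n_outgroup))
    tracks <- purrr::map2(panel, groups, function(g, grp)
      window_pdistance(g, pair$maternal, window_size = cfg$pdist$window_size,
                       min_sites = cfg$pdist$min_sites,
                       sample_id = g$sample_id, group = grp)) %>% bind_rows()
    flips <- detect_flips(tracks)
    res$pdist <- list(tracks = tracks, flips = flips)
    write.table(tracks, file.path(outdir, "pdist_tracks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fl <- flips[flips$flagged, c("chrom", "start", "end")]
    write.table(fl, file.path(outdir, "flips.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (isTRUE(cfg$pdist$figure)) {
      ok <- tryCatch({
        ggplot2::ggsave(file.path(outdir, "pdist_tracks.png"),
                        plot_tracks(tracks, flips), width = 8, height = 4,
                        dpi = 120)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) log_msg("figure rendering unavailable; skipped pdist_tracks.png")
    }
    log_msg("pdist: %d windows, %d flagged", nrow(flips), sum(flips$flagged))
  }
  invisible(res)
}
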