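test_that("pseudo-haploidization keeps homozygous bases, samples heterozygous, masks missing", {
  expect_equal(pseudo_haploidize("ACGT", "ACGT", seed = 1), "ACGT")
  expect_equal(substr(pseudo_haploidize("ACGT", "ACNT", seed = 1), 3, 3), "N")
  # heterozygous site resolves to one of the two alleles
  h <- pseudo_haploidize("AAAA", "AAAT", seed = 1)
  expect_true(substr(h, 4, 4) %in% c("A", "T"))
  expect_error(pseudo_haploidize("ACG", "ACGT"), "length")
  expect_error(pseudo_haploidize("ACG", "ACG", ref_length = 10), "reference")
})

test_that("heterozygous allele choice is uniform and reproducible", {
  n <- 10000
  a1 <- strrep("A", n)
  a2 <- strrep("C", n)
  h1 <- pseudo_haploidize(a1, a2, seed = 9)
  frac_first <- mean(strsplit(h1, "")[[1]] == "A")
  expect_lt(abs(frac_first - 0.5), 3 * sqrt(0.25 / n))
  expect_identical(pseudo_haploidize(a1, a2, seed = 9), h1)
  expect_false(identical(pseudo_haploidize(a1, a2, seed = 10), h1))
})

test_that("window p-distance matches its definition on constructed windows", {
  ref <- strrep("A", 100)
  smp <- paste0(strrep("A", 50), strrep("C", 3), strrep("A", 47))
  tr <- window_pdistance(smp, ref, window_size = 100, min_sites = 1)
  expect_equal(tr$p, 0.03)
  # self-distance is zero
  expect_equal(window_pdistance(ref, ref, window_size = 10, min_sites = 1)$p,
               rep(0, 10))
  # N sites are excluded from the comparison
  smp2 <- paste0(strrep("N", 10), strrep("C", 3), strrep("A", 87))
  tr2 <- window_pdistance(smp2, ref, window_size = 100, min_sites = 1)
  expect_equal(tr2$n_compared, 90)
  expect_equal(tr2$p, 3 / 90)
  # below min_sites the window value is missing
  tr3 <- window_pdistance(smp2, ref, window_size = 100, min_sites = 91)
  expect_true(is.na(tr3$p))
  expect_error(window_pdistance(smp, ref, window_size = 0), "window_size")
  expect_error(window_pdistance("ACG", ref), "length")
})

test_that("windows tile the sequence exactly once and a short final window is kept", {
  ref <- strrep("ACGT", 2600)  # L = 10400
  tr <- window_pdistance(ref, ref, window_size = 1000, min_sites = 1)
  expect_equal(tr$start, seq(0, 10000, by = 1000))
  expect_equal(tr$end, c(seq(1000, 10000, by = 1000), 10400))
  expect_equal(sum(tr$end - tr$start), 10400)
  expect_equal(sum(tr$n_compared), 10400)
})

test_that("genome-wide mean p recovers the simulated divergence exactly", {
  cfg <- sim_config(genome_length = 1e5, indel_rate = 0,
                    long_read_mean_len = 10000, seed = 31)
  pair <- simulate_parent_genomes(cfg)
  ind <- simulate_individual(pair$maternal, 0.005, seed = 8)
  tr <- window_pdistance(ind, pair$maternal, window_size = 10000,
                         min_sites = 100)
  expect_equal(sum(tr$n_diff) / sum(tr$n_compared), 0.005, tolerance = 1e-9)
  expect_identical(window_pdistance(ind, pair$maternal, window_size = 10000,
                                    min_sites = 100), tr)
  # agreement with a plain per-site oracle on one window
  expect_equal(tr$p[3], oracle_pdist(substr(ind$sequence, 20001, 30000),
                                     substr(pair$maternal$sequence, 20001, 30000)))
})

test_that("clean panels show full in/out separation and no flips", {
  cfg <- sim_config(genome_length = 1e5, indel_rate = 0,
                    long_read_mean_len = 10000, seed = 13)
  pair <- simulate_parent_genomes(cfg)
  tracks <- dplyr::bind_rows(c(
    lapply(1:3, function(i)
      window_pdistance(simulate_individual(pair$maternal, 0.004, seed = i),
                       pair$maternal, 10000, 100,
                       sample_id = paste0("in", i), group = "ingroup")),
    lapply(1:3, function(i)
      window_pdistance(simulate_individual(pair$paternal, 0.004, seed = 10 + i),
                       pair$maternal, 10000, 100,
                       sample_id = paste0("out", i), group = "outgroup"))))
  fl <- detect_flips(tracks)
  expect_equal(nrow(fl), 10)
  expect_false(any(fl$flagged))
  expect_true(all(fl$max_ingroup_p < fl$min_outgroup_p))
  # swapping group labels flags every window
  swapped <- dplyr::mutate(tracks, group = ifelse(group == "ingroup",
                                                  "outgroup", "ingroup"))
  expect_true(all(detect_flips(swapped)$flagged))
})

test_that("a haplotype-swapped reference window is flagged and clean windows are not", {
  cfg <- sim_config(genome_length = 1e5, indel_rate = 0,
                    long_read_mean_len = 10000, seed = 41)
  pair <- simulate_parent_genomes(cfg)
  w <- 10000
  ref <- paste0(substr(pair$maternal$sequence, 1, 4 * w),
                substr(pair$paternal$sequence, 4 * w + 1, 5 * w),
                substr(pair$maternal$sequence, 5 * w + 1, 1e5))
  tracks <- dplyr::bind_rows(c(
    lapply(1:3, function(i)
      window_pdistance(simulate_individual(pair$maternal, 0.004, seed = i),
                       ref, w, 100, sample_id = paste0("in", i),
                       group = "ingroup")),
    lapply(1:3, function(i)
      window_pdistance(simulate_individual(pair$paternal, 0.004, seed = 10 + i),
                       ref, w, 100, sample_id = paste0("out", i),
                       group = "outgroup"))))
  fl <- detect_flips(tracks)
  expect_true(fl$flagged[fl$start == 4 * w])
  expect_equal(sum(fl$flagged), 1)
})

test_that("flip detection validates its inputs", {
  tr <- window_pdistance(strrep("A", 1000), strrep("A", 1000),
                         window_size = 100, min_sites = 1,
                         sample_id = "s", group = "ingroup")
  expect_error(detect_flips(tr), "ingroup and one outgroup")
  tr2 <- dplyr::mutate(tr, sample_id = "t", group = "outgroup")
  off_grid <- dplyr::mutate(tr2, start = start + 1, end = end + 1)
  expect_error(detect_flips(dplyr::bind_rows(tr, off_grid)), "grid")
  expect_error(detect_flips(dplyr::mutate(tr, group = NA_character_)), "group")
})

test_that("track plotting is deterministic in its plotted coordinates", {
  fx_tracks <- dplyr::bind_rows(
    window_pdistance(strrep("A", 1000), strrep("A", 1000), 100, 1,
                     sample_id = "a", group = "ingroup"),
    window_pdistance(paste0(strrep("C", 500), strrep("A", 500)),
                     strrep("A", 1000), 100, 1,
                     sample_id = "b", group = "outgroup"))
  p1 <- plot_tracks(fx_tracks, detect_flips(fx_tracks))
  p2 <- plot_tracks(fx_tracks, detect_flips(fx_tracks))
  expect_s3_class(p1, "ggplot")
  expect_identical(ggplot2::layer_data(p1), ggplot2::layer_data(p2))
})

test_that("sample-sheet front end reproduces in-memory tracks", {
  d <- withr::local_tempdir()
  ref <- strrep("ACGTG", 400)
  smp <- paste0(strrep("ACGTG", 200), strrep("TGCAC", 200))
  write_sequences(tibble::tibble(id = "ref", sequence = ref),
                  file.path(d, "ref.fa"))
  write_sequences(tibble::tibble(id = "s1", sequence = smp),
                  file.path(d, "s1.fa"))
  sheet <- tibble::tibble(sample_id = "s1", group = "ingroup",
                          path = file.path(d, "s1.fa"))
  tr <- window_pdistance_files(sheet, file.path(d, "ref.fa"),
                               window_size = 500, min_sites = 10)
  expect_equal(tr, window_pdistance(smp, ref, 500, 10, sample_id = "s1",
                                    group = "ingroup"))
})
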