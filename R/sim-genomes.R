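#' Simulate a pair of divergent parental genomes
#'
#' Generates the two haploid parental genomes of a synthetic interspecies F1
#' cross. The maternal sequence is drawn uniformly over ACGT; the paternal
#' sequence is derived from it by placing exactly
#' `round(d_between * genome_length)` SNPs uniformly without replacement at
#' aligned (maternal-coordinate) sites, plus indel events at `indel_rate`
#' events/bp with geometric lengths (mean 3 bp, capped at 50 bp). Every event
#' is recorded in a truth table; replaying the truth table against the
#' maternal sequence reconstructs the paternal sequence exactly.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `parent_pair` with elements `maternal` and
#'   `paternal` (each of class `parent_genome`: `species_id`, `chrom_id`,
#'   `sequence`, `truth_variants`), plus `truth_variants`, the shared event
#'   table: a tibble with columns `position` (0-based, maternal coordinates),
#'   `ref_base`, `alt_base`, `type` (`snp`, `ins`, `del`).
#' @export
#' @examples
#' pair <- simulate_parent_genomes(sim_config(genome_length = 2e5, seed = 1))
#' nrow(pair$truth_variants)
simulate_parent_genomes <- function(cfg) {
  validate_sim_config(cfg)
  L <- cfg$genome_length
  with_seed(derive_seed(cfg$seed, 101L), {
    maternal_seq <- random_dna(L)
    n_snp <- round(cfg$d_between * L)
    snp_pos <- sort(sample.int(L, n_snp))
    mat_raw <- charToRaw(maternal_seq)
    ref <- rawToChar(mat_raw[snp_pos], multiple = TRUE)
    alt_raw <- substitute_bases(mat_raw, snp_pos)[snp_pos]
    alt <- rawToChar(alt_raw, multiple = TRUE)
    truth <- tibble(position = snp_pos - 1, ref_base = ref, alt_base = alt,
                    type = rep("snp", n_snp))

    n_indel <- rbinom(1L, as.integer(L), cfg$indel_rate)
    if (n_indel > 0) {
      avail <- setdiff(seq_len(L), snp_pos)
      anchors <- sort(sample(avail, min(n_indel, length(avail))))
      lens <- pmin(1L + rgeom(length(anchors), 1 / 3), 50L)
      types <- sample(c("ins", "del"), length(anchors), replace = TRUE)
      # deletions must not swallow later events or run off the sequence
      reserved <- sort(c(snp_pos, anchors, L + 1))
      nxt <- reserved[findInterval(anchors, reserved) + 1L]
      lens <- ifelse(types == "del", pmin(lens, nxt - anchors, L - anchors + 1), lens)
      ins_seq <- vapply(lens, random_dna, character(1))
      indel <- tibble(
        position = anchors - 1,
        ref_base = ifelse(types == "del",
                          substring(maternal_seq, anchors, anchors + lens - 1), ""),
        alt_base = ifelse(types == "ins", ins_seq, ""),
        type = types)
      truth <- bind_rows(truth, indel) %>% arrange(.data$position)
    }
    paternal_seq <- apply_truth_variants(maternal_seq, truth)

    mk <- function(species, seqn) {
      structure(list(species_id = species, chrom_id = "chr1",
                     sequence = seqn, truth_variants = truth),
                class = "parent_genome")
    }
    structure(list(maternal = mk("speciesA", maternal_seq),
                   paternal = mk("speciesB", paternal_seq),
                   truth_variants = truth, d_between = cfg$d_between),
              class = "parent_pair")
  })
}

#' Replay a truth-variant table against a sequence
#'
#' Applies SNP, insertion and deletion events (0-based positions in the
#' coordinates of `sequence`) to reconstruct the derived sequence.
#' Insertions place `alt_base` immediately before `position`; deletions
#' remove `ref_base` starting at `position`.
#'
#' @param sequence A DNA string.
#' @param truth A truth-variant tibble as produced by
#'   [simulate_parent_genomes()].
#' @return The derived sequence as a single string.
#' @export
apply_truth_variants <- function(sequence, truth) {
  if (nrow(truth) == 0) return(sequence)
  truth <- truth[order(truth$position), ]
  pos1 <- truth$position + 1
  pieces <- character(2 * nrow(truth) + 1)
  cur <- 1
  j <- 1
  for (i in seq_len(nrow(truth))) {
    p <- pos1[i]
    pieces[j] <- substring(sequence, cur, p - 1); j <- j + 1
    switch(truth$type[i],
      snp = { pieces[j] <- truth$alt_base[i]; cur <- p + 1 },
      ins = { pieces[j] <- truth$alt_base[i]; cur <- p },
      del = { cur <- p + nchar(truth$ref_base[i]) })
    j <- j + 1
  }
  pieces[j] <- substring(sequence, cur, nchar(sequence))
  paste(pieces, collapse = "")
}

#' Simulate a within-species replacement individual
#'
#' Derives an individual genome from a parental genome by placing exactly
#' `round(d_within * L)` SNPs uniformly without replacement. SNP-only, so
#' reference coordinates are preserved (same length as the base genome).
#'
#' @param base A `parent_genome` (or any object with a `sequence` element).
#' @param d_within SNP divergence from the base genome, a fraction in
#'   `[0, 1)`. For replacement-cross experiments it must be strictly smaller
#'   than the between-species divergence (enforced by
#'   [run_replacement_experiment()]).
#' @param seed Integer seed.
#' @param sample_id Label for the individual.
#' @return An object of class `individual_genome`: `sample_id`, `species_id`,
#'   `chrom_id`, `sequence` and `snp_positions` (0-based).
#' @export
simulate_individual <- function(base, d_within, seed,
                                sample_id = paste0(base$species_id, "_ind")) {
  stopifnot(is.list(base), is.character(base$sequence))
  if (d_within < 0 || d_within >= 1)
    abort("`d_within` must lie in [0, 1)")
  L <- nchar(base$sequence)
  with_seed(derive_seed(seed, 211L), {
    n <- round(d_within * L)
    pos <- sort(sample.int(L, n))
    seq_raw <- substitute_bases(charToRaw(base$sequence), pos)
    structure(list(sample_id = sample_id,
                   species_id = base$species_id %||% "unknown",
                   chrom_id = base$chrom_id %||% "chr1",
                   sequence = rawToChar(seq_raw),
                   snp_positions = pos - 1),
              class = "individual_genome")
  })
}
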