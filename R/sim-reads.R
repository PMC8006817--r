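#' Simulate F1 long reads from two parental haplotypes
#'
#' Draws long reads alternately from the maternal and paternal haplotypes
#' (each read's haplotype of origin is Bernoulli(1/2)), with log-normal read
#' lengths (sd of log = `long_read_sdlog`) truncated below at
#' `long_read_min_len` and mean `long_read_mean_len` before truncation, uniform start positions, and per-base substitution
#' errors at `long_read_error`. Reads are emitted until the total base count
#' reaches `long_read_coverage * genome_length` (per the two-haplotype mean
#' length), so total bases land within a few percent of the target.
#'
#' @param maternal,paternal `parent_genome` objects (or a `parent_pair` as
#'   first argument, in which case `paternal` is taken from it).
#' @param cfg A [sim_config()] object.
#' @param seed Optional seed override; defaults to `cfg$seed`.
#' @return A list of class `long_read_set`: `reads`, a tibble
#'   (`read_id`, `sequence`, `quality`), and `truth`, a tibble
#'   (`read_id`, `haplotype`, `chrom`, `start`, `end`, `length`) with 0-based
#'   half-open truth intervals on the source haplotype.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2e5, long_read_coverage = 2, seed = 3)
#' lr <- simulate_long_reads(simulate_parent_genomes(cfg), cfg = cfg)
#' nrow(lr$reads)
simulate_long_reads <- function(maternal, paternal = NULL, cfg, seed = cfg$seed) {
  if (inherits(maternal, "parent_pair")) {
    paternal <- maternal$paternal
    maternal <- maternal$maternal
  }
  validate_sim_config(cfg)
  if (cfg$long_read_coverage <= 0) abort("long_read_coverage must be > 0")
  haps <- list(maternal = maternal$sequence, paternal = paternal$sequence)
  hap_len <- vapply(haps, nchar, numeric(1))
  target <- cfg$long_read_coverage * cfg$genome_length
  with_seed(derive_seed(seed, 311L), {
    sdl <- cfg$long_read_sdlog
    mu <- log(cfg$long_read_mean_len) - sdl^2 / 2
    n_guess <- ceiling(target / cfg$long_read_mean_len * 1.3) + 10
    lens <- numeric(0)
    while (sum(lens) < target) {
      draw <- round(rlnorm(n_guess, meanlog = mu, sdlog = sdl))
      draw <- draw[draw >= cfg$long_read_min_len]
      lens <- c(lens, draw)
    }
    lens <- lens[seq_len(which(cumsum(lens) >= target)[1])]
    n <- length(lens)
    hap <- sample(c("maternal", "paternal"), n, replace = TRUE)
    lens <- pmin(lens, unname(hap_len[hap]))
    start0 <- floor(runif(n) * (unname(hap_len[hap]) - lens + 1))
    src <- ifelse(hap == "maternal", haps$maternal, haps$paternal)
    seqs <- substring(src, start0 + 1, start0 + lens)
    seqs <- inject_errors(seqs, cfg$long_read_error)
    ids <- sprintf("lr%06d", seq_len(n))
    qual <- strrep(quality_char(cfg$long_read_error), lens)
    structure(list(
      reads = tibble(read_id = ids, sequence = seqs, quality = qual),
      truth = tibble(read_id = ids, haplotype = hap, chrom = maternal$chrom_id,
                     start = start0, end = start0 + lens, length = lens)),
      class = "long_read_set")
  })
}

#' Simulate paired short reads from a genome
#'
#' Generates paired-end reads of fixed length with ~300 bp inserts
#' (Gaussian, sd 25, floored at the read length), uniform fragment
#' placement, and per-base substitution errors. Mate 2 is the reverse
#' complement of the fragment end. Pairs are generated until total bases
#' reach `short_read_coverage * L`.
#'
#' @param genome A `parent_genome` or `individual_genome` (anything with a
#'   `sequence` element), or a plain DNA string.
#' @param cfg A [sim_config()] object.
#' @param seed Optional seed override; defaults to `cfg$seed`.
#' @return A tibble of class `short_read_set` with columns `read_id`, `mate`
#'   (1 or 2), `sequence`, `quality`.
#' @export
simulate_short_reads <- function(genome, cfg, seed = cfg$seed) {
  seqn <- if (is.character(genome)) genome else genome$sequence
  validate_sim_config(cfg)
  L <- nchar(seqn)
  rl <- cfg$short_read_len
  if (rl > L) abort("short_read_len exceeds genome length")
  n_pairs <- ceiling(cfg$short_read_coverage * L / (2 * rl))
  with_seed(derive_seed(seed, 401L), {
    insert <- pmax(round(rnorm(n_pairs, 300, 25)), rl)
    insert <- pmin(insert, L)
    frag_start <- floor(runif(n_pairs) * (L - insert + 1)) + 1
    m1 <- substring(seqn, frag_start, frag_start + rl - 1)
    m2 <- revcomp(substring(seqn, frag_start + insert - rl, frag_start + insert - 1))
    m1 <- inject_errors(m1, cfg$short_read_error)
    m2 <- inject_errors(m2, cfg$short_read_error)
    ids <- sprintf("sr%06d", seq_len(n_pairs))
    q <- strrep(quality_char(cfg$short_read_error), rl)
    out <- tibble(read_id = rep(ids, 2L),
                  mate = rep(c(1L, 2L), each = n_pairs),
                  sequence = c(m1, m2),
                  quality = q)
    class(out) <- c("short_read_set", class(out))
    out
  })
}
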