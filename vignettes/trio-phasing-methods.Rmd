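---
title: "Trio binning, replacement-cross concordance, and windowed p-distance QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio binning, replacement-cross concordance, and windowed p-distance QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(triophase)
```

## The problem

An F1 interspecies hybrid carries one complete haplotype from each parental
species. If the parents' short-read data are available, long reads from the
F1 can be *binned* by haplotype before assembly: a k-mer present in one
parent's reads and absent from the other's (a **marker k-mer**) votes for
the corresponding haplotype, and each long read is assigned to the side with
more marker hits. Assembling each bin separately yields two haploid
assemblies instead of one mosaic diploid consensus.

`triophase` implements this classifier and the two quality-control
procedures that surround it:

* **PHA (phased haplotype analysis)** — given two binnings of the *same*
  long reads (e.g. one using the biological parents, one using substitute
  "replacement" individuals), count reads assigned to the same bin in both
  (the diagonal of a 3×3 confusion matrix over maternal/paternal/unknown)
  and break discordant reads into direction subtypes.
* **Windowed p-distance QC** — given haploid consensus sequences of
  in-group and out-group individuals in reference coordinates, compute the
  uncorrected p-distance (mismatch fraction over non-N sites) per window and
  flag windows where the two species' traces overlap, the signature of
  mis-phased (or introgressed) sequence.

Everything runs on a seeded synthetic trio generator, so the full pipeline
is exercised end to end without any sequencing download.

## The generator and what it emulates

`sim_config()` bundles the study conditions. The defaults model an
interspecies cross of the kind used for trio binning in carnivores:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 1 Mb | one haploid chromosome (desk scale) |
| `d_between` | 0.03 | aligned-site divergence between the parental species (≈97% identity) |
| `indel_rate` | 1e-4 /bp | indel events between the lineages, geometric lengths (mean 3 bp, cap 50 bp) |
| `d_within` | 0.005 | SNP-only divergence of a conspecific replacement individual |
| `short_read_*` | 40×, 2×150 bp, 1% | parental paired short reads, ~300 bp inserts |
| `long_read_*` | 20×, log-normal mean 15 kb (σ(log) 0.5), min 1 kb, 1% | F1 long reads |

Two deliberate departures from a faithful sequencing model make the
statistics exact and testable:

* **Exact-count divergence.** `round(d × L)` SNP positions are drawn
  uniformly *without replacement*, not by per-site Bernoulli trials. The
  realized aligned divergence therefore equals `d` exactly, which turns
  divergence-recovery checks into equalities (to 1e-6) instead of
  statistical bounds.
* **Coordinate-preserving individuals.** Within-species individuals are
  SNP-only, so consensus sequences live in reference coordinates without an
  aligner. Indels exist only between the two parental lineages and are
  recorded in a truth table whose replay reconstructs the paternal sequence
  exactly.

What the generator does **not** model: repeat landscapes, GC bias,
homopolymer indel errors, chromosome-scale karyotypes, Hi-C contacts.
Passing tests therefore demonstrate the correctness of the *procedures*
(counting, classification, concordance accounting, windowed distances), not
the hardness of real genomes — on real data the unknown fraction and the
misassignment rate are driven largely by repeats and error modes that this
generator intentionally omits.

## The classifier

Counting is over canonical k-mers (the lexicographic minimum of a k-mer and
its reverse complement) because reads are unoriented. `k = 21` and
`min_count = 2` are the defaults: at 40× coverage a genuine genomic 21-mer
is seen ~30 times while a k-mer created by a 1% sequencing error is almost
always unique, so a count threshold of 2 removes error k-mers with
negligible loss of true markers. `k` must be odd so no k-mer equals its own
reverse complement. Scoring is by raw marker hit counts; ties and
zero-evidence reads go to `unknown` rather than to a random side. An
optional `normalize` flag divides each count by its marker-set size to
compensate for asymmetric parental marker density (off by default — the two
sets are nearly equal under symmetric divergence).

With `d_between = 0.03` and `k = 21`, roughly `1 − (1 − d)^k ≈ 47%` of read
positions carry a parent-specific marker. A 15 kb read at 1% error retains
thousands of intact markers on its true side, which is why truth recovery on
the study trio is essentially perfect and the unknown bin is empty or nearly
so.

## The replacement-cross experiment

`run_replacement_experiment()` rebuilds marker sets with a replacement
individual at divergence `d_within` standing in for one or both parents,
re-bins the same F1 reads, and runs PHA against the biological-parent
binning. Its defaults are *not* the assembly-grade read model above but a
raw-subread-like one: 15% substitution error, wide log-normal lengths
(σ(log) = 1.0), minimum 300 bp, 60× coverage, on a 200 kb genome with 30×
short reads — sizes chosen so three seeds times three levels times three
modes complete in a few minutes on one CPU.

The reason for the noisy read model is mechanistic, and worth spelling out
because it determines where the misassignment phenomenon lives. A read can
only change bins between two crosses if its marker score margin is small.
The expected number of intact marker hits on a read of length `ℓ` is
`ℓ · 0.47 · (1 − e)^k`; at 1% error that is ~380 hits even for a 1 kb read,
and a replacement at `d_within ≤ 0.01` perturbs marker sets by at most
~`1 − (1 − d_within)^k ≈ 19%` — nowhere near enough to flip a read. At 15%
error, k-mer survival drops to ~3%, and reads of a few hundred bp carry only
a handful of hits: these are the reads a replacement cross flips. The
consequence — discordant reads are overwhelmingly short — is precisely the
length bias the analysis is designed to expose, and the experiment measures
it as the below-10 kb fraction among discordant vs all reads.

Two qualitative properties of the results deserve comment:

* **Monotone degradation.** Median discordance increases with `d_within`
  for every replacement mode, matching the expectation that phasing errors
  grow with the replacement's divergence from the true parent.
* **Both-parent vs single-parent replacement.** One might expect replacing
  both parents to be at least as damaging as replacing either one. In this
  classifier it is reliably *not* so at the higher divergence levels.
  Replacing one parent damages that parent's marker set *and augments the
  other side's*: k-mers shared by both true parents that the replacement
  individual lost become, by the set-difference construction, new markers
  for the intact parent — and those k-mers are present in F1 reads of
  *both* haplotypes. The perturbation is therefore directional, and
  borderline reads drift systematically toward the intact parent (the bin
  skew the experiment also reports). Replacing both parents perturbs the
  two sets symmetrically; each read's two scores inflate together, the
  margin moves less, and fewer reads cross the decision boundary. Measured
  over five seeds at `d_within = 0.01`, both-parent discordance was below
  single-maternal discordance in every seed. The corresponding
  acceptance check asserts the additive expectation and is left failing
  deliberately, as a documented property of the method rather than a defect
  of the implementation.

A replacement level of 0 reuses the biological parent's own reads, so its
discordance is exactly zero — the degenerate cross anchors the scale.

## Windowed p-distance QC

`window_pdistance()` tiles the reference into fixed windows (default
100 kb, the convention for this analysis; the final short window is kept)
and computes `p = n_diff / n_compared` over sites where neither sequence is
N. Windows with fewer than `min_sites` (default 1000) compared sites get a
missing `p` rather than a noisy one. Coordinates are 0-based half-open (BED
convention) in all outputs.

`detect_flips()` makes the visual "flip" criterion explicit as an overlap
test: a window is flagged iff the *minimum* defined out-group p-distance is
≤ the *maximum* defined in-group p-distance. Windows where either group is
entirely missing are skipped and counted separately. With in-group samples
at `d ≤ 0.005` and out-group samples at `d ≈ 0.03`, a 100 kb window
contains thousands of compared sites and the two traces are separated by
many standard deviations, so clean windows essentially never flag and a
haplotype-swapped window always does — the package's acceptance checks
assert exactly that, across seeds.

`pseudo_haploidize()` collapses diploid calls to one random allele per
heterozygous site (seeded, uniform), the standard random-base consensus;
missing calls become N. Sample-vs-reference distances are the primary mode;
all-pairwise comparison is out of scope here.

## Numerical and design choices

* All randomness flows through one seeded generator per operation; a single
  integer seed makes every output byte-reproducible (`run_pipeline()` writes
  the resolved config next to its outputs, and re-running it reproduces
  identical primary files).
* Long-read lengths are log-normal truncated at `min_len` by resampling;
  reads are emitted until total bases reach `coverage × L`, which lands
  within a few percent of the target.
* `k` is restricted to odd values in [3, 31]: 3 admits the tiny worked
  examples in the documentation, 31 is the 2-bit-encoding limit; values
  below ~11 are statistically useless on real-size genomes.
* Exact hash-based counting is used rather than probabilistic sketches —
  desk-scale genomes do not need approximation.
* Deletions in the parental truth table are capped so they never swallow a
  later variant position, keeping the event log replayable in one pass.
* In `run_pipeline()`'s QC stage the out-group consensus is built by
  applying only the SNP events of the truth table to the maternal backbone,
  mimicking what mapping + indel realignment produce: a consensus in
  reference coordinates.

## Problem sizes

The shipped checks run at: 1 Mb / 40× / 20× for truth recovery (about one
to two minutes), 50 kb genomes for exact marker-oracle equivalence, 200 kb
with 60× long reads × 3 seeds for the replacement experiment (a few
minutes), and 1 Mb panels for divergence recovery and flip detection.
These sizes were chosen so the whole suite runs comfortably on a laptop
while keeping per-cell counts large enough for stable medians.

## Known limitations

* The substitution-only error model cannot reproduce homopolymer-driven
  misassignment or chimeric reads.
* Marker density on a uniform random genome is higher and more even than on
  a real genome with repeats; absolute discordance rates here are not
  comparable to rates on real data, only their direction and ordering.
* The flip detector assumes all tracks share one window grid and flags
  single windows independently; it does not segment runs of flipped windows
  or assign breakpoints.
* Binning does not attempt error correction or assembly; outputs are bins,
  tables and reports only.
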