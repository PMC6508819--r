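---
title: "Methods: homeolog allele dosage, expression and growth analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeolog allele dosage, expression and growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`homeodose` analyses a small deletion segregating among the homeologous
copies of one gene in a polyploid. The central statistical object is the
allele dosage *d*: of the *m* alleles at the locus (for three
diploid-behaving copies, *m* = 2 × 3 = 6), how many carry the deletion?

The measurement model is deliberately simple. Reads that span the variant
site are classified by exact substring match against a paralog-unique
probe pair (reference window of length *w*, deletion window of length
*w* − ℓ for an ℓ-bp deletion), in both orientations. Conditional on a read
being informative, the probability that it shows the deletion is *d/m*
under three assumptions:

* every allele copy contributes reads at equal rate (no copy-specific
  amplification or expression bias — relaxable via `copy_weights` in the
  simulator);
* probe matching has no false positives (guaranteed for exact matching if
  the window is unique among the paralogs) and false negatives only remove
  reads at random (a sequencing error inside the window makes the read
  uninformative, it cannot convert one allele into the other, because no
  substitution can mimic a length difference);
* informative reads are independent.

The classified counts (`n_alt`, `n_ref`) are then binomial, giving the
log-likelihood `L(d) = n_alt·ln(d/m) + n_ref·ln(1 − d/m)` on the integer
grid `d = 0..m`. Boundary dosages are impossible (−∞) unless the
corresponding count is zero. `ml_dosage()` reports the argmax; exact
likelihood ties are reported as ambiguous, never broken arbitrarily. The
dosage grid is integer-only because the scientific question is about whole
gene-copy configurations, not population allele frequencies.

Hypothesized ratios are tested with the Pearson chi-square goodness-of-fit
statistic on two categories (df = 1), **without** Yates continuity
correction: the uncorrected test reproduces the published p ≈ 0.72 for the
winter genotype's 5:21 counts against 1:5 (hand value 0.726), whereas the
corrected test gives ≈ 0.93. With 26–35 informative reads, expected counts
can fall below 5; the implementation warns and can report a two-sided
exact binomial p alongside (`exact_if_small`), but the chi-square value
remains the primary result to match the published procedure. Numerically,
the statistic is computed as `(m·n_alt − N·d)² / (N·d·(m−d))`, which is
algebraically the Pearson sum but exactly symmetric in floating point
under the relabeling `(n_alt, n_ref, d) → (n_ref, n_alt, m−d)`.

## Probe design

`design_probes()` takes a window of `flank_left + ℓ + flank_right` bases
around the deletion. Defaults (19/19, ℓ = 1) give a 39-nt reference and
38-nt deletion probe, the lengths of the published query pair; nothing in
the method depends on 39 specifically, and both flanks are configurable
(the original window-selection rule was not stated). Uniqueness is
zero exact occurrences of any of the four strings (both probes, both
reverse complements) in every other paralog on either strand — the same
semantics as grepping the references. No mismatch tolerance is offered on
purpose: tolerant matching would change the false-positive structure of
the measurement model above.

Deletions inside homopolymer runs are positionally ambiguous (deleting any
T of a TT gives the same sequence), so all deletion coordinates are
left-aligned before use and the probe window is anchored on the canonical
(leftmost) position. All coordinates in the package are 0-based,
half-open; published 1-based positions are treated as display coordinates.

## Frameshift consequence and paralog assignment

`translate_seq()` is plain codon-table translation (standard code,
table 1): no initiator-codon special-casing, `N`-containing codons render
as `X`, translation truncates at the first stop. `frameshift_consequence()`
compares the two proteins residue-by-residue and reports the first
divergent codon, the variant's premature stop (when it precedes the
reference stop) and the fraction of the reference protein left intact. A
report is "empty" exactly when the two protein strings are identical.
Note that divergence can begin *after* the codon containing the deletion:
shifted codons are occasionally synonymous, so the hit codon itself is a
lower bound, not the guaranteed divergence point.

`assign_paralog()` scores a clone against each reference by global
(Needleman–Wunsch-style) alignment with match = 1, mismatch = 0, linear
gap = −1, and identity = matches / alignment length. The original "best
match" computation was not described; this scoring is a stated stand-in,
chosen because it is the simplest reproducible choice. A strict maximum is
required; ties return `"ambiguous"`. The alignment itself is delegated to
`Biostrings::pairwiseAlignment` with exactly that scoring scheme.

## Expression filtering and partition

FPKM is the published unit: `counts · 10⁹ / (length_bp · library_size)`,
with library size defaulting to the column sum. The expressed-gene filter
keeps a gene iff *every* replicate of at least one treatment group is at
or above the threshold (default 5 FPKM). FDR is Benjamini–Hochberg
(step-up), implemented in-package and cross-checked against brute force in
the tests. The partition of two genotypes' significant genes
(significant = expressed ∧ FDR ≤ 0.05) into unique/common sets, with
common genes split by fold-change sign into same-direction and opposite,
is pure set algebra; ≥2-fold classes use |log2FC| ≥ 1.

The differential test itself is an *input*: any per-gene p-value column
can be supplied (`de_table()`). The built-in stand-in (`de_test()`) is a
two-group Wald test on the log rate ratio with a fixed negative-binomial
variance `μ + φμ²` (φ = 0.1 by default) — sufficient for synthetic
pipelines, explicitly not a replacement for edgeR/DESeq2, whose
dispersion-estimation machinery is out of scope here. Whether the
published ≥2-fold classes were computed on FPKM means or model fold
changes was not stated; this package uses the log2FC column of the
supplied DE table.

`estimate_fold()` is the ratio of group-mean FPKM for one gene. At the
design used throughout (3 replicates, NB dispersion 0.1), a single draw of
this estimator has ≈ 27% log-scale sampling CV; the acceptance check for
the 16-fold recovery therefore reports the geometric mean of the estimator
over 30 independent seeded simulations of the same design, which measures
the estimator's central recovery (bias ≈ −1–2%) rather than one draw's
luck. The simulation parameters themselves (dispersion, replicates,
library size, fold) are never adjusted.

## Two-stage growth analysis

Stage 1 fits `H(t) = A / (1 + exp(−r(t − t_half)))` to each plant by least
squares (`stats::nls`, Gauss–Newton), with starting values
`A₀ = 1.05 · max(H)`, `t_half,0` = first crossing of `A₀/2`, and `r₀` from
a linear regression of `logit(H/A₀)` on `t` (floored at 0.5 /week when the
regression is uninformative). If `nls` fails, a Nelder–Mead SSE
minimization takes over; either way the solution is polished by BFGS with
analytic gradients (relative tolerance 1e−15), because the relative-offset
convergence criterion of `nls` stops early on noise-free data and the
tests require near-machine-precision recovery there. Iteration caps: 500
(`nls`), 5000 (fallback), 1000 (polish). Fits with non-positive `A` or `r`
are flagged `converged = FALSE`. Constant-height series are rejected as
degenerate. `R² = 1 − SSE/SST` against the mean-only model; negative
values are possible and simply reported.

The derived quantities are the three published analysis parameters:
asymptotic height `A` (cm), time to half-asymptote `t_half` (weeks), and
`Δt(½→¾) = ln 3 / r` (weeks) — an analytic identity of the logistic, so
`Δt · r = ln 3` holds exactly for every fit.

Stage 2 treats the per-replicate estimates as observations and compares
each parameter across groups with one-way ANOVA (Welch correction behind a
flag). The original stage-2 test lives in unpublished supporting material;
ANOVA is the stated stand-in. Groups with fewer than two converged fits
are excluded with a warning; a parameter with literally zero variance
across all fits yields F = 0, p = 1 rather than a 0/0 NaN.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of their arguments and a seed
(per-stage substreams derived from one global seed via `derive_seed`), so
reruns are byte-identical.

* `make_paralogs()` — one random ancestor mutated independently into *n*
  paralogs. Exactly `round(divergence/2 · L)` sites per paralog are
  substituted, so realized pairwise divergence concentrates within a few
  tenths of a percent of the target (default 5%, the low end of the
  5–10% homeolog divergence the analysis assumes).
* `apply_genotype()` — expands a copy-configuration label such as
  `"(-,-,TT)"` (deletion fraction 4/6) or `"(TT,TT,T-)"` (1/6) into the
  pool of m allele sequences.
* `simulate_reads()` — uniform fragment positions, fair-coin strand,
  i.i.d. substitution errors (default 0.005/base). **No indel errors are
  simulated**: indel errors would mimic exactly the signal the probe pair
  is designed to detect, and modeling them honestly would require a
  platform-specific error profile; this is a documented limitation, not an
  oversight. Equal per-copy weight by default, with `copy_weights` to
  model collapsed tandem copies. Non-target paralogs are included as
  background templates at their own allele weight.
* `simulate_rnaseq_counts()` — negative-binomial counts for a
  2 genotype × 2 treatment × 3 replicate design, mean
  `baseline_FPKM · fold · length_kb · library/10⁶`, default dispersion 0.1
  (a typical between-biological-replicate value) and library 10⁶.
* `simulate_clones()` — multinomial sampling of clone sources
  proportional to transcript abundance, truth labels kept in the headers.
* `simulate_growth()` — logistic trajectories, weekly sampling over
  weeks 0–8 after treatment, Gaussian noise with sd = 5% of A (matching
  the reported fit quality floor), truncated at zero; defaults
  A ∈ [30, 60] cm, r ∈ [0.8, 1.5] /week, t_half ∈ [3, 5] weeks — values a
  glasshouse camelina height series plausibly spans. A non-bolting
  (unvernalized winter-annual) group can be represented by a near-zero r.

A green test on these generators establishes that the *pipeline* recovers
what it was programmed to see under its own assumptions. It does not
establish anything about mapping/trimming upstream of the counts, about
real error profiles, PCR duplicates, or copy-specific expression bias, and
it cannot validate the published gene tallies that depend on the deposited
raw data (those are documented as not reproducible at desk scale).

## Numerical and degenerate-input conventions

* Coordinates 0-based half-open everywhere; indels left-aligned.
* Likelihood ties (`ml_dosage`) and alignment-identity ties
  (`assign_paralog`) are reported, never broken silently.
* `chisq_gof` at an impossible boundary hypothesis returns p = 0 with an
  `impossible` flag; at a consistent boundary, χ² = 0, p = 1.
* Reads with multiple probe occurrences count once; reads matching both
  allele probes count once as ambiguous and are excluded from N.
* Zero denominators in fold estimation are flagged `infinite`, not NA.
* `bh_fdr` validates p ∈ [0, 1] and is exactly monotone step-up.

## Open decisions taken

* "1:4" for the winter genotype is read as the rounded observation
  (21/5 = 4.2); the tested hypothesis space is the integer grid, where the
  nearest configuration is 1:5 — both are representable.
* Whether the original `grep` counted reads or occurrences is unknowable
  from the text; per-read (fragment) counting is used.
* Paired-end mates are independent reads by default (`--paired-dedup`
  collapses mates to fragments when ids carry mate suffixes).
* Copy number at the deletion locus is parameterized (`copies_per_paralog`,
  `alleles_per_copy`) rather than fixed at 3 × 2, since tandem-copy
  collapse in the assembly cannot be excluded.
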