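---
title: "Models and methods behind manoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind manoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

manoscreen analyses pooled barcode competition screens of the
mixed-all-nominated-in-one (MANO) type: cell clones, each stably expressing
one gene variant and tagged with a unique 10-bp DNA barcode, are co-cultured
in one dish so that every variant competes against every other under
identical conditions. Sequencing the barcode amplicon at different times, or
under drug versus vehicle, turns clone abundance into a quantitative
phenotype. This vignette documents the models the package implements, the
assumptions behind them, the tunable parameters, and the choices made where
the design was genuinely open. It states no empirical result beyond what the
package's own tests and `scripts/acceptance.R` compute.

## Barcode quantification

Each read is scanned for the fixed amplicon structure
`CTAGACTGCC<10 nt barcode>GGATCACTCT`. Design choices:

* **Flanks are matched exactly.** The 20 flank bases are plasmid-encoded and
  invariant; tolerating mismatches there would mostly admit noise. Mismatch
  tolerance (`max_mismatch`, 0 or 1) applies to the barcode alone.
* **Single-mismatch rescue** assigns an unlisted extracted 10-mer to a
  whitelist barcode iff exactly one whitelist entry lies within Hamming
  distance 1. When the whitelist has minimum pairwise distance 3 or more
  (which `generate_barcodes()` guarantees by construction), a
  single-substitution error can never be rescued to the wrong clone: the
  mutated barcode is at distance 1 from its origin and at distance 2 or more
  from every other entry.
* **Orientation** defaults to `both`: the library orientation after indexing
  is not fixed, so the reverse complement is searched when the forward strand
  has no hit. Under `forward` only the given sequence is scanned.
* **Leftmost hit wins** when a read contains several pattern occurrences;
  surplus occurrences are tallied in a `multi_hit` diagnostic rather than
  counted.
* **Mates are deduplicated by read id**: the same barcode observed on both
  mates of a pair counts once, with the duplicate tallied under a
  `duplicate_mate` reason so that matched + unmatched always equals the
  number of input reads.
* **Base qualities are ignored.** The assay counts clones; a miscalled base
  either breaks the exact flank (read discarded) or lands in the barcode
  (handled by the rescue rule), so a quality filter adds little and is not
  applied.

## Growth and drug normalization

Counts from a pooled screen are compositional: only within-sample fractions
carry information, and any per-sample scaling (sequencing depth) must cancel.
All normalizations therefore start from `count / matched total` per sample.

*Relative proliferation* follows the day-3-reference design: cells are mixed
on day 0, the day-3 pool is the reference, and the endpoint (default day 18)
is expressed per clone as `fraction(endpoint) / fraction(day 3)`, averaging
fractions across replicates per day first, then taking the ratio, then
averaging the (typically three) clones of a variant. Variant values are
reported as log2 ratios against the same gene's wild type, where the common
normalizing factors cancel exactly; on noise-free exponential growth the
log2 value equals growth-rate difference x elapsed days to machine
precision, which the tests assert.

A 0.5-read pseudocount is added to *zero counts only* when fractions are
formed. Adding it unconditionally would bias every fraction and break the
exactness above; adding it to zeros keeps log ratios finite in sparse
samples while leaving fully observed samples untouched. Clones with zero
reference-day reads are excluded with a warning (their ratio is undefined,
not zero), and a variant with no usable clone is reported as missing.

*Significance* of a growth difference is a two-sided paired t-test on log2
relative proliferation. The pairing unit is the replicate experiment: the
three same-variant clones are internal replicates and are averaged within a
replicate first. Pairing by clone instead would treat barcodes as the
experimental unit, but clones share an infection and a dish within a
replicate, so the replicate is the independent unit. Raw p-values at
alpha = 0.05 drive the calls; a Benjamini-Hochberg column is available in
`compare_ic50_all()` style outputs but is not used for the primary calls.
With fewer than three complete pairs the p-value is reported missing with a
reason. Degenerate pairings (zero variance of the paired differences) return
p = 1 when the mean difference is zero and p = 0 otherwise.

*Relative viability* under drug uses vehicle (DMSO) pools of the same batch
as reference: per clone, fraction under drug (averaged over triplicates)
divided by fraction under vehicle. This raw ratio is deliberately
compositional — a resistant clone in a dying pool shows viability above 1 —
and equals `s_v(x) / S(x)`, the variant's survival divided by the
abundance-weighted pool-average survival at that dose.

## From pooled viabilities to IC50: the control-reference correction

Because the raw drug/vehicle ratio carries the pool-average survival `S(x)`
in its denominator, feeding it directly to a curve fitter inflates apparent
IC50s whenever a substantial part of the pool responds to the drug; the
distortion is dose-dependent, so it cannot be absorbed by the free top
asymptote. `viability_from_counts()` therefore divides each variant's ratio
by the mean ratio of the drug-insensitive negative-control clones at the
same dose (default `reference = "negative_control"`). Since those clones
share the same `1 / S(x)` factor, the division cancels it exactly and
restores absolute survival, up to sampling noise. `reference = "none"`
keeps the raw ratios for users who want the uncorrected, purely
compositional read-out.

## The TAS ordered-regression random-effects model

Focus-formation and low-serum proliferation assays yield ordinal scores 1-4
per variant, assay and experimental batch. The transformation activity
score (TAS) integrates them through a latent-variable model: per
experiment,

$$\Upsilon = \beta_{batch} + \tau_{batch}\, f_{variant} + \varepsilon,$$

with the observed score obtained by thresholding $\Upsilon$ at
$T_{1\text{-}2} < T_{2\text{-}3} < T_{3\text{-}4}$. $\beta$ is a batch
location shift, $\tau > 0$ a batch scale (how strongly that batch's assay
separates variants), and $f$ the variant's transforming activity.

Identification and priors. The latent scale is only defined relative to the
error: we fix $\varepsilon$ as standard logistic (scale 1), making the model
an ordered logistic regression and removing the scale trade-off between
$\varepsilon$, $\tau$ and the thresholds. The remaining soft
non-identifiabilities (location trade between $\beta$ and thresholds, scale
trade between $\tau$ and $f$) are resolved by weakly informative priors:
$f \sim N(0,1)$ (unit variant-effect scale), $\tau$ half-normal(1),
$\beta \sim N(0,5^2)$, thresholds an ordered $N(0,5^2)$ vector. Fully flat
priors would be improper here.

Fitting uses MCMC (JAGS), by default 4 chains, 1500 warmup and 2000 retained
iterations per chain; ordering of the thresholds holds in every draw by
construction (`sort` parameterisation), and split-chain R-hat and effective
sample sizes are reported. Any subset of $\beta$, $\tau$ and the thresholds
can be clamped at known values via `fixed =`, which is how the test suite
compares the sampler against a brute-force grid posterior on a two-variant
toy.

Summarisation (`compute_tas()`) draws 500 joint parameter sets from the
trace and forms, per draw, the batch-averaged latent activity
$\Upsilon_v = \frac{1}{B}\sum_b (\beta_b + \tau_b f_v)$. Two deliberate
choices: the experiment-level error $\varepsilon$ is *excluded* (it is assay
noise, not variant signal), and batches enter with equal weight. The 500
values are averaged and the mean is discretised with the posterior-mean
thresholds to give the 1-4 TAS class; a value exactly at a threshold takes
the higher class (the threshold inequalities are read left to right, so the
boundary belongs to the larger score).

## Oncogenicity classification

Five classes from two pieces of evidence, both relative to the same gene's
wild type: TAS comparison (strict; the discrete class by default, the
continuous latent mean optionally) and growth significance
(sign of the log2 difference plus p < alpha). Higher TAS with significantly
faster growth is `oncogenic`; higher TAS without it `likely_oncogenic`;
lower TAS with significantly slower growth `LoF`; lower TAS without it
`likely_LoF`; everything else — including equal TAS, and the literal corner
case of significantly faster growth with *lower* TAS — is `neutral`. Missing
evidence yields `not_evaluable`, never a silent `neutral`. The mapping is
total and monotone in TAS, which the tests verify by exhaustive enumeration
against a committed truth table.

## Dose-response fitting

Viability curves are fit with the three-parameter log-logistic
$f(x) = d / (1 + \exp(b(\ln x - e)))$, lower asymptote fixed at 0 (the
response without drug is normalised out), by ordinary least squares
(Levenberg-Marquardt). "Robust = mean" in the conventional setting of this
model family corresponds to plain least squares, which is what is
implemented. Starting values come from a deterministic self-starter
(`d` = maximum observed viability, `e` = log of the dose nearest half-max,
`b` from a linearised logit regression), with a small restart grid on
failure. The IC50 is the curve's inflection point `exp(e)`, where viability
equals `d/2`.

Censoring: a fit is censored when no half-maximal inhibition is observed
within the tested range (viability at the top dose above half that at the
lowest dose) or when the fitted location falls outside the dose range.
Censored fits report no finite IC50 — values outside the tested range are
never extrapolated — and carry the censoring bound (the top dose) for
display and imputation. Viabilities are not clipped to [0, 1]; negative
plate-reader artifacts are retained with a warning below -0.1.

IC50s of two uncensored fits are compared by a two-sided z-test on the
difference of the log-IC50 locations with the fit standard errors; pairwise
tables add a BH-adjusted column while the primary calls use raw p-values.

## Drug-sensitivity clustering

IC50 matrices (variants x drugs) are log10-transformed and then
Z-standardised per drug column (sample SD). The transform order is
deliberate: standardising first and log-transforming afterwards is
impossible for the negative half of any Z-scored column, so the only
coherent reading of "Euclidean distance of log-transformed Z-score" is log
first, Z second. Censored entries enter at their censoring bound and are
flagged (a drop policy is available). Clustering is agglomerative UPGMA
(unweighted group-average linkage) on Euclidean distances, with
non-decreasing merge heights guaranteed; per-drug standardisation is the
default axis, switchable to per-variant. Trees export as Newick plus a merge
table, and `cutree` provides the k-cluster partition (k = 4 is the
conventional cut for FGFR-inhibitor panels).

## The synthetic-data generator

`screen_scenario()` fixes a desk-scale ground truth mirroring the real
experimental design: three barcoded clones per variant, triplicate samples,
a day-3 reference and day-18 endpoint, a 5-day drug exposure on an 8-point
log-spaced dose grid from 0.1 nM to 10 uM, and 1e5 reads per sample.
Clone abundances grow exponentially at variant-specific rates
(log2 doublings/day relative to wild type: transforming mutants +0.2 to
+0.5, loss-of-function -0.2 to -0.1, a GFP control at -0.2 emulating growth
arrest in low serum, a RAS-like positive control at +0.5); drug-sensitive
variants carry true IC50s log-spaced from 1 nM to 1 uM with Hill slope 1,
while wild types, controls and a gatekeeper-like mutant are insensitive.
Reads are multinomial at the stated depth with optional per-base
substitution errors (substitution-only: an indel can never reproduce the
exact flank + 10-mer structure, so it only ever removes a read).
`noise = "none"` emits exact expected counts — the limit in which the
normalization identities hold to machine precision.

For the TAS recovery studies, `tas_recovery_scenario()` freezes 50 variants
x 8 batches with one score per variant, batch and assay: true
$f \sim N(0,1)$ (matching the model prior, so credible-interval coverage is
a meaningful calibration check), batch shifts $\beta \sim N(0, 0.5)$, batch
scales $\tau \sim |N(2, 0.3)|$ and thresholds (-1.5, 0, 1.5). The scale of 2
was chosen so that simulated scores use the full 1-4 rubric with substantial
mass in the extreme classes, the way real transformation assays separate
clearly neutral from strongly transforming variants; smaller scales leave
most scores in the middle classes, which no published score table resembles.

What the generator does *not* emulate: PCR duplicates and amplification
jackpots, index hopping and chimeric reads, density-dependent growth or
clone-clone interactions, and batch effects in the sequencing itself.
Passing closed-loop tests therefore demonstrates correctness of the
estimators under the model's own assumptions, not robustness to those
artefacts in real libraries.

## Problem sizes, runtimes and numerical choices

The default study sizes are desk-scale by design: about 30 variants x 3
clones for the screens, 1e5 reads per sample, 50 variants x 8 batches for
the TAS recovery study. The full MCMC settings (4 chains, 1500/2000) are
used for the headline recovery fit; replicate calibration studies (20
repeats for interval coverage) use a reduced 2-chain 500/500 setting, which
leaves posterior means essentially unchanged on this design and keeps the
whole suite in the minutes range. All randomness descends from one root
seed through `derive_seed()` (an FNV-1a hash of the stage name folded into
the 31-bit integer range), so every stage is reproducible in isolation and
a pipeline rerun with the same configuration is bit-identical.

Known limitations: the paired t-test with n = 3 replicates has limited
power for small effects; TAS classes near a threshold are sensitive to the
posterior-mean threshold estimate; IC50s near the edges of the dose grid
are estimated with strong asymmetry before censoring kicks in; and the
control-reference viability correction requires at least one genuinely
drug-insensitive clone set in the pool.
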