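# manoscreen

Analysis of pooled barcode competition screens of the
mixed-all-nominated-in-one (MANO) type, as used to annotate the
transforming activity and tyrosine-kinase-inhibitor sensitivity of receptor
variants (e.g. FGFR1-4 mutants). In a MANO screen, cell clones each stably
expressing one variant and tagged with a unique 10-bp DNA barcode are
pooled into a single dish; sequencing the barcode amplicon over time, or
under drug versus vehicle, converts clone abundance into a quantitative
phenotype for every variant simultaneously.

The package implements the complete computational pipeline:

* **Barcode quantification** — extraction of 10-nt barcodes between the
  fixed flanks `CTAGACTGCC…GGATCACTCT` from FASTQ reads, with optional
  single-mismatch rescue against the whitelist, and assembly of a
  clone × sample count matrix with full per-sample accounting.
* **MANO normalization** — relative proliferation against the day-3
  reference pool (log2 vs wild type, paired t-tests vs WT and GFP) and
  relative viability against DMSO vehicle pools.
* **TAS** — a Bayesian ordered-regression random-effects model,

  Υ = β_batch + τ_batch · f_variant + ε,   score = k ⇔ T_{k−1,k} < Υ < T_{k,k+1},

  fit by MCMC, integrating ordinal focus-formation and low-serum
  proliferation scores (1–4) across batches into a transformation activity
  score per variant (500 posterior draws of the batch-averaged Υ,
  discretised at the posterior-mean thresholds).
* **Oncogenicity classification** — the five-class rule set
  (oncogenic / likely oncogenic / neutral / likely LoF / LoF) combining the
  TAS comparison with growth significance against the same gene's wild type.
* **Dose-response** — three-parameter log-logistic fits
  f(x) = d / (1 + exp(b(ln x − e))) with the lower asymptote at 0,
  IC50 = exp(e) at the inflection point, censoring outside the tested dose
  range, and z-tests on log-IC50 differences between variants.
* **Clustering** — log10 + per-drug Z transform of the IC50 matrix and
  UPGMA (group-average) clustering with Euclidean distances, Newick export.
* **Synthetic data** — a generator for every input the pipeline consumes
  (reads, count matrices, assay scores, viability tables) with known ground
  truth, so the whole pipeline is testable closed-loop.

Functions are tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` ggplot2 graphics.

## Worked example

```r
library(manoscreen)
library(dplyr)

# a synthetic screen with known ground truth: ~30 variants x 3 clones,
# day-3 reference, day-18 endpoint, triplicates, 1e5 reads per sample
scenario <- screen_scenario(seed = 42)
growth   <- simulate_growth_screen(scenario)
profile  <- relative_proliferation(growth$counts)
sig      <- growth_significance(profile, comparator = "wild_type")

profile |>
  select(variant_id, r, log2_vs_wt) |>
  left_join(select(sig, variant_id, p, activating), by = "variant_id") |>
  arrange(desc(log2_vs_wt)) |>
  head(5)
#>   variant_id     r log2_vs_wt        p activating
#> 1 FGFR1_M17   2.21       7.56 0.000229 TRUE
#> 2 FGFR1_M13   1.92       7.35 0.000220 TRUE
#> 3 FGFR1_M1    1.83       7.28 0.000347 TRUE
#> 4 FGFR4_M16   2.00       7.14 0.00217  TRUE
#> 5 FGFR2_M2    1.98       7.09 0.000163 TRUE
```

`r` is the variant's day-18/day-3 abundance ratio, `log2_vs_wt` the log2
proliferation advantage over the same gene's wild type (a variant gaining
~0.5 doublings/day over 15 days shows ≈ 7.5), and `activating` flags
significantly faster growth (paired t-test, p < 0.05).

```r
# TAS from simulated ordinal assay scores (20 variants, 4 batches)
scores <- tas_recovery_scenario(n_variants = 20, n_batches = 4, seed = 42)
fit    <- fit_tas(scores$scores, chains = 2, warmup = 500, samples = 500, seed = 42)
tas    <- compute_tas(fit, n_draws = 500, seed = 42)
tas |> arrange(desc(upsilon_mean)) |> head(3)
#>   variant_id upsilon_mean tas_class f_mean f_ci_low f_ci_high rhat_max
#> 1 V12                1.67         4   1.84    0.907      2.94     1.27
#> 2 V07                1.07         4   1.50    0.605      2.47     1.27
#> 3 V09                1.03         4   1.46    0.687      2.37     1.27
cor(tas$f_mean, scores$f[tas$variant_id], method = "spearman")
#> 0.974
```

`upsilon_mean` is the batch-averaged latent activity (mean of 500 posterior
draws), `tas_class` its 1–4 discretisation, and `f_mean` the posterior mean
variant effect with its 90% credible interval — here recovering the
programmed activities with rank correlation 0.97.

```r
# pooled drug screen -> per-variant IC50
drug <- simulate_drug_screen(scenario)
fits <- drug_relative_viability(drug$counts) |>
  viability_from_counts() |>          # cancels the pool-average survival
  fit_dose_response()
inner_join(fits, drug$truth, by = c("variant_id", "drug")) |>
  filter(!is.na(true_ic50_nM), converged, !censored) |>
  select(variant_id, ic50_nM, true_ic50_nM) |> arrange(ic50_nM) |> head(4)
#>   variant_id ic50_nM true_ic50_nM
#> 1 FGFR1_M1     0.749         1
#> 2 FGFR2_M2     1.20          1.50
#> 3 FGFR3_M3     1.83          2.25
#> 4 FGFR4_M4     2.88          3.38
```

Insensitive clones (wild types, the GFP control, a gatekeeper-like
resistant mutant) come back censored — "IC50 beyond the top dose" — rather
than extrapolated. `run_mano_pipeline()` chains all stages (counts →
growth/viability → TAS → classification → IC50 → clustering) with one root
seed and a config-hash provenance report.

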