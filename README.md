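# chromclip

Tools for asking how an abundant lncRNA shapes the enhancer targeting
of a chromatin remodeler. The motivating system is the HERVH
endogenous-retrovirus transcripts of human pluripotent cells and the
remodeler CHD7: PAR-CLIP identifies which RNAs the remodeler touches,
CUT&RUN-style densities measure where it sits on chromatin and what
happens to enhancer acetylation when the RNA or the protein is
removed, and in-vitro titrations quantify the RNA–protein affinity and
its inhibition of nucleosome remodeling. chromclip implements the
statistics connecting those layers, exercised end to end on a
synthetic genome with planted truth.

The package is tidyverse-shaped: functions take data frames (or a
small `signal_matrix` container) and return tibbles, fitted curves
have `tidy()` / `glance()` / `autoplot()` methods, and everything
chains with the pipe.

## What it computes

* **Stringent PAR-CLIP peaks** — `stringent_peak_set()` keeps
  replicate-1 peaks that are reproduced in replicate 2, carry T→C
  conversion evidence (the sequencing signature of a genuine
  crosslink), and pass RPKM > 10; `classify_peak_context()` and
  `bound_fraction_by_expression()` provide the descriptive summaries.
* **Repeat-family enrichment** — `repeat_family_enrichment()`
  compares a peak set's overlap with each RepeatMasker family against
  matched random genomic loci (same count, same length multiset),
  reporting fold, Gaussian Z with one-sided P, and a plus-one-smoothed
  empirical P.
* **Differential enhancer signal and DEGs** — `quantile_normalize()`
  within antibody groups, a negative-binomial exact-style test
  (`differential_regions()`, `call_degs()`) with Benjamini–Hochberg
  FDR and the 1.5-fold / 2-fold direction rules, plus
  `specificity_filter()`, `bound_region_fraction()`,
  `signal_correlation()` and `region_metaprofile()`.
* **Proximity permutation test** — `proximity_enrichment_test()`
  counts distinct differentially expressed genes within 100 kb of a
  set of enhancers and compares against 1,000 length-preserving
  genomic shuffles: the Gaussian Z-score / P-value construction
  `z = (obs − mean_null)/sd_null`.
* **Binding and remodeling curves** — `fit_hill()` fits the specific
  binding law with Hill slope `y = Bmax·xʰ/(Kdʰ + xʰ)` (so the fitted
  response at `x = Kd` is `Bmax/2`); `fit_inhibition()` fits the
  complementary decreasing form for restriction-enzyme-accessibility
  remodeling assays, with `remodeling_efficiency()` expressing
  digestion as percent of the no-RNA control.
* **Synthetic data** — `simulate_genome()`, `simulate_parclip()`,
  `simulate_signal_matrix()`, `simulate_proximity()` and
  `simulate_binding_curve()` generate all inputs with known planted
  effects; `run_pipeline()` chains every stage deterministically from
  one seed.

## Worked example

Plant a fivefold HERVH enrichment in a synthetic PAR-CLIP peak set and
test every repeat family against 500 draws of matched random loci:

```r
library(chromclip)

ann  <- simulate_genome(seed = 1)
clip <- simulate_parclip(ann, target_family = "HERVH",
                         enrichment_factor = 5, n_peaks = 1000,
                         seed = 23)
enr  <- repeat_family_enrichment(clip$peaks, ann$repeats, ann$genome,
                                 n_iter = 500, seed = 24)
dplyr::select(enr, family, observed, null_mean, fold, z, p_gauss, p_emp)
#> # A tibble: 4 × 7
#>   family observed null_mean  fold      z  p_gauss   p_emp
#>   <chr>     <dbl>     <dbl> <dbl>  <dbl>    <dbl>   <dbl>
#> 1 HERVH       131      26.4 4.96  20.4   5.30e-93 0.00200
#> 2 HERVK        22      24.0 0.917 -0.395 6.53e- 1 0.699
#> 3 L1          22       26.2 0.839 -0.847 8.01e- 1 0.820
#> 4 SINE        27       24.9 1.09   0.436 3.32e- 1 0.363
```

131 of 1,000 peaks overlap HERVH copies where random placement
predicts about 26 — a 4.96-fold enrichment recovering the planted
fivefold effect, with an astronomically small Gaussian tail and the
smallest empirical P available at 500 iterations (1/501). The other
families sit at fold ≈ 1 with unremarkable P-values.

Fitting a noisy titration (true Kd 7.7 nM, Hill slope 1.5, noise SD
0.03):

```r
sim <- simulate_binding_curve(Bmax = 1, Kd = 7.7, h = 1.5,
                              noise_sd = 0.03, seed = 4)
fit <- fit_hill(sim$curve)
fit
#> <hill_fit: binding> converged
#>   Bmax  0.972691 (se 0.0163)
#>   Kd    6.79931 (se 0.309)
#>   h     1.6657 (se 0.105)
#>   rss 0.002229 on 8 points
```

`glance(fit)` returns the same as a one-row tibble and
`autoplot(fit)` draws the curve over the points.

A full synthetic run — all five analysis stages, deterministic per
seed, with an md5 manifest:

```r
manifest <- run_pipeline(run_config(outdir = "run1", seed = 42))
```

A thin command-line wrapper lives at
`inst/scripts/chromclip-pipeline.R`.

## Vignette

`vignettes/chromclip-methods.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale,
what the synthetic generator does and does not emulate, and the
numerical choices (pseudocounts, dispersion bias correction,
multi-start fitting, tie handling).
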