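---
title: "chromclip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromclip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromclip)
```

chromclip implements the computational chain used to connect an
abundant lncRNA (the HERVH endogenous-retrovirus family) to the
enhancer targeting of a chromatin remodeler (CHD7): stringent PAR-CLIP
peak selection, repeat-family enrichment against random genomic loci,
differential CUT&RUN-style signal at enhancers, a genomic-shuffle test
for enhancer–DEG proximity, and Hill-equation quantification of
binding and remodeling-inhibition titrations. Every stage runs on a
synthetic genome with planted truth, so the whole chain is testable
without any sequencing data. This vignette explains each model, the
parameters that matter, and the design decisions taken where the
choice was genuinely open.

## Coordinate model

All intervals are 0-based, half-open BED coordinates on a named-
chromosome genome (`genome_layout()`); 1-based inputs (RepeatMasker
`.out`) are converted at the reader boundary. Overlap and distance
ignore strand; strand is kept only for metaprofile orientation and TSS
definition. Distance between intervals on different chromosomes is an
infinite sentinel rather than a large finite number, so "closest gene"
can never cross a chromosome. The interval core is vectorized base R;
the test suite checks it against all-pairs brute force and against
GenomicRanges on randomized instances.

## Stringent PAR-CLIP peaks

PAR-CLIP leaves T→C transitions in reads at genuine RNA–protein
contact sites. A candidate peak from replicate 1 enters the stringent
set iff it

1. overlaps a replicate-2 peak by at least 1 bp (replicate
   consistency),
2. overlaps a conversion-supported cluster (crosslink evidence; every
   cluster must carry at least one conversion), and
3. exceeds an RPKM cutoff (default 10) — RPKM is
   `count / ((length/1000) · (library/10^6))`, averaged over
   replicates, each with its own library size.

Replicate consistency is read as one-directional ≥1-bp overlap with
replicate-1 coordinates reported; this is the simplest reading of
"consistently called in two replicates" and is isolated in one
function so it can be revisited. Peak context uses the precedence
coding > lincRNA > intergenic, because a single-label summary needs a
tie-break and overlap with a coding gene is the most specific claim.

The windowed peak caller (`call_enriched_windows()`) is a
self-contained stand-in, not a reimplementation of any published
caller: fixed non-overlapping windows, a minimum IP/input fold, and an
exact conditional test. We use the conditional-binomial form (IP count
given the window total, with success probability set by the library
totals) rather than a Poisson tail at the observed input expectation:
the input track is itself noisy, and treating it as a known mean is
anti-conservative at realistic counts, which would break the
calibration property the suite enforces (false calls at most `alpha`
under exchangeable IP/input). When the scaled input is below one read
it is floored at a pseudo-expectation of one read, and density is
IP-only (input enters through the test), matching a peak filter by
absolute read density.

## Repeat-family enrichment

For each repeat family, the observed number of peaks overlapping the
family is compared with the counts from `n_iter` draws (default
1,000) of the same number of random genomic loci with the same length
multiset. Placement is uniform over valid start positions, with
chromosomes weighted by their number of valid starts; a
`same_chromosome` mode is exposed because published descriptions of
such shuffles rarely state whether chromosome of origin is preserved.
Random loci may overlap each other — forbidding that would bias the
null on a small genome. Family labels are taken verbatim from the
repeat table; subfamilies are never merged.

Each test reports the fold over the null mean, the Gaussian Z-score
with its one-sided upper-tail probability (the depletion tail is
reported separately), a plus-one-smoothed empirical probability
`(1 + #{null ≥ obs}) / (n_iter + 1)` that can never be zero, and the
null skewness as a diagnostic. The empirical value is reported
alongside the Gaussian one deliberately: with a skewed null at small
`n_iter` the Gaussian tail is unreliable, and the skewness diagnostic
says when to prefer the empirical value.

## Differential signal and DEGs

Region-by-sample densities live in a `signal_matrix` with an explicit
raw/normalized provenance flag, so the two layers cannot be conflated.
Quantile normalization (via `limma::normalizeQuantiles`, ties
averaged) is applied within groups of samples sharing an antibody;
groups of one sample are left unchanged with a warning.

The differential test is a deliberate stand-in for the established
count-model packages, because the substance here is the threshold and
filter logic, and a small self-contained test can be verified by
simulation end to end:

* densities are rounded to counts;
* a common negative-binomial dispersion is estimated per group by the
  median method of moments, `median(max(0, (s² − m)/m²))`, rescaled by
  `qchisq(0.5, r − 1)/(r − 1)` because the median of a sample variance
  at r = 4 replicates sits well below its expectation — without this
  correction the test is anti-conservative at the 1% level;
* each region's replicate sums are compared by the conditional
  distribution given the region total (binomial in the Poisson limit),
  with the exact-test convention of summing all conditional
  probabilities no larger than the observed one;
* Benjamini–Hochberg correction gives the FDR.

The `up`/`down` label requires all three of: FDR below the cutoff,
|log2 fold change| above the cutoff (1.5-fold for enhancer signal,
2-fold for DEGs, both at FDR < 0.01), and agreement of per-replicate
fold-change signs with replicates paired by index — the package's
rendering of "consistently altered in four replicates". A pseudocount
of 0.25 (RPKM or counts) appears in every fold change whose
denominator can be zero; the value is small, fixed, and recorded in
the output. The suite checks type-I error within a factor of two of
nominal at α = 0.05 and 0.01, mean false-discovery proportion under
the null, and ≥80% power for fourfold effects at mean 100, dispersion
0.1, 4 vs 4 replicates. An edgeR exact test on the same counts serves
as an independent cross-check of the p-value ranking in one test; it
is never the implementation.

The specificity filter retains regions with mean wild-type RPKM above
1 that lose at least twofold of their signal in the depletion control
(`mean(WT) / (mean(KO) + 0.25) > 2`); the knockout is read as the
negative control in which true peaks should vanish.

## Proximity of DEGs to affected enhancers

The headline resampling statistic asks whether differentially
expressed genes cluster within a window (default 100 kb) of the
enhancers whose acetylation changed. The counting unit is distinct
genes, never gene–enhancer pairs; the distance anchor is the gene
interval (a TSS anchor is available behind a flag). Enhancer positions
are shuffled `n_iter` times (default 1,000) with lengths preserved,
and the observed count is summarized exactly as in the repeat module
(fold, Gaussian Z, one-sided upper-tail P, empirical P, skewness).
Shuffling is genome-wide by default with a `same_chromosome` switch;
no assembly-gap exclusion is applied on the synthetic genome, but the
sampler accepts an exclusion list.

Two practical notes established by the calibration suite. First, the
Gaussian tail is trustworthy when the null count aggregates many
quasi-independent enhancer windows away from its floor and ceiling;
with only a handful of enhancers the null is visibly skewed and the
empirical probability should be preferred — this is why the
calibration study uses 30 enhancers with 20-kb windows and 100 gene
labels on the toy genome, a regime chosen so the null count (mean
around half the labels) is comfortably interior. Second, a fixed
annotation carries its own proximity geometry: under a true uniform
null the feature positions must be redrawn per dataset, otherwise
every replicate inherits the same genome-level offset.

## Binding curves

EMSA titrations are quantified as `fraction_bound = bound/(bound +
free)` per lane and fitted to the specific-binding law with Hill
slope, `y = Bmax·xʰ/(Kdʰ + xʰ)`; by construction the fitted response
at `x = Kd` is exactly `Bmax/2`. Remodeling inhibition uses the
complementary decreasing form `y = 100 − Bmax·xʰ/(Kdʰ + xʰ)` on
percent-of-control efficiencies, with 100% defined by the no-RNA
control; values above 100% are allowed and flagged. Concentrations are
nM throughout and must be strictly positive (readers reject zeros
rather than log-transforming them).

Fitting is Levenberg–Marquardt least squares from a fixed start grid —
`Kd` at the concentration quartiles, slope in {0.5, 1, 2}, plateau at
the response span — because the objective is multimodal at high Hill
slopes; the best start by residual sum of squares wins and the
convergence flag records failure of all starts. Points are unweighted
(no error model is assumed) unless a weight column is given. Standard
errors come from the curvature at the optimum; when replicate curves
exist, both the fit SE and the across-replicate spread are worth
reporting, since published "±" values rarely say which they are. A
flat no-inhibition curve resolves to a plateau near zero with a wide
standard error rather than a spurious small `Kd`; the suite checks
this degenerate case explicitly, alongside exact recovery on clean
curves, 10%-median `Kd` recovery at noise SD 0.03 with 8 log-spaced
points, and the scale equivariance `Kd(c·x) = c·Kd(x)`.

## The synthetic genome and what passing tests mean

`simulate_genome()` builds the default study substrate: 2 chromosomes
of 1 Mb, 200 non-overlapping repeats from 4 families with log-normal
lengths, 300 enhancers, 400 genes with biotypes and strands — sized so
the full pipeline completes in well under two minutes on one CPU while
keeping the interval geometry non-trivial. The other generators plant
known truth on top: a repeat-family overlap probability equal to a
chosen multiple of the measured background rate (rejection-free
mixture placement), negative-binomial count matrices with planted
folds and ±20% library jitter, DEG labels with a planted proximity
fold, Binomial(reads, 0.1) conversion counts, and Hill curves with
Gaussian noise. Each generator is a pure function of its seed, and
planted truth is serialized separately from the emitted data files.

Two planting subtleties are worth knowing. Forcing the target family's
overlap rate up necessarily diverts peaks from everywhere else, so
non-target families sit slightly below fold 1 (about 0.9 at a planted
fivefold target on the default genome) — the recovery study therefore
averages folds over repeated datasets rather than judging a single
draw. And with 100-kb windows on a 2-Mb genome, a handful of enhancers
already covers a third of the genome, so proximity planting uses small
enhancer subsets (two in the pipeline) to leave geometric room for a
threefold enrichment.

What passing tests do not show: the generators place features
uniformly and independently, so nothing here validates behavior under
clustered gene models, mappability structure, assembly gaps,
copy-number variation, or correlated replicate noise — all properties
of real genomes that genome-scale analyses must confront. The
planted effects are also homogeneous (one fold per region), unlike
biological effect-size distributions.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → stringent peaks → repeat
enrichment → normalization and differential calls → proximity test →
curve fit, with every stage default at the analysis-defining values
(RPKM > 10; specificity >1 RPKM and >2-fold over knockout; 1.5-fold /
FDR 0.01 enhancers; 2-fold / FDR 0.01 DEGs; 100-kb window; 1,000
iterations). All randomness flows from one master seed through named
substreams, so stages re-run in isolation reproduce the full-run
results, and two runs from one configuration are byte-identical — the
manifest records an md5 digest per artifact and the suite asserts
digest equality across reruns. Warnings with scientific content
(clipped metaprofile windows, singleton normalization groups,
unconverged fits) are surfaced, not swallowed.

## Known limitations

* The differential test models a single two-group contrast with a
  common dispersion: no GLM designs, batch covariates, tagwise
  shrinkage, or composition normalization (TMM).
* The proximity test associates enhancers and genes by linear distance
  only; no contact-map or TAD awareness.
* The peak caller is windowed and merge-adjacent; it does not model
  read-level crosslink geometry and is not a substitute for the
  dedicated PAR-CLIP callers when real reads are available.
* Enrichment backgrounds assume uniform mappability.
* Hill fits are equilibrium-only; no kinetic or competition
  thermodynamics beyond the quantified bands.
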