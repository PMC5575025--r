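---
title: "Negative-control regression decontamination: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-control regression decontamination: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocuscrub)
```

## The problem

Low-biomass specimens such as ocular-surface swabs yield so little microbial
DNA that contaminant molecules from extraction kits, PCR reagents and
handling can contribute a substantial — sometimes dominant — fraction of the
sequenced reads. Simple exclusion rules ("discard every OTU seen in a
negative control") fail here, because genuinely resident taxa also appear at
low levels in blank swabs: the most abundant members of the dataset
typically show up, faintly, in the controls. What distinguishes a
contaminant is not presence in a control but *predictability from* the
control.

## The contamination model

The filter rests on the reagent model of contamination: each contaminant OTU
enters every library as an approximately fixed absolute amount determined by
its concentration in the shared reagents, independent of how much target DNA
the specimen contributed. Two consequences follow.

1. In a low-biomass control, contaminants dominate, so a control measures
   the contaminant input profile.
2. After relative abundances are weighted by a per-sample biomass surrogate,
   a contaminant's weighted abundance is approximately its absolute input —
   the *same* quantity in subjects and controls. On the log scale,
   contaminant OTUs therefore fall on a line of slope one through the
   origin when subject means are regressed on control means, while truly
   resident OTUs sit far above it (their subject abundance reflects real
   biomass that the control lacks).

The biomass surrogate is the luminosity of the amplicon's gel band.
`relative_luminosity()` scales each band by the brightest one
(`w = L / L_max`), so the highest-biomass sample keeps weight 1 and faint
control bands are shrunk accordingly. The complementary form
`(L_max - L) / L_max` is available as `luminosity_mode = "literal"` for
comparison; it assigns the brightest band weight zero, which annihilates the
strongest sample and contradicts the quantity's role as a biomass surrogate,
so it is not the default.

## The nine filtering steps

`run_contaminant_pipeline()` executes, in order:

* **(a)** remove samples with fewer than 10,000 reads (strictly less-than;
  a sample with exactly 10,000 reads stays);
* **(b)** convert counts to within-sample relative abundances;
* **(c)** multiply by the relative band luminosity;
* **(d)** average the weighted abundances per OTU within each sample type
  (subject, blank swab, water), zeros included;
* **(e)** remove OTUs whose share of the summed subject-sample means is
  strictly below `rare_fraction` (default 1e-6, i.e. 0.0001%). The share
  basis is subject samples only, so abundance driven by controls cannot
  rescue an OTU;
* **(f, g)** ordinary least squares of `log(subject mean + eps)` on
  `log(blank mean + eps)`; OTUs whose residual exceeds
  `se_multiplier * SE` — equivalently whose subject abundance exceeds the
  contamination prediction by more than a factor `exp(se_multiplier * SE)` —
  are flagged as truly present. `SE` is the residual standard error
  `sqrt(RSS / (n - 2))` and the default multiplier is 5;
* **(h)** the blank-swab regression is repeated;
* **(i)** a final pass uses the water-control means as predictor; OTUs never
  flagged in any pass are discarded as contamination.

The log scale is the only one on which "multiply the SE by five and take
the exponent" is meaningful: the threshold is a fold-change. Zeros are
handled with a pseudocount equal to half the smallest non-zero mean among
the values entering that particular regression (both axes pooled, refreshed
at every pass) — standard compositional practice that leaves
absent-from-control OTUs as large positive residuals, i.e. retainable,
which is the filter's intent.

## Why the passes accumulate

A single pooled-SE threshold has a hard combinatorial property: because OLS
residuals satisfy `sum(r^2) = (n - 2) * SE^2`, at most `(n - 2) / m^2`
points can lie more than `m` standard errors from the fit. With `m = 5`,
one pass can flag at most 4% of its input. If each subsequent pass re-fitted
*on the flagged outliers themselves*, the second pass would face a
homogeneous set — its own regression line runs through the retained OTUs —
and could keep at most 4% of *them*; three chained passes would end empty on
essentially any input. That wiring cannot produce a non-trivial final set.

The pipeline therefore treats the passes as iterative outlier *extraction*:
OTUs flagged in a pass are set aside as truly present and the regression is
re-fit on the remaining pool. Early passes have their residual SE inflated
by the very outliers they are trying to find; once those are removed, the
refreshed fit tightens around the contaminant line and previously masked
residents surface. The final retained set is the union of extractions from
the two blank-swab passes and the water pass. The literal re-fit-on-survivors
wiring remains available as `pass_mode = "survivor"` for comparison.

The same arithmetic defines the filter's operating envelope: the true
residents must be a small minority of the OTUs entering the regression
(fraction below `1 / (1 + m^2)`, about 4% at `m = 5`), otherwise they
inflate the SE so much that nothing clears the threshold and the filter
returns an empty set. This is the regime the method was built for —
amplicon OTU tables in which thousands of low-level reagent OTUs surround a
few dozen genuine residents — and the synthetic-data module can generate
both regimes (see below).

## The synthetic experiment generator

`generate_experiment()` emulates a three-visit longitudinal cohort:
45 subjects at baseline, one month and three months, 9 blank-swab and
3 water controls, sequencing depths drawn from a normal with mean 54,652
and SD 28,912 truncated at 1,000 reads, and per-sample true communities of
roughly 10–40 OTUs. Subjects carry individual-specific profiles: a fixed
per-subject core (default 10 OTUs) present at every visit plus non-core
OTUs present sporadically (probability 0.3 per sample), with a per-subject
OTU affinity (log-normal, SD 0.7) held constant over time so that
within-subject communities are more similar than between-subject ones.

Values the emulated study does not pin down were chosen once on realism
grounds: per-sample biomass is log-normal with median 2e4 units and log-SD
0.8 (swab yields vary several-fold); control biomass is 1% of the mean
subject biomass, representing handling/cross-over material spread over the
true OTU pool — which is what makes resident taxa appear faintly in blanks;
contaminant concentrations are log-normal (median 3 units, log-SD 1.5, so
reagent OTUs span about three orders of magnitude and total roughly 6% of a
typical subject library while dominating controls); luminosity noise is
multiplicative with log-SD 0.2 (gel densitometry is coarse). Counts are a
multinomial draw at the sample's depth, so library size carries no
information about biomass — only luminosity does.

The generator does **not** simulate read-level error, chimeras, taxonomic
misassignment, index hopping, or well-to-well cross-contamination that is
correlated between neighbouring samples. Passing recovery tests on these
bundles therefore demonstrates that the statistical machinery is correct
under the reagent model, not that the filter is robust to every failure
mode of real amplicon data.

## Core microbiome and diversity conventions

* Presence is `count >= 1` by default; the threshold is configurable
  because presence under heterogeneous depth is threshold-sensitive, and no
  canonical value exists.
* A (subject, time) cell with no sample is *missing*, never "absent";
  subjects with incomplete sampling leave the denominator of "all subjects
  at all time points" entirely, matching how longitudinal cohorts handle
  discontinued participants.
* Shannon diversity uses natural logarithms (index values of ~1.6 for
  communities of 10–30 OTUs are consistent with nats); the base is
  configurable.
* Bray-Curtis is computed on within-sample relative abundances, never raw
  counts, because sequencing depth varies several-fold.
* The temporal coefficient of variation uses the sample (n − 1) standard
  deviation over per-time mean relative abundances; taxa with zero mean are
  reported as `NA` rather than zero.
* Rarefaction is Monte-Carlo subsampling without replacement (`n_reps`
  replicates per depth, seeded); the tests cross-check it against the exact
  hypergeometric expectation.

## Numerical and degenerate-input conventions

* Both printed removal thresholds are strict: strictly fewer than 10,000
  reads removes a sample; a share strictly below `rare_fraction` removes an
  OTU.
* Retention is also strict (`residual > m * SE`), so a perfect fit
  (`SE = 0`) retains nothing — there is no evidence against contamination
  for any OTU in that case.
* A regression pass is recorded as *skipped* (no extraction, note in the
  report) when its pool has fewer than 3 OTUs, when every control mean is
  zero, or when the predictor has zero variance; direct calls to
  `fit_control_regression()` raise errors in those situations instead.
* The pipeline validates cross-table consistency up front and annotates
  stage failures with their step letter.
* All simulation and rarefaction randomness is locally seeded and restores
  the caller's RNG state, so identical configurations are bit-identical and
  test order cannot affect results.

## Problem sizes

The test-suite and example cohorts are deliberately desk-scale: the default
synthetic cohort is 147 samples by 190 OTUs, and the contaminant-dominated
demonstrations use 72 samples by 615 OTUs, which keeps every property test
and the full acceptance script comfortably within a coffee break on one
core while preserving the structure (subject:control imbalance, depth
spread, minority-resident pools) that the statistics depend on.

## Known limitations

* The filter assumes contaminant input is shared across all libraries; a
  contaminant present in only one reagent lot, or introduced after
  aliquoting, violates the regression's premise and will look like a
  resident.
* When true residents exceed a few percent of the candidate pool, the
  pooled-SE threshold (see the envelope argument above) cannot separate
  them; the pipeline returns small or empty sets there by construction
  rather than degrading gracefully.
* Luminosity is a coarse biomass surrogate; saturation of bright bands
  compresses the top of the scale and is not modelled.
* The presence threshold for "core" membership interacts with depth; the
  package reports prevalence at a declared threshold rather than claiming a
  depth-free core.
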