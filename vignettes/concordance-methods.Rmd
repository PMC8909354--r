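---
title: "Methods: immune-scoring concordance, simulation, and impact modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-scoring concordance, simulation, and impact modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoconcord)
```

This vignette documents the statistical model behind `immunoconcord`, the
choices made where the methodology was genuinely open, and what the
simulation does and does not establish about real slide data.

## The scoring model

A case contributes four densities (cells/mm²): CD3+ and CD8+ T cells in
the center of tumor (CT) and at the invasive margin (IM). Each density is
converted to a percentile of the corresponding channel of a reference
cohort, the four percentiles are averaged into the mean percentile mP, and
mP is classified at the clinical cutoff: IS-Low for mP ≤ 25, IS-High for
mP > 25. A five-level grading (IS 0–4) and decile bins (0–10%, 10–20%, …)
refine the same scale.

**Percentile scheme.** The empirical distribution function is evaluated
with plotting positions (i − 0.5)/n and linear interpolation between order
statistics. This scheme is symmetric (the median of an odd-sized reference
maps exactly to 50) and keeps interior values away from 0/100 saturation;
querying the reference against itself returns exactly uniform percentiles.
Tied reference values share the mean of their plotting positions, so the
function stays single-valued and monotone. Values outside the reference
range clamp to 0 and 100. No interpolation scheme is canonical for this
assay; this one was fixed once for its symmetry and is recorded here as a
package choice.

**Boundary conventions.** All cutoff comparisons are made in double
precision with no epsilon: mP = 25 is Low, matching the inclusive clinical
definition. Decile bins are right-closed ((10b, 10(b+1)], lowest bin closed
at 0) so that mP = 10 belongs to bin 0, consistent with the inclusive Low
cutoff. The five-level cutpoints default to (10, 25, 70, 95); only the 25
is clinically fixed, so only that one is validated, and the others are
overridable through `classify_five_level()` — the finer internal cutpoints
of the commercial assay are not public.

## Study-design operations

`stratified_sample()` draws `n_per_bin` cases (default 5) uniformly without
replacement from each mP decile, reproducing a 50-case set spread evenly
over the score's dynamic range. The draw is seeded and pool-order invariant
(cases are sorted by id before sampling). `cutoff_subset()` forms the
20-case set around the clinical cutoff as the 10 Low cases with the largest
mP and the 10 High cases with the smallest — i.e. nearest-by-rank on each
side. A distance-window rule would be an equally defensible reading of
"around the cutoff"; nearest-by-rank was chosen because it always yields
exactly 10 + 10 and needs no window parameter. Ties break by case id.

## Agreement statistics

For a 2 × 2 confusion table (a = ref-Low/called-Low, b = ref-Low/called-High,
c = ref-High/called-Low, d = ref-High/called-High):

* percent agreement `100 (a + d)/n`;
* Cohen's κ = (p_o − p_e)/(1 − p_e) with p_e from the two margins;
* PPA = `100 d/(c + d)` and NPA = `100 a/(a + b)`; sensitivity and PPV use
  IS-High as the positive class, so sensitivity coincides with PPA;
* Fleiss' κ for the multi-rater panel, computed on the four raters' 2-level
  T-scores with the reference excluded; with two raters it reduces to
  Scott's π (property-tested against an independent implementation).

Qualitative bands follow the McHugh-style intervals: none (≤ 0.20, and any
negative κ), minimal (0.21–0.39), weak (0.40–0.59), moderate (0.60–0.79),
strong (0.80–0.90), almost perfect (> 0.90). Because the printed interval
labels leave gaps (e.g. between 0.90 and "> 0.90"), κ is rounded to two
decimals before banding, which makes the bands exhaustive and monotone.

Two degenerate situations get explicit conventions rather than errors, so
batch simulations survive unanimous panels: when chance agreement p_e = 1
(both margins concentrated on the same class), κ is returned as 1 if
observed agreement is perfect and 0 otherwise, with a warning. The
**3-level → 2-level mapping** sends Intermediate to High: the IS-High
clinical class (IS 2–4) spans the intermediate-to-high percentile range
while IS-Low is only the bottom quartile. The mapping is exposed as
`three_to_two_class()` and can be replaced wholesale by supplying your own
`tscore2` column.

Panel-level disagreement counts a case as discordant when *any* rater's
T-score differs from the reference. The training-impact typology crosses
concordance before/after training: Type 1 concordant–concordant, Type 2
discordant–discordant, Type 3 discordant–concordant (training helped),
Type 4 concordant–discordant (training hurt).

## Repeatability

`repeat_concordance()` reports three agreement levels: per repeat, pooled
over all (case, repeat) cells, and case-level, where a case is concordant
only if *every* repeat matches the reference. The strict case-level rate is
the headline number (it is the only reading under which three distinct
misclassified cases out of 50 give 94%); the pooled rate is reported
alongside for transparency.

## The synthetic-data generator

No slide-level data from the motivating study are deposited, so the
generator stands in for them. It emulates three layers:

**Cohort.** Log-densities are multivariate normal over the four channels
with a separable correlation structure: `corr_markers` (default 0.7)
between CD3 and CD8 within a region, `corr_regions` (default 0.5) between
CT and IM within a marker; the 4 × 4 correlation matrix is the Kronecker
product of the two 2 × 2 factors, hence positive semi-definite by
construction. Default log-means put the IM above the CT for both markers
(≈ 800 vs 500 cells/mm² for CD3, ≈ 400 vs 200 for CD8), reflecting the
denser infiltrate at the margin, with a common log-SD of 0.9 — a spread
wide enough that the cohort covers the full percentile range. These values
are calibration choices of realistic magnitude, not measured quantities,
and are flagged as such in the packaged configuration.

**Raters.** A rater perceives `s = mP + bias + ε`, ε ~ N(0, noise_sd²)
drawn independently per case from a per-(rater, phase) substream, and calls
Low for s ≤ τ_low, High for s > τ_high, Intermediate otherwise (the
inclusive lower boundary mirrors the ≤ 25 clinical convention). Perception
operates on the percentile scale rather than on raw densities: it is the
simplest mechanism that reproduces the empirically observed concentration
of disagreement near the cutoff. Training pulls τ_low toward 25 and τ_high
toward 70 — the two density anchors used in the training material — by the
same `learning_rate`, and multiplies the noise by `noise_shrink`.
Heterogeneous learning rates, including a negative one, are the mechanism
for training helping some raters and worsening others. The packaged default
panel of four raters was calibrated (by a 20-seed sweep, before any test
was frozen) so the simulated study lands in the qualitative regime of
interest: mean rater-vs-reference κ ≈ 0.48 before training, higher after,
with rater P4 responding negatively to training.

**Repeats.** Each automated repeat perturbs mP by N(0, measurement_sd²)
with `measurement_sd = 1.5` percentile points (three repeats by default)
and clamps to [0, 100]; clamping was preferred to resampling because the
affected mass is negligible at that SD. A 1.5-point run-to-run SD makes
classification flips essentially impossible except within a few points of
the cutoff, matching the observed behavior of the automated assay.

**Random-stream discipline.** One master seed spawns named substreams
(`cohort`, `selection`, `rater:<id>:<phase>`, `repeats`) via a 31-bit
string hash, so adding a rater or changing the panel never perturbs the
cohort or the repeats, and every output is bit-reproducible under
(config, seed).

**What passing tests do not show.** The generator summarizes slide
heterogeneity — staining variation, spatial clustering, gland/stroma
structure — as a single Gaussian perception noise. Tests passing on this
model validate the statistical machinery and the qualitative mechanism
(boundary-concentrated discordance, heterogeneous training response), not
any quantitative claim about real pathologists or real slides.

## The impact model

The decision-tree model propagates misclassification rates through stage
II/III treatment pathways. With NPA and PPA in percent and a
`population_scenario`:

* stage II under-treatment: `(1 − NPA/100) × p(IS-Low | low-clinical-risk)`
  of low-risk patients, times `p(low-risk | stage II)` for the share of all
  stage II; over-treatment: `(1 − PPA/100) × p(IS-High relevant)`;
* stage III: analogous with the T4/N2 high-clinical-risk group, and
  `1 − PPA/100` of IS-High cases over-treated;
* annual counts: `round(incidence₂ × rate₂ + incidence₃ × rate₃)` with the
  rates supplied explicitly, because no published derivation links the
  headline annual counts to the agreement statistics.

The prevalence defaults are *assumptions back-solved* from the headline
decision-tree percentages (17, 9, 7, 37, 15, 21 at NPA 25 / PPA 79): e.g.
`p(IS-Low | low-risk stage II) = 0.17/0.75`. They live in a clearly
labelled `impact` block of the configuration and should be replaced with
registry estimates for any serious use. Annual incidences default to
101,420 (stage II) and 23,000 (stage III) new cases per year.

## Problem sizes and numerical tolerances

The shipped tests run the design at its native scale — 1000-case reference
cohorts, 50-case panels, 4 raters, 3 repeats — with 50–100 seed replicates
for the distributional properties (noise-monotonicity of κ, near-cutoff
discordance) and 200 random tables for the oracle equivalences; the full
suite completes in well under a minute. Closed-form checks are asserted to
1e-12; Monte-Carlo correlation checks to ±0.1 at n = 1000; the back-solved
impact round-trip to 0.5 percentage points, the slack inherited from
rounding the published percentages.

## Known limitations

* The rater model has no case-specific difficulty term: a slide that is
  hard for every pathologist is represented only through its proximity to
  the cutoff, not through correlated errors across raters. Real inter-rater
  kappas may therefore be lower than simulated ones at matched marginal
  accuracy.
* The reference cohort for percentile conversion is treated as an input;
  whether percentiles should be computed against an external fixed
  reference or the study cohort itself is a deployment decision.
* Confidence intervals for kappa are not provided; the study-scale
  quantities (n = 50) are reported as point estimates, as in the motivating
  analysis.
* The impact model is a static proportion tree: no survival modelling, no
  treatment-effect heterogeneity, no cost-effectiveness.
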