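# immunoconcord

Concordance analysis of automated immune scoring versus pathologist visual
assessment in early-stage colon cancer.

The immune response to a colon tumor — quantified as the densities of CD3+
and CD8+ tumor-infiltrating T cells in the center of the tumor (CT) and at
the invasive margin (IM) — is prognostic of recurrence. The standardized
Immunoscore (IS) converts the four densities into percentiles against a
reference cohort, averages them into a mean percentile

    mP = (P_CD3,CT + P_CD3,IM + P_CD8,CT + P_CD8,IM) / 4

and classifies cases at a clinical cutoff: **IS-Low** when mP ≤ 25 (high
recurrence risk) and **IS-High** when mP > 25, with a finer five-level
grading IS 0–4 nested inside (IS 0–1 = Low). Pathologists can instead score
the same stained slides visually into a two-level **T-score**. This package
implements everything needed to ask how well the two agree, and what a
disagreement costs clinically:

* **Scoring** — empirical percentile conversion (plotting positions
  (i − 0.5)/n with linear interpolation, tie-aware), mP, two-level,
  five-level, and decile classification.
* **Study design** — stratified selection of 50 cases uniform over mP
  deciles and of the 20-case subset straddling the 25% cutoff.
* **Agreement statistics** — confusion tables, percent agreement, positive
  and negative percent agreement (PPA/NPA), sensitivity/PPV, Cohen's kappa
  `κ = (p_o − p_e)/(1 − p_e)`, Fleiss' kappa for multi-rater panels, and
  the McHugh-style qualitative bands (none … almost perfect), plus
  panel-level disagreement rates and the 4-type classification of how a
  training intervention changed each rater-case concordance.
* **Repeatability** — per-repeat, pooled, and strict case-level concordance
  of repeated automated runs, with the discordant near-cutoff cases listed.
* **Simulation** — a seeded generator of log-normal density cohorts with a
  marker × region correlation structure, of noisy threshold-based
  pathologist raters before/after training, and of repeated measurements.
* **Impact model** — a decision-tree propagation of misclassification rates
  (1 − NPA, 1 − PPA) to under-/over-treatment fractions and annual patient
  counts for stage II/III colon cancer populations.

## Worked example

Score a new case against a (here: simulated) reference cohort:

```r
library(immunoconcord)
dens <- generate_reference_cohort(cohort_params(n_reference = 1000, seed = 7))
ref  <- reference_distribution(dens)
case <- data.frame(case_id = "S1",
                   marker  = c("CD3", "CD3", "CD8", "CD8"),
                   region  = c("CT",  "IM",  "CT",  "IM"),
                   density = c(350, 620, 140, 310))   # cells/mm^2
score_cases(case, ref)
#>   case_id p_cd3_ct p_cd3_im p_cd8_ct p_cd8_im    mP  is2 is5 decile_bin
#> 1      S1    34.63    39.53    35.54    39.13 37.21 High   2          3
```

Each density sits near the 35th–40th percentile of the reference cohort, so
the mean percentile is 37.2: above the 25% cutoff, hence IS-High (IS 2),
decile bin 3.

Agreement between a rater and the reference, from a 2×2 tally (12 of 15
reference-Low called Low, 29 of 35 reference-High called High):

```r
t <- confusion_counts(a = 12, b = 3, c = 6, d = 29)
percent_agreement(t)                 # 82
cohen_kappa(t)                       # 0.5945946
interpret_kappa(cohen_kappa(t))      # weak
```

The full simulated study — cohort, case selection, 4-rater panel before and
after training, repeated runs, impact model — in one call:

```r
m <- run_pipeline(seed = 1, out_dir = "pipeline_out")
print(m)
#>    case_set  phase n_cases n_discordant percent
#> 1   full_50 before      50           33      66
#> 2   full_50  after      50           21      42
#> 3 cutoff_20 before      20           19      95
#> 4 cutoff_20  after      20           17      85
#>    case_set  phase n_cases n_raters fleiss_kappa    band
#> 1   full_50 before      50        4   0.20660916 minimal
#> 2   full_50  after      50        4   0.40957515    weak
#> 3 cutoff_20 before      20        4  -0.07744108    none
#> 4 cutoff_20  after      20        4   0.03492063    none
#> case-level agreement 96.0% (pooled 98.0%, kappa 0.95); 2 discordant case(s)
#> Decision-tree impact (NPA 50%, PPA 61.1%):
#>   stage II : under-treated 11% of low-clinical-risk (6% of all), over-treated 13% of all
#>   stage III: under-treated 25% of T4/N2 (10% of all), over-treated 39% of IS-High
#>   ~31727 patients misclassified annually
```

Reading the output: at least one of the four simulated pathologists
disagrees with the reference IS on 66% of the 50 cases before training
(42% after), and on nearly every case in the 20-case subset around the
cutoff; inter-rater agreement is minimal-to-weak; the repeated automated
runs disagree with the reference on only 2 of 50 cases, both near the
cutoff. The same tables are written to `pipeline_out/` as CSV/JSON, and a
command-line wrapper is available as
`Rscript scripts/pipeline.R --seed 1 --out pipeline_out`.

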