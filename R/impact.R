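#' Population scenario for the clinical decision-tree impact model
#'
#' Incidence and prevalence assumptions through which misclassification
#' rates are propagated. The annual stage II/III counts default to the
#' published US estimates (101,420 and 23,000 new cases per year). The
#' prevalence proportions are configurable assumptions: the defaults are
#' back-solved from the headline impact percentages of the decision tree
#' (e.g. an NPA of 25% turning into 17% of low-risk stage II patients
#' implies an IS-Low share of 0.17/0.75 among them) and shipped as a
#' clearly-labelled assumptions block in the default configuration.
#'
#' @param annual_stage2,annual_stage3 Annual new stage II / III colon
#'   cancer cases.
#' @param p_lowrisk_given_stage2 Proportion of stage II patients at low
#'   clinical risk.
#' @param p_islow_given_lowrisk2 Proportion IS-Low among low-clinical-risk
#'   stage II patients.
#' @param p_ishigh_relevant2 Proportion of all stage II patients who are
#'   IS-High and for whom a false Low call would trigger overtreatment.
#' @param p_highclin_given_stage3 Proportion of stage III patients at high
#'   clinical risk (T4/N2).
#' @param p_islow_given_highclin3 Proportion IS-Low among
#'   high-clinical-risk stage III patients.
#' @return A list of class `population_scenario`.
#' @export
population_scenario <- function(annual_stage2 = 101420,
                                annual_stage3 = 23000,
                                p_lowrisk_given_stage2 = 0.09 / 0.17,
                                p_islow_given_lowrisk2 = 0.17 / 0.75,
                                p_ishigh_relevant2 = 0.07 / 0.21,
                                p_highclin_given_stage3 = 0.15 / 0.37,
                                p_islow_given_highclin3 = 0.37 / 0.75) {
  pr <- c(p_lowrisk_given_stage2, p_islow_given_lowrisk2,
          p_ishigh_relevant2, p_highclin_given_stage3,
          p_islow_given_highclin3)
  if (any(pr < 0) || any(pr > 1)) stop("proportions must lie in [0, 1]")
  if (annual_stage2 < 0 || annual_stage3 < 0) stop("counts must be >= 0")
  structure(list(annual_stage2 = annual_stage2,
                 annual_stage3 = annual_stage3,
                 p_lowrisk_given_stage2 = p_lowrisk_given_stage2,
                 p_islow_given_lowrisk2 = p_islow_given_lowrisk2,
                 p_ishigh_relevant2 = p_ishigh_relevant2,
                 p_highclin_given_stage3 = p_highclin_given_stage3,
                 p_islow_given_highclin3 = p_islow_given_highclin3),
            class = "population_scenario")
}

check_rate_pct <- function(x, what) {
  if (!is.finite(x) || x < 0 || x > 100)
    stop(what, " must be a percent in [0, 100]")
  x
}

#' Stage II under/over-treatment fractions from agreement rates
#'
#' A missed IS-Low call (1 - NPA) labels a truly high-biological-risk
#' patient as low risk: under-screening/under-treatment. A missed IS-High
#' call (1 - PPA) sends a low-recurrence-risk patient to unnecessary
#' adjuvant chemotherapy: over-treatment.
#'
#' @param npa,ppa Negative / positive percent agreement, percents.
#' @param scenario A `population_scenario`.
#' @return Named list: `under2_lowrisk_frac` (share of low-clinical-risk
#'   stage II under-treated), `under2_all_frac` (share of all stage II),
#'   `over2_all_frac` (share of all stage II over-treated).
#' @export
stage2_impact <- function(npa, ppa, scenario = population_scenario()) {
  check_rate_pct(npa, "npa"); check_rate_pct(ppa, "ppa")
  miss_low <- 1 - npa / 100
  under_lowrisk <- miss_low * scenario$p_islow_given_lowrisk2
  list(under2_lowrisk_frac = under_lowrisk,
       under2_all_frac = under_lowrisk * scenario$p_lowrisk_given_stage2,
       over2_all_frac = (1 - ppa / 100) * scenario$p_ishigh_relevant2)
}

#' Stage III under/over-treatment fractions from agreement rates
#'
#' @inheritParams stage2_impact
#' @return Named list: `under3_highclin_frac` (share of T4/N2 stage III
#'   wrongly deemed good responders), `under3_all_frac` (share of all stage
#'   III), `over3_ishigh_frac` (share of IS-High cases wrongly treated as
#'   poor responders).
#' @export
stage3_impact <- function(npa, ppa, scenario = population_scenario()) {
  check_rate_pct(npa, "npa"); check_rate_pct(ppa, "ppa")
  miss_low <- 1 - npa / 100
  under_highclin <- miss_low * scenario$p_islow_given_highclin3
  list(under3_highclin_frac = under_highclin,
       under3_all_frac = under_highclin * scenario$p_highclin_given_stage3,
       over3_ishigh_frac = 1 - ppa / 100)
}

#' Annual misclassified patient count
#'
#' @param scenario A `population_scenario` (provides the annual stage II
#'   and III incidences).
#' @param misclass_rate_stage2,misclass_rate_stage3 Overall
#'   misclassification proportions in \[0, 1\] for each stage.
#' @return Rounded annual count.
#' @export
annual_misclassified <- function(scenario, misclass_rate_stage2,
                                 misclass_rate_stage3) {
  r <- c(misclass_rate_stage2, misclass_rate_stage3)
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("misclassification rates must lie in [0, 1]")
  round(scenario$annual_stage2 * misclass_rate_stage2 +
          scenario$annual_stage3 * misclass_rate_stage3)
}

#' Full decision-tree impact report
#'
#' Combines both stages and, optionally, annual counts from overall
#' misclassification rates.
#'
#' @inheritParams stage2_impact
#' @param misclass_rate_stage2,misclass_rate_stage3 Optional overall
#'   misclassification proportions used for the annual count (default:
#'   both stages use the pooled disagreement implied by 1 - observed
#'   percent agreement is NOT assumed; pass explicit rates).
#' @return List of class `impact_result` with all six fractions and, when
#'   rates are supplied, `annual_misclassified`.
#' @export
impact_report <- function(npa, ppa, scenario = population_scenario(),
                          misclass_rate_stage2 = NULL,
                          misclass_rate_stage3 = NULL) {
  res <- c(stage2_impact(npa, ppa, scenario),
           stage3_impact(npa, ppa, scenario))
  if (!is.null(misclass_rate_stage2) && !is.null(misclass_rate_stage3))
    res$annual_misclassified <-
      annual_misclassified(scenario, misclass_rate_stage2,
                           misclass_rate_stage3)
  res$npa <- npa
  res$ppa <- ppa
  structure(res, class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat("Decision-tree impact (NPA", paste0(x$npa, "%,"), "PPA",
      paste0(x$ppa, "%):\n"))
  cat(sprintf(
    "  stage II : under-treated %.0f%% of low-clinical-risk (%.0f%% of all), over-treated %.0f%% of all\n",
    100 * x$under2_lowrisk_frac, 100 * x$under2_all_frac,
    100 * x$over2_all_frac))
  cat(sprintf(
    "  stage III: under-treated %.0f%% of T4/N2 (%.0f%% of all), over-treated %.0f%% of IS-High\n",
    100 * x$under3_highclin_frac, 100 * x$under3_all_frac,
    100 * x$over3_ishigh_frac))
  if (!is.null(x$annual_misclassified))
    cat(sprintf("  ~%d patients misclassified annually\n",
                x$annual_misclassified))
  invisible(x)
}
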