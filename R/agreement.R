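#' Collapse a 3-level visual call to the 2-level T-score
#'
#' Clinical reporting uses two classes. Low maps to Low; Intermediate and
#' High both map to High, because the IS-High clinical class (IS 2-4) spans
#' the intermediate-to-high percentile range while IS-Low is only the bottom
#' quartile.
#'
#' @param call3 Factor/character vector with values `Low`, `Intermediate`,
#'   `High`.
#' @return Factor with levels `Low`, `High`.
#' @export
three_to_two_class <- function(call3) {
  call3 <- as.character(call3)
  bad <- setdiff(unique(call3), c("Low", "Intermediate", "High"))
  if (length(bad))
    stop("unknown 3-level category: ", paste(bad, collapse = ", "))
  factor(ifelse(call3 == "Low", "Low", "High"), levels = c("Low", "High"))
}

#' Two-by-two confusion table against the reference classification
#'
#' Counts are laid out as: `a` = reference Low called Low, `b` = reference
#' Low called High, `c` = reference High called Low, `d` = reference High
#' called High.
#'
#' @param calls Factor/character vector of 2-level calls (`Low`/`High`).
#' @param reference Matching vector of reference classes, same cases in the
#'   same order (or named vectors sharing names).
#' @return Object of class `confusion_2x2` with fields `a`, `b`, `c`, `d`,
#'   `n`.
#' @export
confusion_table <- function(calls, reference) {
  calls <- as.character(calls); reference <- as.character(reference)
  if (length(calls) != length(reference))
    stop("calls and reference cover different case sets")
  if (length(calls) == 0L) stop("empty comparison")
  ok <- c("Low", "High")
  if (!all(calls %in% ok) || !all(reference %in% ok))
    stop("2-level classes must be Low or High")
  structure(list(a = sum(reference == "Low" & calls == "Low"),
                 b = sum(reference == "Low" & calls == "High"),
                 c = sum(reference == "High" & calls == "Low"),
                 d = sum(reference == "High" & calls == "High"),
                 n = length(calls)),
            class = "confusion_2x2")
}

#' Build a confusion table directly from the four counts
#'
#' @param a,b,c,d Non-negative integer counts (see [confusion_table()]).
#' @return A `confusion_2x2` object.
#' @export
confusion_counts <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  n <- sum(v)
  if (n == 0L) stop("empty confusion table")
  structure(list(a = a, b = b, c = c, d = d, n = n), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(reference = c("Low", "High"),
                              call = c("Low", "High")))
  print(m)
  invisible(x)
}

#' Raw percent agreement
#'
#' @param t A `confusion_2x2` object.
#' @return Percent of cases on the diagonal, in \[0, 100\].
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  100 * (t$a + t$d) / t$n
}

#' Cohen's kappa for a 2x2 confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement computed from the two marginal distributions. Negative values
#' indicate less agreement than expected by chance. When both margins are
#' degenerate (`p_e = 1`), the statistic is undefined; the convention here
#' returns 1 for perfect observed agreement and 0 otherwise, with a warning,
#' so batch pipelines survive unanimous panels.
#'
#' @param t A `confusion_2x2` object.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (pe >= 1 - 1e-12) {
    warning("degenerate margins: kappa undefined, returning ",
            if (po >= 1 - 1e-12) 1 else 0)
    return(if (po >= 1 - 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Multi-rater chance-corrected agreement. Every case must be rated by the
#' same number of raters (k >= 2); per-case agreement is the proportion of
#' concordant rater pairs, and chance agreement uses the pooled category
#' proportions. With k = 2 this equals Scott's pi.
#'
#' @param ratings Matrix or data.frame, cases in rows and raters in
#'   columns, categorical entries.
#' @param categories Optional vector of category labels; defaults to the
#'   observed ones. Categories never used still contribute zero to the
#'   chance term.
#' @return Kappa in \[-1, 1\] (degenerate chance agreement handled as in
#'   [cohen_kappa()]).
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop("every case must be rated by the same raters (no missing cells)")
  k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters")
  n <- nrow(ratings)
  if (n < 1L) stop("empty ratings matrix")
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1L, function(r)
    tabulate(factor(r, levels = categories), nbins = length(categories))))
  counts <- matrix(counts, nrow = n)
  if (any(rowSums(counts) != k))
    stop("unrecognized category present in ratings")
  Pi <- (rowSums(counts^2) - k) / (k * (k - 1))
  Pbar <- mean(Pi)
  pc <- colSums(counts) / (n * k)
  Pe <- sum(pc^2)
  if (Pe >= 1 - 1e-12) {
    warning("degenerate pooled margins: kappa undefined, returning ",
            if (Pbar >= 1 - 1e-12) 1 else 0)
    return(if (Pbar >= 1 - 1e-12) 1 else 0)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Positive and negative percent agreement
#'
#' PPA is the fraction of reference-High cases called High; NPA the
#' fraction of reference-Low cases called Low. An empty reference class
#' yields `NA` for that component.
#'
#' @param t A `confusion_2x2` object.
#' @return Named numeric vector `c(ppa = , npa = )`, percents.
#' @export
ppa_npa <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  ppa <- if (t$c + t$d > 0) 100 * t$d / (t$c + t$d) else NA_real_
  npa <- if (t$a + t$b > 0) 100 * t$a / (t$a + t$b) else NA_real_
  c(ppa = ppa, npa = npa)
}

#' Sensitivity and positive predictive value (positive class = High)
#'
#' The positive class is IS-High, matching the PPA orientation: sensitivity
#' is identical to PPA, and PPV conditions on the call rather than the
#' reference.
#'
#' @param t A `confusion_2x2` object.
#' @return Named numeric vector `c(sensitivity = , ppv = )`, percents;
#'   `NA` on a zero denominator.
#' @export
sensitivity_ppv <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  sens <- if (t$c + t$d > 0) 100 * t$d / (t$c + t$d) else NA_real_
  ppv <- if (t$b + t$d > 0) 100 * t$d / (t$b + t$d) else NA_real_
  c(sensitivity = sens, ppv = ppv)
}

#' Qualitative interpretation band for a kappa value
#'
#' McHugh-style bands: none (<= 0.20, including negative kappa), minimal
#' (0.21-0.39), weak (0.40-0.59), moderate (0.60-0.79), strong (0.80-0.90),
#' almost perfect (> 0.90). The printed band edges leave gaps between
#' percent labels; these are resolved by rounding kappa to 2 decimals
#' before banding.
#'
#' @param kappa Numeric vector of kappa values in \[-1, 1\].
#' @return Ordered factor of band labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1) || any(kappa > 1))
    stop("kappa must lie in [-1, 1]")
  k <- round(kappa, 2)
  bands <- c("none", "minimal", "weak", "moderate", "strong",
             "almost perfect")
  idx <- findInterval(k, c(0.205, 0.395, 0.595, 0.795, 0.905)) + 1L
  # findInterval on the rounded value: 0.20 -> none, 0.21 -> minimal, ...
  factor(bands[idx], levels = bands, ordered = TRUE)
}

#' Full agreement summary for one rater against the reference
#'
#' @param calls,reference 2-level vectors as in [confusion_table()].
#' @return List of class `agreement_result`: `table` (confusion), and
#'   `percent_agreement`, `kappa`, `band`, `ppa`, `npa`, `sensitivity`,
#'   `ppv`.
#' @export
agreement_summary <- function(calls, reference) {
  t <- confusion_table(calls, reference)
  kap <- cohen_kappa(t)
  pn <- ppa_npa(t)
  sp <- sensitivity_ppv(t)
  structure(list(table = t,
                 percent_agreement = percent_agreement(t),
                 kappa = kap,
                 band = interpret_kappa(kap),
                 ppa = pn[["ppa"]], npa = pn[["npa"]],
                 sensitivity = sp[["sensitivity"]], ppv = sp[["ppv"]]),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement %.1f%%, kappa %.3f (%s), PPA %.1f%%, NPA %.1f%%\n",
              x$percent_agreement, x$kappa, as.character(x$band),
              x$ppa, x$npa))
  invisible(x)
}

#' Panel-level disagreement rate with the reference
#'
#' A case counts as discordant when at least one rater's 2-level T-score
#' differs from the reference classification of that case.
#'
#' @param ratings Ratings table slice for one phase: columns `case_id`,
#'   `rater_id`, `tscore2`; every case must be rated by every rater.
#' @param reference An `is_result` data.frame (or data.frame with
#'   `case_id`, `is2`) covering the same cases.
#' @return List with `n_discordant`, `percent`, and the discordant
#'   `case_ids`.
#' @export
overall_disagreement_rate <- function(ratings, reference) {
  cases <- unique(ratings$case_id)
  raters <- unique(ratings$rater_id)
  if (nrow(ratings) != length(cases) * length(raters) ||
      anyDuplicated(ratings[c("case_id", "rater_id")]))
    stop("ratings panel is incomplete or duplicated")
  ref <- reference$is2[match(cases, reference$case_id)]
  if (anyNA(ref)) stop("reference missing for some rated cases")
  mism <- as.character(ratings$tscore2) !=
    as.character(ref[match(ratings$case_id, cases)])
  disc <- cases[cases %in% unique(ratings$case_id[mism])]
  list(n_discordant = length(disc),
       percent = 100 * length(disc) / length(cases),
       case_ids = disc)
}

#' Classify the impact of training per (rater, case)
#'
#' Crosses concordance with the reference before and after training:
#' Type 1 = concordant in both phases; Type 2 = discordant in both
#' (training had no impact); Type 3 = discordant then concordant (positive
#' impact); Type 4 = concordant then discordant (training worsened the
#' concordance).
#'
#' @param before,after Ratings table slices for the two phases (columns
#'   `case_id`, `rater_id`, `tscore2`), same (case, rater) panel.
#' @param reference An `is_result` data.frame covering the cases.
#' @return List with `types` (data.frame `case_id`, `rater_id`, `type`) and
#'   `percent` (named numeric, Types 1-4, sums to 100).
#' @export
training_impact_types <- function(before, after, reference) {
  key <- function(d) paste(d$case_id, d$rater_id, sep = "\r")
  before <- before[order(key(before)), , drop = FALSE]
  after <- after[order(key(after)), , drop = FALSE]
  if (!identical(key(before), key(after)))
    stop("before/after phases cover different (case, rater) panels")
  ref <- reference$is2[match(before$case_id, reference$case_id)]
  if (anyNA(ref)) stop("reference missing for some rated cases")
  cb <- as.character(before$tscore2) == as.character(ref)
  ca <- as.character(after$tscore2) == as.character(ref)
  type <- ifelse(cb & ca, 1L, ifelse(!cb & !ca, 2L, ifelse(!cb & ca, 3L, 4L)))
  pct <- 100 * tabulate(type, 4L) / length(type)
  names(pct) <- paste0("type", 1:4)
  list(types = data.frame(case_id = before$case_id,
                          rater_id = before$rater_id,
                          type = type, stringsAsFactors = FALSE),
       percent = pct)
}

#' Read / write the ratings CSV dialect
#'
#' Header: `case_id,rater_id,phase,call3,tscore2` (optional per-channel
#' 3-level columns `cd3_ct,cd3_im,cd8_ct,cd8_im` are passed through).
#'
#' @param path CSV path.
#' @return Ratings data.frame.
#' @export
read_ratings_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(case_id = "character"))
  need <- c("case_id", "rater_id", "phase", "call3", "tscore2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("ratings table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(d$phase %in% c("before", "after")))
    stop("phase must be 'before' or 'after'")
  d
}

#' @rdname read_ratings_csv
#' @param x Ratings data.frame.
#' @export
write_ratings_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
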