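#' Concordance of repeated automated measurements with the reference score
#'
#' Each repeat's mean percentile is classified at the 25 cutoff and compared
#' with the reference classification. Agreement is reported per repeat, as a
#' pooled rate over all (case, repeat) cells, and at case level, where a
#' case counts as concordant only when every repeat matches the reference —
#' the strictest reading, and the one under which three distinct
#' misclassified cases out of 50 give 94%.
#'
#' @param repeats Data.frame with columns `case_id`, `repeat_id`, `mP`
#'   (the `is2` column is recomputed). Every case must appear in every
#'   repeat.
#' @param reference An `is_result` data.frame covering the same cases.
#' @return List of class `repeatability_result`: `per_repeat_agreement`
#'   (named percents), `pooled_agreement`, `case_level_agreement`,
#'   `pooled_table` (confusion over all cells), `pooled_kappa`,
#'   `discordant` (data.frame `case_id`, `reference_mP`, `repeat_classes`).
#' @export
repeat_concordance <- function(repeats, reference) {
  reps <- unique(repeats$repeat_id)
  cases <- unique(repeats$case_id)
  if (nrow(repeats) != length(reps) * length(cases) ||
      anyDuplicated(repeats[c("case_id", "repeat_id")]))
    stop("every case must be present in every repeat")
  ref_idx <- match(cases, reference$case_id)
  if (anyNA(ref_idx)) stop("reference missing for some cases")
  ref2 <- as.character(reference$is2)[ref_idx]
  repeats$is2 <- as.character(classify_two_level(repeats$mP))
  ref_for_row <- ref2[match(repeats$case_id, cases)]
  match_row <- repeats$is2 == ref_for_row

  per_rep <- vapply(reps, function(r) {
    sel <- repeats$repeat_id == r
    100 * mean(match_row[sel])
  }, numeric(1))
  names(per_rep) <- reps

  all_match <- vapply(cases, function(cid)
    all(match_row[repeats$case_id == cid]), logical(1))
  disc_cases <- cases[!all_match]
  disc <- data.frame(
    case_id = disc_cases,
    reference_mP = reference$mP[match(disc_cases, reference$case_id)],
    repeat_classes = vapply(disc_cases, function(cid) {
      sel <- repeats$case_id == cid
      paste(repeats$repeat_id[sel], repeats$is2[sel],
            sep = "=", collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)

  pooled <- confusion_table(repeats$is2, ref_for_row)
  structure(list(per_repeat_agreement = per_rep,
                 pooled_agreement = percent_agreement(pooled),
                 case_level_agreement = 100 * mean(all_match),
                 pooled_table = pooled,
                 pooled_kappa = cohen_kappa(pooled),
                 discordant = disc),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "case-level agreement %.1f%% (pooled %.1f%%, kappa %.2f); %d discordant case(s)\n",
    x$case_level_agreement, x$pooled_agreement, x$pooled_kappa,
    nrow(x$discordant)))
  invisible(x)
}

#' Read the repeats CSV dialect (`case_id,repeat_id,mP`)
#'
#' @param path CSV path.
#' @return Data.frame suitable for [repeat_concordance()].
#' @export
read_repeats_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(case_id = "character"))
  miss <- setdiff(c("case_id", "repeat_id", "mP"), names(d))
  if (length(miss))
    stop("repeats table is missing columns: ", paste(miss, collapse = ", "))
  d
}
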