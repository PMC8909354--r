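#' Stratified sample, uniform across mP deciles
#'
#' Reproduces the study design of drawing the same number of cases from
#' every decile of the mean percentile, giving a case set spread uniformly
#' along the dynamic range of the score (50 cases at the default 5 per
#' decile). Sampling is without replacement within each decile bin and is
#' invariant to the ordering of the pool: cases are sorted by `case_id`
#' before the seeded draw.
#'
#' @param pool An `is_result` data.frame (the scored cohort).
#' @param n_per_bin Cases to draw per decile bin (default 5).
#' @param seed Integer seed.
#' @return The selected rows of `pool`, with a `label` attribute
#'   `"full_50"`, ordered by decile bin then `case_id`.
#' @export
stratified_sample <- function(pool, n_per_bin = 5, seed = 1L) {
  stopifnot(n_per_bin >= 1)
  pool <- pool[order(pool$case_id), , drop = FALSE]
  counts <- table(factor(pool$decile_bin, levels = 0:9))
  short <- names(counts)[counts < n_per_bin]
  if (length(short))
    stop("decile bin(s) ", paste(short, collapse = ", "),
         " hold fewer than ", n_per_bin, " cases")
  set.seed(substream_seed(seed, "selection"))
  picked <- unlist(lapply(0:9, function(b) {
    ids <- pool$case_id[pool$decile_bin == b]
    sample(ids, n_per_bin)
  }))
  sel <- pool[match(picked, pool$case_id), , drop = FALSE]
  sel <- sel[order(sel$decile_bin, sel$case_id), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "label") <- "full_50"
  sel
}

#' Around-the-cutoff subset: 10 Low and 10 High cases nearest 25
#'
#' From a stratified case set, selects the 10 IS-Low cases with the largest
#' mean percentile (closest below or at the 25 cutoff) and the 10 IS-High
#' cases with the smallest (closest above). Ties are broken by `case_id`
#' order for reproducibility.
#'
#' @param cases An `is_result` data.frame (typically the full 50-case set).
#' @param n_per_side Cases per side of the cutoff (default 10).
#' @return The selected rows, `label` attribute `"cutoff_20"`.
#' @export
cutoff_subset <- function(cases, n_per_side = 10) {
  low <- cases[cases$is2 == "Low", , drop = FALSE]
  high <- cases[cases$is2 == "High", , drop = FALSE]
  if (nrow(low) < n_per_side)
    stop("need at least ", n_per_side, " Low cases, have ", nrow(low))
  if (nrow(high) < n_per_side)
    stop("need at least ", n_per_side, " High cases, have ", nrow(high))
  low <- low[order(-low$mP, low$case_id), , drop = FALSE][seq_len(n_per_side), ]
  high <- high[order(high$mP, high$case_id), , drop = FALSE][seq_len(n_per_side), ]
  sel <- rbind(low, high)
  sel <- sel[order(sel$mP, sel$case_id), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "label") <- "cutoff_20"
  sel
}
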