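MARKERS <- c("CD3", "CD8")
REGIONS <- c("CT", "IM")

#' Channel labels for the four marker x region measurements
#'
#' The assay quantifies two markers (CD3+, CD8+ T cells) in two tumor
#' regions (CT = center of tumor, IM = invasive margin), giving four
#' measurement channels per case.
#'
#' @return Character vector `c("CD3.CT", "CD3.IM", "CD8.CT", "CD8.IM")`.
#' @export
is_channels <- function() {
  as.vector(outer(MARKERS, REGIONS, paste, sep = "."))[c(1, 3, 2, 4)]
}

#' Build a reference distribution for percentile conversion
#'
#' Collects the per-channel density values of a reference cohort and stores
#' them sorted, ready for empirical-percentile lookups. Densities are
#' cells/mm^2.
#'
#' @param densities Long-format data.frame with columns `case_id`, `marker`
#'   (`"CD3"`/`"CD8"`), `region` (`"CT"`/`"IM"`), `density` (non-negative).
#' @return An object of class `ref_dist`: a named list of sorted numeric
#'   vectors, one per channel (`CD3.CT`, `CD3.IM`, `CD8.CT`, `CD8.IM`).
#' @export
reference_distribution <- function(densities) {
  densities <- validate_density_table(densities)
  out <- lapply(is_channels(), function(ch) {
    parts <- strsplit(ch, ".", fixed = TRUE)[[1]]
    v <- densities$density[densities$marker == parts[1] &
                             densities$region == parts[2]]
    if (length(v) < 2L)
      stop("reference distribution for channel ", ch,
           " needs at least 2 values, got ", length(v))
    sort(v)
  })
  names(out) <- is_channels()
  structure(out, class = "ref_dist")
}

validate_density_table <- function(densities) {
  densities <- as.data.frame(densities)
  need <- c("case_id", "marker", "region", "density")
  miss <- setdiff(need, names(densities))
  if (length(miss))
    stop("density table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(densities$marker %in% MARKERS))
    stop("marker must be one of: ", paste(MARKERS, collapse = ", "))
  if (!all(densities$region %in% REGIONS))
    stop("region must be one of: ", paste(REGIONS, collapse = ", "))
  if (any(!is.finite(densities$density)) || any(densities$density < 0))
    stop("densities must be finite and non-negative")
  densities
}

#' Empirical percentile of a density against a reference channel
#'
#' Evaluates the empirical cumulative distribution of the reference values
#' at `x`, on a 0-100 scale. Order statistics get plotting positions
#' (i - 0.5)/n, with linear interpolation between them; tied reference
#' values share the mean of their plotting positions. Values below the
#' reference minimum map to 0 and above the maximum to 100.
#'
#' @param x Numeric vector of non-negative densities (cells/mm^2).
#' @param ref Sorted numeric vector of reference densities for the same
#'   channel (length >= 2), or a single `ref_dist` channel.
#' @return Percentiles in \[0, 100\], monotone non-decreasing in `x`.
#' @export
empirical_percentile <- function(x, ref) {
  if (is.null(ref) || length(ref) == 0L)
    stop("empty reference distribution")
  if (length(ref) < 2L)
    stop("reference distribution needs at least 2 values")
  if (is.unsorted(ref))
    stop("reference distribution must be sorted non-decreasing")
  if (any(!is.finite(x)) || any(x < 0))
    stop("densities must be finite and non-negative")
  n <- length(ref)
  pos <- (seq_len(n) - 0.5) / n
  # ties: one node per distinct value at the mean of its plotting positions
  vals <- unique(ref)
  ppos <- vapply(split(pos, match(ref, vals)), mean, numeric(1))
  p <- if (length(vals) == 1L) {
    rep(ppos[1L], length(x))
  } else {
    stats::approx(vals, ppos, xout = pmin(pmax(x, vals[1L]),
                                          vals[length(vals)]))$y
  }
  p <- 100 * p
  p[x < ref[1L]] <- 0
  p[x > ref[n]] <- 100
  pmin(pmax(p, 0), 100)
}

#' Mean percentile (mP) of the four channels
#'
#' @param p Numeric vector (or matrix with 4 columns) of the four channel
#'   percentiles (CD3.CT, CD3.IM, CD8.CT, CD8.IM), each in \[0, 100\].
#' @return The arithmetic mean, in \[0, 100\].
#' @export
mean_percentile <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    p <- as.matrix(p)
    if (ncol(p) != 4L) stop("expected 4 percentile channels, got ", ncol(p))
    if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
      stop("percentiles must lie in [0, 100]")
    return(rowMeans(p))
  }
  if (length(p) != 4L) stop("expected 4 percentile channels, got ", length(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("percentiles must lie in [0, 100]")
  mean(p)
}

#' Two-level Immunoscore classification at the 25% clinical cutoff
#'
#' Cases with mean percentile at or below 25 are IS-Low (high recurrence
#' risk); above 25 they are IS-High. The comparison is exact: mP = 25 is Low.
#'
#' @param mP Numeric vector of mean percentiles in \[0, 100\].
#' @return Factor with levels `Low`, `High`.
#' @export
classify_two_level <- function(mP) {
  check_mp(mP)
  factor(ifelse(mP <= 25, "Low", "High"), levels = c("Low", "High"))
}

check_mp <- function(mP) {
  if (any(!is.finite(mP)) || any(mP < 0) || any(mP > 100))
    stop("mP must lie in [0, 100]")
  invisible(mP)
}

#' Five-level Immunoscore classification
#'
#' Bins the mean percentile into the five assay categories IS 0-4 using four
#' ascending internal cutpoints. Bins are left-open/right-closed (the lowest
#' bin is closed at 0), so the two-level classes nest exactly: IS 0-1 is
#' IS-Low, IS 2-4 is IS-High. Only the 25 cutpoint is clinically fixed; the
#' other three are configurable.
#'
#' @param mP Numeric vector of mean percentiles in \[0, 100\].
#' @param cutpoints Four strictly ascending values in (0, 100); the second
#'   must equal 25 so the five-level and two-level classifications nest.
#' @return Integer vector with values 0-4.
#' @export
classify_five_level <- function(mP, cutpoints = c(10, 25, 70, 95)) {
  check_mp(mP)
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0) ||
      any(cutpoints <= 0) || any(cutpoints >= 100))
    stop("cutpoints must be 4 strictly ascending values in (0, 100)")
  if (cutpoints[2L] != 25)
    stop("second cutpoint must be 25 so five-level nests the clinical cutoff")
  breaks <- c(0, cutpoints, 100)
  as.integer(cut(mP, breaks = breaks, right = TRUE,
                 include.lowest = TRUE, labels = FALSE)) - 1L
}

#' Decile bin of the mean percentile
#'
#' Bins mP into the ten categories 0-10%, 10-20%, ..., 90-100%. Bins are
#' right-closed to match the Low cutoff convention (mP = 10 falls in bin 0;
#' mP = 100 in bin 9).
#'
#' @param mP Numeric vector of mean percentiles in \[0, 100\].
#' @return Integer vector with values 0-9.
#' @export
decile_bin <- function(mP) {
  check_mp(mP)
  b <- as.integer(ceiling(mP / 10)) - 1L
  pmin(pmax(b, 0L), 9L)
}

#' Score a cohort of density profiles against a reference distribution
#'
#' Converts each case's four raw densities to percentiles against the
#' reference cohort, averages them into the mean percentile mP, and applies
#' the two-level (clinical), five-level, and decile classifications.
#'
#' @param densities Long-format density table (see
#'   [reference_distribution()]); each case must have exactly the four
#'   marker x region values.
#' @param ref A `ref_dist` object.
#' @param cutpoints Internal five-level cutpoints, see
#'   [classify_five_level()].
#' @return Data.frame of class `is_result` with columns `case_id`,
#'   `p_cd3_ct`, `p_cd3_im`, `p_cd8_ct`, `p_cd8_im`, `mP`, `is2`, `is5`,
#'   `decile_bin`.
#' @export
score_cases <- function(densities, ref, cutpoints = c(10, 25, 70, 95)) {
  if (!inherits(ref, "ref_dist")) stop("ref must be a ref_dist object")
  densities <- validate_density_table(densities)
  key <- paste(densities$marker, densities$region, sep = ".")
  cases <- unique(densities$case_id)
  mat <- matrix(NA_real_, nrow = length(cases), ncol = 4L,
                dimnames = list(NULL, is_channels()))
  idx <- cbind(match(densities$case_id, cases), match(key, is_channels()))
  if (anyNA(idx)) stop("unrecognized marker/region combination")
  if (anyDuplicated(idx))
    stop("duplicate density rows for the same case and channel")
  mat[idx] <- densities$density
  if (anyNA(mat)) {
    bad <- cases[apply(mat, 1L, anyNA)]
    stop("incomplete density profile for case(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  pct <- vapply(is_channels(),
                function(ch) empirical_percentile(mat[, ch], ref[[ch]]),
                numeric(length(cases)))
  pct <- matrix(pct, nrow = length(cases),
                dimnames = list(NULL, is_channels()))
  mP <- rowMeans(pct)
  res <- data.frame(
    case_id = cases,
    p_cd3_ct = pct[, "CD3.CT"],
    p_cd3_im = pct[, "CD3.IM"],
    p_cd8_ct = pct[, "CD8.CT"],
    p_cd8_im = pct[, "CD8.IM"],
    mP = mP,
    is2 = classify_two_level(mP),
    is5 = classify_five_level(mP, cutpoints),
    decile_bin = decile_bin(mP),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("is_result", "data.frame")
  res
}

#' Read a density CSV
#'
#' Expected header: `case_id,marker,region,density` with marker in
#' CD3/CD8, region in CT/IM, density in cells/mm^2.
#'
#' @param path Path to the CSV file.
#' @return Validated density data.frame.
#' @export
read_density_csv <- function(path) {
  validate_density_table(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(case_id = "character")))
}

#' Write scored cases to CSV
#'
#' @param x An `is_result` data.frame from [score_cases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_is_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
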