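#' Derive a reproducible substream seed from a master seed
#'
#' One master seed spawns named substreams (cohort, rater x phase, repeats)
#' so that, e.g., adding raters never perturbs the simulated cohort. The
#' derived seed is a deterministic 31-bit hash of the master seed and the
#' stream name.
#'
#' @param master Integer master seed.
#' @param name Character stream name, e.g. `"cohort"` or `"rater:P1:before"`.
#' @return An integer seed in \[0, 2^31 - 1).
#' @export
substream_seed <- function(master, name) {
  m <- 2147483647          # 2^31 - 1 (prime)
  h <- as.numeric(master) %% m
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer(h)
}

#' Parameters of the synthetic reference cohort
#'
#' Per-channel densities are log-normal: log-densities are multivariate
#' normal with a separable correlation structure (one correlation between
#' markers within a region, one between regions within a marker). Default
#' channel means put the invasive margin above the tumor center for both
#' markers, as observed in colon tumors, with CD3+ denser than CD8+.
#'
#' @param n_reference Number of reference cases (default 1000).
#' @param mean_log_density Named numeric vector of log-scale means for the
#'   channels `CD3.CT`, `CD3.IM`, `CD8.CT`, `CD8.IM` (log cells/mm^2).
#' @param sd_log_density Common log-scale standard deviation (> 0).
#' @param corr_markers Correlation between CD3 and CD8 log-densities within
#'   a region, in \[-1, 1\] (default 0.7).
#' @param corr_regions Correlation between CT and IM log-densities within a
#'   marker, in \[-1, 1\] (default 0.5).
#' @param seed Integer seed for the cohort substream.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_reference = 1000,
                          mean_log_density = c(CD3.CT = log(500),
                                               CD3.IM = log(800),
                                               CD8.CT = log(200),
                                               CD8.IM = log(400)),
                          sd_log_density = 0.9,
                          corr_markers = 0.7,
                          corr_regions = 0.5,
                          seed = 1L) {
  stopifnot(n_reference >= 1, sd_log_density >= 0,
            abs(corr_markers) <= 1, abs(corr_regions) <= 1)
  mean_log_density <- mean_log_density[is_channels()]
  if (anyNA(mean_log_density))
    stop("mean_log_density must name all four channels: ",
         paste(is_channels(), collapse = ", "))
  p <- list(n_reference = as.integer(n_reference),
            mean_log_density = mean_log_density,
            sd_log_density = sd_log_density,
            corr_markers = corr_markers,
            corr_regions = corr_regions,
            seed = as.integer(seed))
  ev <- eigen(cohort_cov(p), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied covariance matrix is not positive semi-definite")
  structure(p, class = "cohort_params")
}

# Separable marker x region correlation: Kronecker product of the two 2x2
# correlation matrices, hence PSD whenever each factor is.
cohort_cov <- function(params) {
  Rm <- matrix(c(1, params$corr_markers, params$corr_markers, 1), 2)
  Rr <- matrix(c(1, params$corr_regions, params$corr_regions, 1), 2)
  R <- kronecker(Rm, Rr)   # channel order CD3.CT, CD3.IM, CD8.CT, CD8.IM
  dimnames(R) <- list(is_channels(), is_channels())
  params$sd_log_density^2 * R
}

#' Generate a synthetic reference cohort of density profiles
#'
#' Draws log-normal densities for the four channels under the correlation
#' structure of [cohort_params()]. Output is the long density table used
#' throughout the package.
#'
#' @param params A `cohort_params` object.
#' @return Long data.frame with columns `case_id`, `marker`, `region`,
#'   `density`.
#' @export
generate_reference_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    params <- do.call(cohort_params, as.list(params))
  set.seed(substream_seed(params$seed, "cohort"))
  n <- params$n_reference
  S <- cohort_cov(params)
  logd <- MASS::mvrnorm(n, mu = params$mean_log_density, Sigma = S)
  logd <- matrix(logd, nrow = n, dimnames = list(NULL, is_channels()))
  ids <- sprintf("REF%04d", seq_len(n))
  long <- expand.grid(case_id = ids, channel = is_channels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(long$channel, ".", fixed = TRUE))
  data.frame(case_id = long$case_id,
             marker = parts[, 1L],
             region = parts[, 2L],
             density = exp(logd[cbind(match(long$case_id, ids),
                                      match(long$channel, is_channels()))]),
             stringsAsFactors = FALSE)
}

#' Parameters of a simulated pathologist rater
#'
#' The rater perceives each case's mean percentile with an additive bias and
#' Gaussian noise (both in percentile points) and applies personal
#' thresholds: perceived scores at or below `tau_low` are called Low, above
#' `tau_high` High, otherwise Intermediate. Training pulls `tau_low` toward
#' the clinical 25 cutoff and `tau_high` toward the 70 anchor with the same
#' `learning_rate` (negative rates model raters whose concordance worsens),
#' and rescales the noise by `noise_shrink`.
#'
#' @param rater_id Identifier string.
#' @param bias Additive perception bias, percentile points.
#' @param noise_sd Perception noise SD, percentile points (>= 0).
#' @param tau_low Perceived Low/Intermediate threshold, in (0, 100).
#' @param tau_high Perceived Intermediate/High threshold, in
#'   (`tau_low`, 100).
#' @param learning_rate Training pull in \[-0.5, 1\]; 1 recalibrates the
#'   thresholds exactly, negative values move them away.
#' @param noise_shrink Post-training multiplier on `noise_sd`, in (0, 2\].
#' @return A list of class `rater_params`.
#' @export
rater_params <- function(rater_id, bias = 0, noise_sd = 10,
                         tau_low = 25, tau_high = 70,
                         learning_rate = 0.5, noise_shrink = 0.8) {
  stopifnot(noise_sd >= 0, tau_low > 0, tau_low < 100,
            tau_high > tau_low, tau_high < 100,
            learning_rate >= -0.5, learning_rate <= 1,
            noise_shrink > 0, noise_shrink <= 2)
  structure(list(rater_id = as.character(rater_id), bias = bias,
                 noise_sd = noise_sd, tau_low = tau_low,
                 tau_high = tau_high, learning_rate = learning_rate,
                 noise_shrink = noise_shrink),
            class = "rater_params")
}

#' Effective rater parameters in a given phase
#'
#' @param rater A `rater_params` object.
#' @param phase `"before"` or `"after"` (training).
#' @return List with `tau_low`, `tau_high`, `noise_sd` as used in `phase`.
#' @export
rater_phase_params <- function(rater, phase = c("before", "after")) {
  phase <- match.arg(phase)
  if (phase == "before")
    return(list(tau_low = rater$tau_low, tau_high = rater$tau_high,
                noise_sd = rater$noise_sd))
  list(tau_low = rater$tau_low + rater$learning_rate * (25 - rater$tau_low),
       tau_high = rater$tau_high + rater$learning_rate * (70 - rater$tau_high),
       noise_sd = rater$noise_sd * rater$noise_shrink)
}

#' Simulate one rater's visual calls on a set of scored cases
#'
#' Each case's perceived score is `mP + bias + noise`; the rater's
#' thresholds produce a 3-level overall call (Low/Intermediate/High), and
#' the 2-level T-score follows the clinical mapping (Intermediate joins
#' High, mirroring the IS-High percentile range). A perceived score equal to
#' `tau_low` is called Low, matching the inclusive <= 25 clinical cutoff.
#'
#' @param cases An `is_result` data.frame from [score_cases()].
#' @param rater A `rater_params` object.
#' @param phase `"before"` or `"after"` training.
#' @param seed Master seed; the draw uses the `"rater:<id>:<phase>"`
#'   substream so each (rater, phase) panel is independent.
#' @return Data.frame with columns `case_id`, `rater_id`, `phase`, `call3`,
#'   `tscore2`.
#' @export
simulate_rater_calls <- function(cases, rater, phase = c("before", "after"),
                                 seed = 1L) {
  phase <- match.arg(phase)
  if (!inherits(rater, "rater_params"))
    rater <- do.call(rater_params, as.list(rater))
  pp <- rater_phase_params(rater, phase)
  set.seed(substream_seed(seed, paste("rater", rater$rater_id, phase,
                                      sep = ":")))
  eps <- if (pp$noise_sd > 0)
    stats::rnorm(nrow(cases), 0, pp$noise_sd) else numeric(nrow(cases))
  s <- cases$mP + rater$bias + eps
  call3 <- ifelse(s <= pp$tau_low, "Low",
                  ifelse(s > pp$tau_high, "High", "Intermediate"))
  call3 <- factor(call3, levels = c("Low", "Intermediate", "High"))
  data.frame(case_id = cases$case_id,
             rater_id = rater$rater_id,
             phase = phase,
             call3 = call3,
             tscore2 = three_to_two_class(call3),
             stringsAsFactors = FALSE)
}

#' Simulate a full rater panel across both phases
#'
#' @param cases An `is_result` data.frame.
#' @param raters List of `rater_params`.
#' @param seed Master seed (substreams per rater and phase).
#' @return Ratings table: one row per (case, rater, phase).
#' @export
simulate_rater_panel <- function(cases, raters, seed = 1L) {
  rows <- lapply(raters, function(r) {
    rbind(simulate_rater_calls(cases, r, "before", seed),
          simulate_rater_calls(cases, r, "after", seed))
  })
  do.call(rbind, rows)
}

#' Parameters of repeated automated measurements
#'
#' @param n_repeats Number of repeated runs per case (default 3).
#' @param measurement_sd Run-to-run SD of the measured mean percentile,
#'   percentile points (default 1.5).
#' @param seed Integer seed for the repeats substream.
#' @return A list of class `repeat_params`.
#' @export
repeat_params <- function(n_repeats = 3, measurement_sd = 1.5, seed = 1L) {
  stopifnot(n_repeats >= 1, measurement_sd >= 0)
  structure(list(n_repeats = as.integer(n_repeats),
                 measurement_sd = measurement_sd,
                 seed = as.integer(seed)),
            class = "repeat_params")
}

#' Simulate repeated automated scoring runs
#'
#' Each repeat perturbs every case's reference mean percentile with
#' independent Gaussian measurement noise, clamps to \[0, 100\], and
#' re-applies the two-level classification. With the default 1.5-point SD,
#' discordant repeats arise only for cases near the 25 cutoff.
#'
#' @param cases An `is_result` data.frame.
#' @param params A `repeat_params` object.
#' @return Data.frame with columns `case_id`, `repeat_id` (`"DP1"`, ...),
#'   `mP`, `is2`.
#' @export
simulate_repeat_measurements <- function(cases, params = repeat_params()) {
  if (!inherits(params, "repeat_params"))
    params <- do.call(repeat_params, as.list(params))
  set.seed(substream_seed(params$seed, "repeats"))
  out <- lapply(seq_len(params$n_repeats), function(r) {
    eta <- if (params$measurement_sd > 0)
      stats::rnorm(nrow(cases), 0, params$measurement_sd)
    else numeric(nrow(cases))
    mP <- pmin(pmax(cases$mP + eta, 0), 100)
    data.frame(case_id = cases$case_id,
               repeat_id = sprintf("DP%d", r),
               mP = mP,
               is2 = classify_two_level(mP),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Load a simulation/analysis configuration
#'
#' Reads a JSON configuration with blocks `cohort`, `raters`, `repeats`,
#' `selection`, and `impact`. With `path = NULL` the packaged default
#' configuration is used; its rater panel is calibrated so the simulated
#' study lands in a realistic concordance regime (mean rater-vs-reference
#' kappa in the weak band before training, higher after).
#'
#' @param path Path to a JSON config, or `NULL` for the packaged default.
#' @return Nested list with typed parameter objects under `cohort`,
#'   `raters`, `repeats`, plus raw `selection` and `impact` blocks.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.json",
                        package = "immunoconcord", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- list()
  cohort <- as.list(raw$cohort)
  if (!is.null(cohort$mean_log_density))
    cohort$mean_log_density <- unlist(cohort$mean_log_density)
  cfg$cohort <- do.call(cohort_params, cohort)
  raters <- raw$raters
  if (is.data.frame(raters))
    raters <- split(raters, seq_len(nrow(raters)))
  cfg$raters <- lapply(raters, function(r)
    do.call(rater_params, as.list(r)[names(as.list(r)) != ""]))
  names(cfg$raters) <- vapply(cfg$raters, `[[`, "", "rater_id")
  cfg$repeats <- do.call(repeat_params, as.list(raw$repeats))
  cfg$selection <- as.list(raw$selection)
  cfg$impact <- as.list(raw$impact)
  cfg
}
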