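#' Run the full concordance study pipeline
#'
#' Orchestrates the end-to-end analysis: simulate a reference cohort, score
#' it against itself, draw the decile-stratified 50-case set and the
#' 20-case around-cutoff subset, simulate the 4-rater panel before and
#' after training, compute all rater-vs-reference and inter-rater agreement
#' statistics, evaluate repeatability of repeated automated runs, and
#' propagate the observed worst-case agreement rates through the clinical
#' decision tree. All tables are written as CSV, the numeric report and the
#' run manifest as JSON; re-running with the same configuration and seed
#' reproduces the outputs byte for byte.
#'
#' @param config Path to a JSON configuration, or `NULL` for the packaged
#'   default.
#' @param seed Master seed; all randomness (cohort, selection, each
#'   rater x phase panel, repeats) flows through named substreams of it.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param subset `"all"` to analyze both case sets, `"cutoff20"` to
#'   restrict agreement outputs to the around-cutoff subset.
#' @return List of class `run_manifest`: `seed`, `config` (path),
#'   `config_digest` (MD5), `results` (all computed objects), `files`
#'   (written file inventory with MD5 sums).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = NULL,
                         subset = c("all", "cutoff20")) {
  subset <- match.arg(subset)
  config_path <- if (is.null(config))
    system.file("extdata", "default_config.json",
                package = "immunoconcord", mustWork = TRUE) else config
  cfg <- load_config(config_path)
  cfg$cohort$seed <- as.integer(seed)
  cfg$repeats$seed <- as.integer(seed)

  densities <- generate_reference_cohort(cfg$cohort)
  ref <- reference_distribution(densities)
  pool <- score_cases(densities, ref)

  n_per_bin <- cfg$selection$n_per_bin %||% 5
  n_per_side <- cfg$selection$n_per_side %||% 10
  full50 <- stratified_sample(pool, n_per_bin = n_per_bin, seed = seed)
  cutoff20 <- cutoff_subset(full50, n_per_side = n_per_side)

  ratings <- simulate_rater_panel(full50, cfg$raters, seed = seed)
  repeats <- simulate_repeat_measurements(full50, cfg$repeats)

  case_sets <- if (subset == "cutoff20")
    list(cutoff_20 = cutoff20)
  else list(full_50 = full50, cutoff_20 = cutoff20)

  phases <- c("before", "after")
  rater_ids <- names(cfg$raters)

  # per-rater agreement vs reference (Fig 1 analogue)
  rater_rows <- list()
  for (set_name in names(case_sets)) {
    cs <- case_sets[[set_name]]
    for (ph in phases) for (rid in rater_ids) {
      sl <- ratings[ratings$phase == ph & ratings$rater_id == rid &
                      ratings$case_id %in% cs$case_id, ]
      sl <- sl[match(cs$case_id, sl$case_id), ]
      s <- agreement_summary(sl$tscore2, cs$is2)
      rater_rows[[length(rater_rows) + 1L]] <- data.frame(
        case_set = set_name, phase = ph, rater_id = rid, n = nrow(cs),
        percent_agreement = s$percent_agreement, kappa = s$kappa,
        band = as.character(s$band), ppa = s$ppa, npa = s$npa,
        sensitivity = s$sensitivity, ppv = s$ppv,
        stringsAsFactors = FALSE)
    }
  }
  rater_agreement <- do.call(rbind, rater_rows)

  # inter-rater Fleiss kappa on 2-level T-scores (Fig 3 analogue)
  fleiss_rows <- list()
  for (set_name in names(case_sets)) {
    cs <- case_sets[[set_name]]
    for (ph in phases) {
      m <- sapply(rater_ids, function(rid) {
        sl <- ratings[ratings$phase == ph & ratings$rater_id == rid, ]
        as.character(sl$tscore2[match(cs$case_id, sl$case_id)])
      })
      k <- fleiss_kappa(m, categories = c("Low", "High"))
      fleiss_rows[[length(fleiss_rows) + 1L]] <- data.frame(
        case_set = set_name, phase = ph, n_cases = nrow(cs),
        n_raters = length(rater_ids), fleiss_kappa = k,
        band = as.character(interpret_kappa(k)), stringsAsFactors = FALSE)
    }
  }
  fleiss <- do.call(rbind, fleiss_rows)

  # panel disagreement with the reference (Fig 4 analogue)
  disagree_rows <- list()
  for (set_name in names(case_sets)) {
    cs <- case_sets[[set_name]]
    for (ph in phases) {
      sl <- ratings[ratings$phase == ph & ratings$case_id %in% cs$case_id, ]
      d <- overall_disagreement_rate(sl, cs)
      disagree_rows[[length(disagree_rows) + 1L]] <- data.frame(
        case_set = set_name, phase = ph, n_cases = nrow(cs),
        n_discordant = d$n_discordant, percent = d$percent,
        stringsAsFactors = FALSE)
    }
  }
  disagreement <- do.call(rbind, disagree_rows)

  # impact of training per (rater, case) (Fig 2 analogue), full set
  impact_set <- case_sets[[1L]]
  ti <- training_impact_types(
    ratings[ratings$phase == "before" &
              ratings$case_id %in% impact_set$case_id, ],
    ratings[ratings$phase == "after" &
              ratings$case_id %in% impact_set$case_id, ],
    impact_set)

  # repeatability (Fig 5 analogue), always on the full 50-case set
  repeatability <- repeat_concordance(repeats, full50)

  # decision-tree impact (Fig 6 analogue): worst observed NPA/PPA before
  # training, annual counts from the mean per-rater disagreement per phase
  scen <- do.call(population_scenario, cfg$impact)
  ra_before <- rater_agreement[rater_agreement$phase == "before" &
                                 rater_agreement$case_set == names(case_sets)[1L], ]
  ra_after <- rater_agreement[rater_agreement$phase == "after" &
                                rater_agreement$case_set == names(case_sets)[1L], ]
  worst_npa <- min(ra_before$npa, na.rm = TRUE)
  worst_ppa <- min(ra_before$ppa, na.rm = TRUE)
  rate_before <- 1 - mean(ra_before$percent_agreement) / 100
  rate_after <- 1 - mean(ra_after$percent_agreement) / 100
  impact <- impact_report(npa = worst_npa, ppa = worst_ppa, scenario = scen,
                          misclass_rate_stage2 = rate_before,
                          misclass_rate_stage3 = rate_before)
  annual_after <- annual_misclassified(scen, rate_after, rate_after)

  results <- list(pool = pool, full50 = full50, cutoff20 = cutoff20,
                  ratings = ratings, repeats = repeats,
                  rater_agreement = rater_agreement, fleiss = fleiss,
                  disagreement = disagreement, training_impact = ti,
                  repeatability = repeatability, impact = impact,
                  annual_misclassified_after = annual_after)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(as.data.frame(obj), p, row.names = FALSE,
                       quote = FALSE)
      p
    }
    files <- c(
      wr(full50, "cases_full50.csv"),
      wr(cutoff20, "cases_cutoff20.csv"),
      wr(ratings, "ratings.csv"),
      wr(repeats, "repeats.csv"),
      wr(rater_agreement, "rater_agreement.csv"),
      wr(fleiss, "fleiss.csv"),
      wr(disagreement, "disagreement.csv"),
      wr(ti$types, "training_impact_types.csv"))
    report <- list(
      seed = as.integer(seed),
      fleiss = fleiss, disagreement = disagreement,
      training_impact_percent = as.list(ti$percent),
      repeatability = list(
        per_repeat_agreement = as.list(repeatability$per_repeat_agreement),
        pooled_agreement = repeatability$pooled_agreement,
        case_level_agreement = repeatability$case_level_agreement,
        pooled_kappa = repeatability$pooled_kappa,
        discordant = repeatability$discordant),
      impact = unclass(impact),
      annual_misclassified_after = annual_after)
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, rp)
  }

  manifest <- list(seed = as.integer(seed),
                   config = config_path,
                   config_digest = unname(tools::md5sum(config_path)),
                   results = results,
                   files = if (length(files))
                     data.frame(file = basename(files),
                                md5 = unname(tools::md5sum(files)),
                                stringsAsFactors = FALSE)
                   else NULL)
  class(manifest) <- "run_manifest"
  if (!is.null(out_dir)) {
    mf <- manifest
    mf$results <- NULL
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("concordance pipeline run (seed", x$seed, ")\n")
  print(x$results$disagreement)
  print(x$results$fleiss)
  print(x$results$repeatability)
  print(x$results$impact)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
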