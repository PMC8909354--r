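# Independent oracles, kept deliberately naive: direct formula evaluation
# on explicit tallies, and Scott's pi for the two-rater case.

oracle_cohen <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}

oracle_scott_pi <- function(r1, r2, categories) {
  n <- length(r1)
  po <- mean(r1 == r2)
  pc <- sapply(categories, function(ct) (sum(r1 == ct) + sum(r2 == ct)) / (2 * n))
  pe <- sum(pc^2)
  (po - pe) / (1 - pe)
}

test_that("3-level calls collapse to the clinical 2-level T-score", {
  expect_equal(as.character(three_to_two_class(
    c("Low", "Intermediate", "High"))), c("Low", "High", "High"))
  expect_error(three_to_two_class("Medium"), "unknown")
})

test_that("confusion tables tally reference/call pairs exhaustively", {
  ref <- c("Low", "Low", "Low", "High", "High", "High")
  call <- c("Low", "High", "Low", "Low", "High", "High")
  t <- confusion_table(call, ref)
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 1, 2))
  expect_equal(t$n, 6)
  # order-invariance
  o <- sample(6)
  t2 <- confusion_table(call[o], ref[o])
  expect_equal(unclass(t)[1:5], unclass(t2)[1:5])
  # identical and complementary vectors
  ti <- confusion_table(ref, ref)
  expect_equal(ti$b + ti$c, 0)
  tc <- confusion_table(ifelse(ref == "Low", "High", "Low"), ref)
  expect_equal(tc$a + tc$d, 0)
  expect_error(confusion_table(call[1:3], ref), "different case sets")
})

test_that("percent agreement and Cohen's kappa match hand evaluation", {
  t <- confusion_counts(12, 3, 6, 29)
  expect_equal(percent_agreement(t), 82)
  # p_o = 0.82, p_e = (15*18 + 35*32)/2500 = 0.556
  expect_equal(cohen_kappa(t), (0.82 - 0.556) / (1 - 0.556),
               tolerance = 1e-12)
  expect_equal(round(cohen_kappa(t), 4), 0.5946)
  expect_equal(cohen_kappa(confusion_counts(10, 0, 0, 40)), 1)
  expect_equal(cohen_kappa(confusion_counts(0, 25, 25, 0)), -1)
  expect_equal(percent_agreement(confusion_counts(0, 1, 1, 0)), 0)
})

test_that("Cohen's kappa agrees with oracles on random tables", {
  set.seed(31)
  for (i in 1:200) {
    cnt <- as.vector(rmultinom(1, sample(5:80, 1), runif(4, 0.05, 1)))
    t <- confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    k_or <- oracle_cohen(cnt[1], cnt[2], cnt[3], cnt[4])
    if (!is.finite(k_or)) next  # degenerate margins handled separately
    expect_equal(cohen_kappa(t), k_or, tolerance = 1e-12)
    expect_true(cohen_kappa(t) >= -1 - 1e-12 && cohen_kappa(t) <= 1 + 1e-12)
    # transpose invariance (swap the two raters: b <-> c)
    expect_equal(cohen_kappa(confusion_counts(cnt[1], cnt[3], cnt[2], cnt[4])),
                 cohen_kappa(t), tolerance = 1e-12)
  }
  if (requireNamespace("e1071", quietly = TRUE)) {
    t <- confusion_counts(12, 3, 6, 29)
    m <- matrix(c(12, 3, 6, 29), 2, byrow = TRUE)
    expect_equal(cohen_kappa(t), e1071::classAgreement(m)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("degenerate unanimous margins return the flagged convention", {
  expect_warning(k <- cohen_kappa(confusion_counts(10, 0, 0, 0)), "degenerate")
  expect_equal(k, 1)
  # one degenerate margin is not enough: perfect disagreement with all-Low
  # reference evaluates to 0 through the ordinary formula (p_o = p_e = 0)
  expect_equal(cohen_kappa(confusion_counts(0, 10, 0, 0)), 0)
  expect_warning(kf <- fleiss_kappa(matrix("Low", 4, 3)), "degenerate")
  expect_equal(kf, 1)
})

test_that("Fleiss' kappa matches hand evaluation and Scott's pi at k = 2", {
  # unanimity across raters
  m <- cbind(rep(c("Low", "High"), 5), rep(c("Low", "High"), 5))
  expect_equal(fleiss_kappa(m), 1)
  # 3 cases x 2 raters with count rows (2,0), (1,1), (0,2):
  # P_bar = 2/3, Pe = 1/2, kappa = 1/3
  m2 <- rbind(c("A", "A"), c("A", "B"), c("B", "B"))
  expect_equal(fleiss_kappa(m2), 1 / 3, tolerance = 1e-12)
  # Scott's pi equivalence on 200 random two-rater tables
  set.seed(17)
  cats <- c("Low", "Intermediate", "High")
  for (i in 1:200) {
    n <- sample(4:40, 1)
    r1 <- sample(cats, n, replace = TRUE)
    r2 <- ifelse(runif(n) < 0.6, r1, sample(cats, n, replace = TRUE))
    pi_or <- oracle_scott_pi(r1, r2, cats)
    if (!is.finite(pi_or)) next
    expect_equal(fleiss_kappa(cbind(r1, r2), categories = cats), pi_or,
                 tolerance = 1e-12)
  }
  expect_error(fleiss_kappa(cbind(r1 = "Low", r2 = NA)), "missing")
  expect_error(fleiss_kappa(matrix("Low", 3, 1)), "at least 2")
})

test_that("PPA/NPA and sensitivity/PPV have the IS-High orientation", {
  t <- confusion_counts(4, 12, 21, 79)
  pn <- ppa_npa(t)
  expect_equal(unname(pn["npa"]), 25)
  expect_equal(unname(pn["ppa"]), 79)
  sp <- sensitivity_ppv(confusion_counts(14, 1, 2, 33))
  expect_equal(unname(round(sp["sensitivity"], 1)), 94.3)
  expect_equal(unname(round(sp["ppv"], 1)), 97.1)
  perfect <- confusion_counts(10, 0, 0, 40)
  expect_equal(unname(ppa_npa(perfect)), c(100, 100))
  expect_equal(unname(sensitivity_ppv(perfect)), c(100, 100))
  expect_equal(unname(sensitivity_ppv(confusion_counts(5, 0, 3, 0))["sensitivity"]), 0)
  expect_true(is.na(ppa_npa(confusion_counts(0, 0, 3, 4))["npa"]))
})

test_that("percent agreement decomposes as the PPA/NPA weighted identity", {
  set.seed(13)
  for (i in 1:50) {
    cnt <- as.vector(rmultinom(1, sample(10:100, 1), runif(4)))
    if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[4] == 0) next
    t <- confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    pn <- ppa_npa(t)
    n_low <- cnt[1] + cnt[2]; n_high <- cnt[3] + cnt[4]
    expect_equal(percent_agreement(t),
                 (pn[["npa"]] * n_low + pn[["ppa"]] * n_high) / t$n,
                 tolerance = 1e-12)
  }
})

test_that("kappa interpretation bands are correct and monotone", {
  expect_equal(as.character(interpret_kappa(c(0.34, 0.57, 0.93))),
               c("minimal", "weak", "almost perfect"))
  expect_equal(as.character(interpret_kappa(c(-0.4, 0, 0.20, 0.21, 0.39,
                                              0.40, 0.59, 0.60, 0.79,
                                              0.80, 0.90, 0.91, 1))),
               c("none", "none", "none", "minimal", "minimal",
                 "weak", "weak", "moderate", "moderate",
                 "strong", "strong", "almost perfect", "almost perfect"))
  grid <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(as.integer(interpret_kappa(grid))) >= 0))
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("panel disagreement counts cases with any discordant rater", {
  cases <- make_cases50()
  perfect <- make_panel(cases, c("P1", "P2"), "before")
  d0 <- overall_disagreement_rate(perfect, cases)
  expect_equal(d0$n_discordant, 0)
  expect_equal(d0$percent, 0)
  # brute-force oracle on random small panels
  set.seed(41)
  for (i in 1:20) {
    cs <- make_cases(runif(5, 0, 100))
    raters <- c("R1", "R2")
    grid <- expand.grid(case_id = cs$case_id, rater_id = raters,
                        stringsAsFactors = FALSE)
    flips <- grid[runif(nrow(grid)) < 0.3, ]
    panel <- make_panel(cs, raters, "before", flips)
    d <- overall_disagreement_rate(panel, cs)
    expect_equal(d$n_discordant, length(unique(flips$case_id)))
  }
  expect_error(overall_disagreement_rate(perfect[-1, ], cases),
               "incomplete")
})

test_that("training impact types tally the four concordance transitions", {
  cases <- make_cases50()
  raters <- c("P1", "P2")
  same <- make_panel(cases, raters, "before")
  all_wrong <- make_panel(cases, raters, "before",
                          flips = expand.grid(case_id = cases$case_id,
                                              rater_id = raters,
                                              stringsAsFactors = FALSE))
  t1 <- training_impact_types(same, same, cases)
  expect_equal(unname(t1$percent["type1"]), 100)
  t3 <- training_impact_types(all_wrong, same, cases)
  expect_equal(unname(t3$percent["type3"]), 100)
  # random panels against a brute-force 4-way tally
  set.seed(59)
  for (i in 1:20) {
    cs <- make_cases(runif(6, 0, 100))
    grid <- expand.grid(case_id = cs$case_id, rater_id = raters,
                        stringsAsFactors = FALSE)
    fb <- grid[runif(nrow(grid)) < 0.4, ]
    fa <- grid[runif(nrow(grid)) < 0.4, ]
    before <- make_panel(cs, raters, "before", fb)
    after <- make_panel(cs, raters, "after", fa)
    res <- training_impact_types(before, after, cs)
    keyb <- paste(grid$case_id, grid$rater_id) %in% paste(fb$case_id, fb$rater_id)
    keya <- paste(grid$case_id, grid$rater_id) %in% paste(fa$case_id, fa$rater_id)
    exp_type <- ifelse(!keyb & !keya, 1, ifelse(keyb & keya, 2,
                                                ifelse(keyb & !keya, 3, 4)))
    expect_equal(sort(res$types$type), sort(exp_type))
    expect_equal(sum(res$percent), 100)
  }
})
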