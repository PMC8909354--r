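test_that("empirical percentile follows the plotting-position convention", {
  ref <- sort(c(12, 40, 7, 55, 90, 23, 64, 31, 77, 48))  # 10 distinct values
  # value equal to the i-th order statistic -> 100 * (i - 0.5) / 10
  expect_equal(empirical_percentile(ref[3], ref), 25.0)
  expect_equal(empirical_percentile(ref[7], ref), 65.0)
  # median of an odd-sized reference -> 50
  odd <- sort(c(5, 11, 19, 42, 73))
  expect_equal(empirical_percentile(19, odd), 50)
  # clamping outside the reference range
  expect_equal(empirical_percentile(0, ref), 0)
  expect_equal(empirical_percentile(1e6, ref), 100)
  expect_equal(empirical_percentile(min(ref), ref), 5)    # (1-0.5)/10
  # linear interpolation between order statistics
  expect_equal(empirical_percentile(mean(ref[3:4]), ref), 30.0)
})

test_that("tied reference values share the mean of their plotting positions", {
  ref <- c(1, 2, 2, 2, 3)
  # positions (i-0.5)/5 = .1 .3 .5 .7 .9; the three 2s average to 0.5
  expect_equal(empirical_percentile(2, ref), 50)
  expect_equal(empirical_percentile(1, ref), 10)
  expect_equal(empirical_percentile(3, ref), 90)
})

test_that("percentile conversion is monotone and self-uniform", {
  set.seed(42)
  ref <- sort(rlnorm(1000, 6, 0.9))
  x <- sort(runif(200, 0, max(ref) * 1.1))
  p <- empirical_percentile(x, ref)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 100))
  # reference against itself is uniform: KS statistic well under 0.05
  selfp <- empirical_percentile(ref, ref) / 100
  ks <- suppressWarnings(ks.test(selfp, "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("percentile input validation rejects bad references and densities", {
  expect_error(empirical_percentile(1, numeric(0)), "empty")
  expect_error(empirical_percentile(1, 5), "at least 2")
  expect_error(empirical_percentile(-1, c(1, 2)), "non-negative")
  expect_error(empirical_percentile(1, c(3, 1, 2)), "sorted")
})

test_that("mean percentile is the arithmetic mean of four channels", {
  expect_equal(mean_percentile(c(25, 25, 25, 25)), 25)
  expect_equal(mean_percentile(c(0, 0, 100, 100)), 50)
  expect_equal(mean_percentile(c(10, 20, 30, 40)), 25)
  expect_error(mean_percentile(c(10, 20, 30)), "4 percentile")
  expect_error(mean_percentile(c(10, 20, 30, 101)), "\\[0, 100\\]")
})

test_that("two-level classification is inclusive at the 25 cutoff", {
  expect_equal(as.character(classify_two_level(c(21.2, 26.2, 25, 0, 100))),
               c("Low", "High", "Low", "Low", "High"))
  expect_error(classify_two_level(125), "\\[0, 100\\]")
})

test_that("five-level bins nest the two-level classification", {
  expect_equal(classify_five_level(0), 0L)
  expect_equal(classify_five_level(25), 1L)
  expect_equal(classify_five_level(100), 4L)
  grid <- seq(0, 100, by = 0.25)
  is5 <- classify_five_level(grid)
  is2 <- classify_two_level(grid)
  expect_equal(is5 <= 1L, is2 == "Low")
  expect_error(classify_five_level(50, cutpoints = c(10, 30, 70, 95)),
               "second cutpoint")
  expect_error(classify_five_level(50, cutpoints = c(25, 10, 70, 95)),
               "ascending")
})

test_that("decile bins are right-closed", {
  expect_equal(decile_bin(c(5, 10, 10.0001, 100, 0)),
               c(0L, 0L, 1L, 9L, 0L))
  expect_equal(decile_bin(10 * (1:10)), 0:9)
})

test_that("raising any single density never lowers percentile, mP, or class", {
  set.seed(7)
  dens <- do.call(rbind, lapply(1:30, function(i)
    make_profile(sprintf("C%02d", i),
                 rlnorm(1, 6.2, 0.9), rlnorm(1, 6.7, 0.9),
                 rlnorm(1, 5.3, 0.9), rlnorm(1, 6.0, 0.9))))
  ref <- reference_distribution(dens)
  base <- score_cases(dens, ref)
  for (ch_row in c(1, 2, 3, 4)) {
    bumped <- dens
    # bump one channel of one case
    idx <- which(dens$case_id == "C05")[ch_row]
    bumped$density[idx] <- bumped$density[idx] * 3
    res <- score_cases(bumped, ref)
    i <- which(res$case_id == "C05")
    expect_gte(res$mP[i], base$mP[which(base$case_id == "C05")])
    expect_gte(as.integer(res$is2[i]),
               as.integer(base$is2[which(base$case_id == "C05")]))
  }
})

test_that("scoring is idempotent and the CSV dialect round-trips", {
  set.seed(11)
  dens <- do.call(rbind, lapply(1:20, function(i)
    make_profile(sprintf("C%02d", i),
                 rlnorm(1, 6.2, 0.9), rlnorm(1, 6.7, 0.9),
                 rlnorm(1, 5.3, 0.9), rlnorm(1, 6.0, 0.9))))
  ref <- reference_distribution(dens)
  r1 <- score_cases(dens, ref)
  r2 <- score_cases(dens, ref)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$mP - rowMeans(
    r1[, c("p_cd3_ct", "p_cd3_im", "p_cd8_ct", "p_cd8_im")])) < 1e-12))

  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(dens, csv, row.names = FALSE)
  expect_equal(read_density_csv(csv)$density, dens$density)
  out <- withr::local_tempfile(fileext = ".csv")
  write_is_csv(r1, out)
  back <- read.csv(out, colClasses = c(case_id = "character"))
  expect_equal(back$mP, r1$mP, tolerance = 1e-12)
})

test_that("incomplete or invalid density profiles are rejected", {
  d <- make_profile("A", 100, 200, 50, 80)
  expect_error(score_cases(d[-2, ], reference_distribution(
    rbind(d, make_profile("B", 10, 20, 5, 8)))), "incomplete")
  bad <- d; bad$density[1] <- -5
  expect_error(reference_distribution(bad), "non-negative")
})
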