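# Hand-computed Wald-interval oracles for the Ry examples:
#   n=1000, p=0.10: se = sqrt(.1*.9/1000) = 0.00948683 -> [0.081406, 0.118594]
#   n=1000, p=0.05: se = sqrt(.05*.95/1000) = 0.00689202 -> [0.036492, 0.063508]
#   n=1000, p=0.01: se = sqrt(.01*.99/1000) = 0.00314643 -> [0.003833, 0.016167]
test_that("compute_ry matches the Wald-interval oracle and classifies", {
  r <- compute_ry(make_counts(n_y = 0, n_x = 5000))
  expect_equal(r$point, 0)
  expect_equal(c(r$ci_low, r$ci_high), c(0, 0))
  expect_equal(r$estimate$sex, "XX")
  expect_equal(r$estimate$certainty, "definitive")

  r <- compute_ry(make_counts(n_y = 100, n_x = 900))
  expect_equal(r$point, 0.1)
  expect_equal(r$ci_low, 0.1 - 1.96 * sqrt(0.1 * 0.9 / 1000))
  expect_equal(r$ci_high, 0.1 + 1.96 * sqrt(0.1 * 0.9 / 1000))
  expect_equal(round(c(r$ci_low, r$ci_high), 4), c(0.0814, 0.1186))
  expect_equal(r$estimate$sex, "XY")
  expect_equal(r$estimate$certainty, "definitive")
  expect_equal(r$n_sex_reads, 1000L)

  r <- compute_ry(make_counts(n_y = 50, n_x = 950))
  expect_equal(round(c(r$ci_low, r$ci_high), 4), c(0.0365, 0.0635))
  expect_equal(r$estimate$sex, "indeterminate")

  r <- compute_ry(make_counts(n_y = 10, n_x = 990))
  expect_equal(round(c(r$ci_low, r$ci_high), 4), c(0.0038, 0.0162))
  expect_equal(r$estimate$sex, "XX")
  expect_equal(r$estimate$certainty, "conditional")
})

test_that("compute_ry handles zero sex reads and sets the low-data flag", {
  r <- compute_ry(make_counts(n_y = 0, n_x = 0, auto_reads = 10))
  expect_equal(r$estimate$sex, "indeterminate")
  expect_match(r$estimate$diagnostic, "no reads")
  expect_true(is.na(r$point))

  # below both minima -> flagged; either minimum satisfied -> not flagged
  expect_true(compute_ry(make_counts(100, 900, auto_reads = 10))$estimate$low_data)
  expect_false(compute_ry(make_counts(400, 2700, auto_reads = 10))$estimate$low_data)
  expect_false(compute_ry(make_counts(100, 900, auto_reads = 5000))$estimate$low_data)
})

test_that("compute_rx recovers dosage exactly in noise-free cases", {
  # rate_X equal to every autosomal rate: all ratios 1, sd 0
  r <- compute_rx(make_counts(n_y = 0, n_x = 4000, auto_reads = 4000))
  expect_equal(r$point, 1.0)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(r$estimate$sex, "XX")
  expect_equal(r$estimate$certainty, "definitive")
  expect_length(r$per_autosome_ratios, 22)

  # half dosage
  r <- compute_rx(make_counts(n_y = 2000, n_x = 2000, auto_reads = 4000))
  expect_equal(r$point, 0.5)
  expect_equal(r$estimate$sex, "XY")
  expect_equal(r$estimate$certainty, "definitive")
})

test_that("compute_rx matches the mean/sd oracle on alternating ratios", {
  # ratios 0.70 x11 and 0.80 x11: mean .75, sd = sqrt(22*.0025/21)
  auto <- rep(c(1200, 1050), 11)     # 840/1200 = .7, 840/1050 = .8
  r <- compute_rx(make_counts(n_y = 0, n_x = 840, auto_reads = auto))
  expect_equal(r$point, 0.75)
  sd_o <- sqrt(sum((rep(c(0.7, 0.8), 11) - 0.75)^2) / 21)
  expect_equal(r$ci_low, 0.75 - 1.96 * sd_o / sqrt(22))
  expect_equal(round(c(r$ci_low, r$ci_high), 3), c(0.729, 0.771))
  expect_equal(r$estimate$sex, "indeterminate")
})

test_that("compute_rx reports autosome dropout as indeterminate", {
  auto <- rep(4000, 22); auto[7] <- 0
  r <- compute_rx(make_counts(0, 4000, auto_reads = auto))
  expect_equal(r$estimate$sex, "indeterminate")
  expect_match(r$estimate$diagnostic, "7")
})

test_that("classify_interval decides the stated geometric cases", {
  mh <- list(bound = 0.075, side = "above")
  fl <- list(bound = 0.016, side = "below")
  expect_equal(classify_interval(0.1, 0.09, 0.12, mh, fl)$certainty, "definitive")
  e <- classify_interval(0.01, 0.004, 0.017, mh, fl)
  expect_equal(c(e$sex, e$certainty), c("XX", "conditional"))
  expect_equal(classify_interval(0.05, 0.01, 0.10, mh, fl)$sex, "indeterminate")
  # endpoint exactly on a threshold counts as crossing
  expect_equal(classify_interval(0.05, 0.02, 0.075, mh, fl)$certainty, "conditional")
  expect_equal(classify_interval(0.01, 0.005, 0.0155, mh, fl)$certainty, "definitive")
  expect_error(classify_interval(0.1, 0.2, 0.1, mh, fl))
})

test_that("classification agrees with the independent geometry oracle", {
  set.seed(42)
  n <- 2000
  for (orient in c("male_high", "female_high")) {
    tf <- if (orient == "male_high") 0.016 else 0.80
    tm <- if (orient == "male_high") 0.075 else 0.60
    lo <- runif(n, -0.05, 1.0)
    hi <- lo + rexp(n, 20)
    # salt with exact-threshold endpoints
    lo[1:4] <- c(tf, tm, tf - 0.01, tm - 0.01)
    hi[1:4] <- c(tf, tm, tf, tm)
    for (i in seq_len(n)) {
      expect_identical(
        classify_with_package(lo[i], hi[i], orient, tf, tm),
        oracle_classify(lo[i], hi[i], orient, tf, tm),
        info = sprintf("%s [%g, %g]", orient, lo[i], hi[i]))
    }
  }
})

test_that("Ry is monotone in added Y reads", {
  pts <- vapply(seq(0, 500, by = 50),
                function(k) compute_ry(make_counts(100 + k, 900))$point,
                numeric(1))
  expect_true(all(diff(pts) >= 0))
})

test_that("downsample_counts preserves totals, proportions and determinism", {
  cc <- make_counts(n_y = 5000, n_x = 50000, auto_reads = 100000)
  expect_equal(as.data.frame(downsample_counts(cc, total_mapped(cc), seed = 1)),
               as.data.frame(cc))
  expect_error(downsample_counts(cc, total_mapped(cc) + 1), "exceeds")

  a <- downsample_counts(cc, 10000, seed = 99)
  b <- downsample_counts(cc, 10000, seed = 99)
  expect_equal(a$mapped, b$mapped)
  expect_equal(total_mapped(a), 10000)

  # sampling-theory oracle: mean per-chromosome fraction over 200 replicates
  # within 3 hypergeometric MC standard errors of the source fraction
  set.seed(7)
  target <- round(total_mapped(cc) * 0.1)
  reps <- replicate(200, downsample_counts(cc, target)$mapped)
  p <- cc$mapped / total_mapped(cc)
  se <- sqrt(p * (1 - p) / target) / sqrt(200)   # conservative (ignores FPC)
  frac <- rowMeans(reps) / target
  expect_true(all(abs(frac - p) <= 3 * se + 1e-12))
})

test_that("depth_reliability_curve degenerates to direct classification", {
  cc <- make_counts(n_y = 5000, n_x = 50000, auto_reads = 100000)
  curve <- depth_reliability_curve(cc, total_mapped(cc), replicates = 3,
                                   seed = 5, statistic = "RY", truth = "XY")
  expect_equal(nrow(curve), 1)
  direct <- compute_ry(cc)
  expect_equal(curve$frac_definitive,
               as.numeric(direct$estimate$certainty == "definitive"))
  expect_error(depth_reliability_curve(cc, integer(0)), "empty")
})

test_that("Ry Wald CI attains nominal coverage on simulated XY cohorts", {
  cfg <- sim_config(seed = 1)
  w <- 2 * hg19_chromosome_lengths()
  w[["X"]] <- hg19_chromosome_lengths()[["X"]]
  w[["Y"]] <- cfg$y_mappability * hg19_chromosome_lengths()[["Y"]]
  p_true <- w[["Y"]] / (w[["X"]] + w[["Y"]])
  set.seed(31)
  draws <- rmultinom(1000, 50000, w / sum(w))
  cover <- vapply(seq_len(ncol(draws)), function(j) {
    cc <- chrom_counts(hg19_chromosome_lengths(),
                       setNames(draws[, j], canonical_chromosomes()))
    r <- compute_ry(cc)
    r$ci_low <= p_true && p_true <= r$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("fixture classification partition is exhaustive per statistic", {
  coh <- load_fixture_cohort()
  sens <- sensitivity_summary(coh)
  expect_true(all(sens$n_definitive + sens$n_conditional +
                    sens$n_indeterminate == nrow(coh)))
})
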