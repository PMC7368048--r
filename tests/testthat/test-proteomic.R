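toy_x <- "MPLPPHPGHPGYINF"
toy_y <- "MPLPPHPGHPGYINL"

test_that("assign_specificity partitions against toy isoforms", {
  expect_equal(assign_specificity("GYINF", toy_x, toy_y), "X_specific")
  expect_equal(assign_specificity("PPHPGHPG", toy_x, toy_y), "shared")
  expect_equal(assign_specificity("WWWW", toy_x, toy_y), "unmatched")
  # vectorized: exactly one label each
  labs <- assign_specificity(c("GYINF", "GYINL", "MPLPP", "KKK"), toy_x, toy_y)
  expect_equal(labs, c("X_specific", "Y_specific", "shared", "unmatched"))
})

test_that("I/L equivalence merges only I/L differences", {
  # F vs L is not an I/L difference: still X-specific under the flag
  expect_equal(assign_specificity("GYINF", toy_x, toy_y, il_equivalent = TRUE),
               "X_specific")
  # the isoforms differ only by trailing F/L here, so under I/L equivalence
  # a peptide ending in L is still Y-specific (X has F)
  expect_equal(assign_specificity("GYINL", toy_x, toy_y, il_equivalent = TRUE),
               "Y_specific")
  # but an I-for-L variant of a shared core becomes shared under the flag
  x2 <- "AAAPILPAAA"; y2 <- "AAAPLLPAAA"
  expect_equal(assign_specificity("PILP", x2, y2), "X_specific")
  expect_equal(assign_specificity("PILP", x2, y2, il_equivalent = TRUE), "shared")
  expect_error(assign_specificity("", toy_x, toy_y), "empty")
})

test_that("strip_modifications handles the common annotation dialects", {
  expect_equal(strip_modifications("PEPT(+.98)IDE"), "PEPTIDE")
  expect_equal(strip_modifications("PEPTIDE + Oxidation (M)"), "PEPTIDE")
  expect_equal(strip_modifications("PEP[+15.99]TIDE"), "PEPTIDE")
  expect_equal(strip_modifications("peptide"), "PEPTIDE")
})

test_that("cumulative_intensity sums target-specific PTM variants per mg", {
  obs <- data.frame(
    sequence = c("GYINF", "GYINF(+.98)", "MPLPP", "GYINL"),
    intensity = c(1e9, 2e9, 5e8, 7e8),
    specificity = c("X_specific", "X_specific", "shared", "Y_specific"))
  expect_equal(cumulative_intensity(obs, "X", 10), 3e8)
  expect_equal(cumulative_intensity(obs, "Y", 10), 7e7)
  none <- obs[obs$specificity == "shared", ]
  expect_equal(cumulative_intensity(none, "Y", 10), 0)
  raw <- cumulative_intensity(obs, "X")
  expect_equal(as.numeric(raw), 3e9)
  expect_true(attr(raw, "unnormalized"))
})

test_that("cumulative intensity is additive under PTM row splitting", {
  base <- data.frame(sequence = "GYINF", intensity = 6e9,
                     specificity = "X_specific")
  split <- data.frame(sequence = c("GYINF", "GYINF(+.98)"),
                      intensity = c(2.5e9, 3.5e9),
                      specificity = "X_specific")
  expect_equal(cumulative_intensity(base, "X", 10),
               cumulative_intensity(split, "X", 10))
})

test_that("pr_female matches the closed-form logistic", {
  expect_equal(pr_female(7.54), (1 + 0.059) / 2)
  expect_equal(pr_female(1e-9), 0.059, tolerance = 1e-6)  # lower asymptote
  # direct-evaluation oracles
  expect_equal(round(pr_female(9), 3), 0.927)
  expect_equal(round(pr_female(6), 3), 0.096)
  # strict monotonicity over the calibrated domain (far below it the curve
  # plateaus at the floor within double precision)
  xs <- seq(5, 11, by = 0.01)
  expect_true(all(diff(pr_female(xs)) > 0))
  expect_true(all(pr_female(xs) > 0.059 & pr_female(xs) < 1))
  expect_error(pr_female(0), "x > 0")
  expect_error(pr_female(-1), "x > 0")
})

test_that("classify_proteomic applies the male rule before Pr(F)", {
  cfg <- threshold_config()
  # many unique AMELY peptides: definitive male regardless of AMELX level
  expect_equal(classify_proteomic(11, 1e9, cfg)$sex, "XY")
  expect_equal(classify_proteomic(11, NA, cfg)$certainty, "definitive")
  # exactly the threshold count is NOT enough (rule is exclusive)
  expect_equal(classify_proteomic(2, 10^9, cfg)$sex, "XX")
  # Pr(F) >= 0.5: female; below: indeterminate
  high <- classify_proteomic(0, 10^9, cfg)     # x = 9 -> Pr(F) ~ .927
  expect_equal(high$sex, "XX")
  expect_equal(attr(high, "prf"), pr_female(9))
  low <- classify_proteomic(0, 10^7, cfg)      # x = 7 -> Pr(F) ~ .30
  expect_equal(low$sex, "indeterminate")
  expect_lt(attr(low, "prf"), 0.5)
  # no signal at all
  expect_equal(classify_proteomic(0, 0, cfg)$sex, "indeterminate")
})

test_that("proteomic_sex pipeline is order-invariant and counts unique peptides", {
  iso <- amelogenin_isoforms()
  obs <- data.frame(
    sequence = c("PSQQPVIPRQPLMP", "PSQQPVIPRQ(+.98)PLMP", "QPLMPFPG",
                 "PAQQPVIPQQ", "PPHPGHPGY", "WWWWW"),
    modifications = "", intensity = c(1e8, 2e8, 3e8, 4e9, 1e9, 5),
    accession = "x", stringsAsFactors = FALSE)
  res <- proteomic_sex(obs, mass_mg = 10)
  # two distinct stripped Y sequences (PTM variant counts once)
  expect_equal(res$n_amely_unique, 2L)
  expect_equal(res$specificity_report[["shared"]], 1L)
  expect_equal(res$specificity_report[["unmatched"]], 1L)
  expect_equal(res$amelx_ci_per_mg, 4e9 / 10)
  expect_equal(res$amely_ci_per_mg, 6e8 / 10)

  res2 <- proteomic_sex(obs[sample(nrow(obs)), ], mass_mg = 10)
  expect_equal(res2$estimate$sex, res$estimate$sex)
  expect_equal(res2$amelx_ci_per_mg, res$amelx_ci_per_mg)

  empty <- proteomic_sex(obs[0, ], 10)
  expect_equal(empty$estimate$sex, "indeterminate")
})

test_that("blank_qc tolerates one stray AMELX spectrum but no AMELY", {
  empty <- data.frame(sequence = character(0))
  expect_true(blank_qc(empty)$pass)
  one_x <- data.frame(sequence = "PAQQPVIPQQ")   # X-specific in bundled pair
  expect_true(blank_qc(one_x)$pass)
  one_y <- data.frame(sequence = "PSQQPVIPRQ")   # Y-specific in bundled pair
  expect_false(blank_qc(one_y)$pass)
  two_x <- data.frame(sequence = c("PAQQPVIPQQ", "QQPMMPVPG"))
  expect_false(blank_qc(two_x)$pass)
})
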