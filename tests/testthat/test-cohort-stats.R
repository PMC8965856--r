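test_that("BMI z-score arithmetic and affine equivariance", {
  norms <- structure(
    data.frame(sex = "M", age_lo = 10, age_hi = 20, mean = 21.0, sd = 3.0),
    class = c("bmi_norm_table", "data.frame"))
  expect_equal(bmi_zscore(21.0, 15, "M", norms), 0)
  expect_equal(bmi_zscore(27.0, 15, "M", norms), 2.0)
  expect_equal(bmi_zscore(25.5, 15, "M", norms), 1.5)
  shifted <- norms; shifted$mean <- shifted$mean + 2.4
  expect_equal(bmi_zscore(25.5, 15, "M", shifted),
               bmi_zscore(25.5, 15, "M", norms) - 2.4 / 3.0)
  expect_error(bmi_zscore(22, 60, "M", norms), "no norm band")
  expect_error(bmi_zscore(22, 15, "F", norms), "no norm band")
})

test_that("bundled norm table is valid and covers the cohort age range", {
  norms <- default_bmi_norms()
  expect_s3_class(norms, "bmi_norm_table")
  expect_true(all(norms$sd > 0))
  z <- bmi_zscore(c(25.7, 23.6), c(18.5, 19.8), c("M", "F"), norms)
  expect_true(all(is.finite(z)))
})

test_that("weight classification uses strict cutoffs at z = 1 and z = 2", {
  expect_equal(as.character(classify_weight(c(1.0, 1.5, 2.0, 2.5, -0.3))),
               c("normal", "overweight", "overweight", "obese", "normal"))
  expect_identical(is_overweight_or_obese(c(0.9, 1.0, 1.1)),
                   c(FALSE, FALSE, TRUE))
  expect_error(classify_weight(NaN), "finite")
})

test_that("2x2 chi-square: closed form, demographic worked examples, flags", {
  expect_equal(round(chi_square_2x2(rbind(c(4, 6), c(5, 5)))$p_value, 3), 0.653)
  expect_equal(round(chi_square_2x2(rbind(c(7, 3), c(4, 6)))$p_value, 3), 0.178)

  set.seed(21)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-12)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-12)
    refy <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_lt(abs(chi_square_2x2(tab, correct = TRUE)$p_value - refy$p.value), 1e-12)
  }

  prop <- chi_square_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "degenerate")
})

test_that("Mann-Whitney: exact small-sample behavior and symmetries", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)

  expect_equal(mann_whitney(c(1, 5, 9), c(9, 5, 1))$p_value, 1)  # identical multisets
  a <- c(1.2, 3.4, 5.6, 7.1); b <- c(2.3, 4.5, 8.8)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(10 * a, 10 * b)$p_value)
  expect_error(mann_whitney(numeric(0), b), "empty sample")
  expect_error(mann_whitney(c(1, 1, 2), c(2, 3, 4), mode = "exact"), "tie-free")
})

test_that("exact Mann-Whitney agrees with full enumeration for tie-free samples", {
  set.seed(33)
  for (n1 in c(2, 4, 7)) {
    for (n2 in c(3, 5, 7)) {
      pooled <- sample(100, n1 + n2)
      a <- pooled[seq_len(n1)]; b <- pooled[-seq_len(n1)]
      expect_equal(mann_whitney(a, b, mode = "exact")$p_value,
                   enumerate_mw_p(a, b), tolerance = 1e-12)
    }
  }
})

test_that("Spearman: rank invariance, t-approximation p, exact option, errors", {
  x <- c(2, 5, 1, 9, 7, 4)
  st <- spearman_test(x, x^3)
  expect_equal(st$rho, 1)
  expect_equal(st$p_value, 0)

  set.seed(8)
  y <- rnorm(12); z <- rnorm(12)
  expect_equal(spearman_test(y, z)$rho, spearman_test(exp(y), z)$rho)
  expect_equal(spearman_test(y, z)$p_value,
               spearman_p_from_rho(spearman_test(y, z)$rho, 12))

  ex <- spearman_test(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5), method = "exact")
  expect_true(ex$p_value > 0 && ex$p_value <= 1)
  # enumeration sanity: perfectly concordant n = 5 has p = 2/5! (both tails)
  perfect <- spearman_test(1:5, 1:5, method = "exact")
  expect_equal(perfect$p_value, 2 / factorial(5))

  expect_error(spearman_test(rep(1, 6), y[1:6]), "zero rank variance")
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("per-frequency t-tests: identical groups, degenerate bins, Welch flag", {
  set.seed(12)
  sp <- lapply(1:3, function(i) {
    normalize_spectrum(make_spectrum(matrix(rexp(101) + 0.1, 1), labels = "Cz"))
  })
  same <- per_frequency_ttest(sp, sp)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_value == 1))

  flat0 <- make_spectrum(matrix(1, 1, 101), labels = "Cz")
  flat1 <- make_spectrum(matrix(2, 1, 101), labels = "Cz")
  deg <- per_frequency_ttest(list(flat0, flat0), list(flat1, flat1))
  expect_true(all(deg$degenerate))
  expect_true(all(is.na(deg$p_value)))

  ga <- lapply(1:4, function(i) make_spectrum(matrix(rnorm(101, 10), 1), labels = "Cz"))
  gb <- lapply(1:4, function(i) make_spectrum(matrix(rnorm(101, 10), 1), labels = "Cz"))
  pooled <- per_frequency_ttest(ga, gb, var_equal = TRUE)
  welch <- per_frequency_ttest(ga, gb, var_equal = FALSE)
  expect_equal(pooled$df, rep(6, 101))
  expect_false(all(welch$df == 6))
  withbh <- per_frequency_ttest(ga, gb, bh = TRUE)
  expect_true(all(withbh$p_bh >= withbh$p_value, na.rm = TRUE))
  expect_error(per_frequency_ttest(ga[1], gb), "at least 2")
})

test_that("cohort_compare: cloned groups give null results; ranks ignore scale", {
  set.seed(44)
  half <- data.frame(
    id = sprintf("P%02d", 1:6), group = "PWS",
    age = rnorm(6, 18, 3), sex = rep(c("M", "F"), 3),
    intelligence = c(2, 2, 2, 1, 1, 0), bmi = rnorm(6, 25, 2),
    bmi_z = rnorm(6, 1, 0.5),
    cpt_commission = rnorm(6, 55, 5), cpt_omission = rnorm(6, 60, 8),
    stringsAsFactors = FALSE
  )
  clone <- half; clone$group <- "control"; clone$id <- sprintf("C%02d", 1:6)
  cc <- cohort_compare(rbind(half, clone))
  expect_true(all(cc$cpt$p_value == 1))
  cont <- cc$demographics[cc$demographics$type == "continuous", ]
  expect_true(all(cont$p_value == 1))
  catg <- cc$demographics[cc$demographics$type == "categorical", ]
  expect_true(all(catg$statistic == 0))

  scaled <- rbind(half, clone)
  scaled$cpt_commission[scaled$group == "PWS"] <-
    scaled$cpt_commission[scaled$group == "PWS"] + 10
  cc1 <- cohort_compare(scaled)
  scaled2 <- scaled; scaled2$cpt_commission <- scaled2$cpt_commission * 3.7
  cc2 <- cohort_compare(scaled2)
  expect_equal(cc1$cpt[cc1$cpt$variable == "commission", "p_value"],
               cc2$cpt[cc2$cpt$variable == "commission", "p_value"])
})
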