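# LOO cross-validation, conformity regression, precision, matrix effect.

test_that("noiseless data recalculate onto themselves", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 3)
  recalc <- loo_cv(std, "linear")
  expect_equal(recalc, std$area_au, tolerance = 1e-9)
  res <- validate_recalc_regression(std$area_au, recalc)
  expect_equal(res$line_intercept, 0, tolerance = 1e-8)
  expect_equal(res$line_slope, 1, tolerance = 1e-9)
  expect_true(res$conforms)
})

test_that("LOO matches an explicit fold-by-fold least-squares oracle", {
  toy <- data.frame(conc_um = c(1, 2, 3, 4), area_au = c(1, 2.1, 2.9, 4.2))
  recalc <- loo_cv(toy, "linear")
  oracle <- vapply(1:4, function(i) {
    cf <- normal_equations_fit(toy$conc_um[-i], toy$area_au[-i], 1)
    cf[1] + cf[2] * toy$conc_um[i]
  }, numeric(1))
  expect_equal(recalc, oracle, tolerance = 1e-10)
})

test_that("permuting input rows permutes LOO outputs identically", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 3,
                                 noise_sd = 0.5, seed = 2)
  base <- loo_cv(std, "linear")
  perm <- withr::with_seed(1, sample(nrow(std)))
  expect_equal(loo_cv(std[perm, ], "linear"), base[perm], tolerance = 1e-12)
})

test_that("a row's own response never influences its recalculated value", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 3,
                                 noise_sd = 0.5, seed = 3)
  base <- loo_cv(std, "linear")
  tampered <- std
  tampered$area_au[5] <- 999
  expect_equal(loo_cv(tampered, "linear")[5], base[5], tolerance = 1e-12)
})

test_that("rank-deficient subfits are rejected naming the row", {
  std <- data.frame(conc_um = c(1, 1, 1, 2), area_au = c(1, 1.1, 0.9, 2))
  expect_error(loo_cv(std, "linear"), "row 4")
})

test_that("identity recalculation conforms; a doubled slope does not", {
  y <- withr::with_seed(10, rnorm(20, mean = 10, sd = 3))
  ident <- validate_recalc_regression(y, y)
  expect_equal(ident$line_intercept, 0, tolerance = 1e-10)
  expect_equal(ident$line_slope, 1, tolerance = 1e-12)
  expect_true(ident$conforms)
  doubled <- validate_recalc_regression(y, 2 * y)
  expect_false(doubled$conforms)
  expect_error(validate_recalc_regression(rep(1, 5), rnorm(5)),
               "zero variance")
})

test_that("calibration-mode recalculated values share the original fit's R^2", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                 noise_sd = 0.514, seed = 7)
  fit <- fit_calibration(std, "linear")
  res <- cv_validate(std, "linear", mode = "calibration")
  expect_equal(res$r_squared, fit$r_squared, tolerance = 1e-12)
})

test_that("seeded synthetic standards conform in at least 90% of runs", {
  conf <- vapply(1:500, function(s) {
    std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                   noise_sd = 0.514, seed = s)
    cv_validate(std, "linear", mode = "cv")$conforms
  }, logical(1))
  expect_gte(mean(conf), 0.90)
})

test_that("the joint conformity test agrees with the marginal one on clean data", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                 noise_sd = 0.2, seed = 12)
  recalc <- loo_cv(std, "linear")
  marg <- validate_recalc_regression(std$area_au, recalc)
  joint <- validate_recalc_regression(std$area_au, recalc, test = "joint")
  expect_true(marg$conforms)
  expect_true(joint$conforms)
})

test_that("degenerate precision input reports zero CV and a zero-variance flag", {
  std <- data.frame(conc_um = rep(c(1, 2), each = 6),
                    area_au = rep(c(5, 9), each = 6),
                    day = rep(rep(1:3, each = 2), 2),
                    replicate = rep(1:2, 6))
  pr <- precision_study(std)
  expect_equal(pr$levels$intra_cv_percent, c(0, 0))
  expect_true(all(pr$levels$zero_variance))
  expect_true(pr$passes)
})

test_that("the precision t statistic equals the pooled-variance formula", {
  x <- withr::with_seed(21, rnorm(5, 10, 1))
  y <- withr::with_seed(22, rnorm(5, 10.5, 1))
  std <- data.frame(conc_um = 3, area_au = c(x, y),
                    day = rep(1:2, each = 5), replicate = rep(1:5, 2))
  pr <- precision_study(std)
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(-abs(tstat), df = 8)
  expect_equal(pr$levels$t_p_value, p_hand, tolerance = 1e-10)
  # cross-check against the stock implementation
  p_ref <- t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(pr$levels$t_p_value, p_ref, tolerance = 1e-10)
})

test_that("large injected day offsets break precision at alpha 0.05", {
  base <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                  noise_sd = 0.2, n_days = 3,
                                  day_effect_sd = 0, seed = 30)
  base$area_au[base$day == 2] <- base$area_au[base$day == 2] + 1  # 5 SD
  pr <- precision_study(base)
  expect_false(pr$passes)
  expect_true(any(pr$levels$t_p_value < 0.05))
})

test_that("single-day tables flag the absent inter-day comparison", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                 noise_sd = 0.2, n_days = 1, seed = 5)
  pr <- precision_study(std)
  expect_true(pr$single_day)
  expect_true(all(is.na(pr$levels$inter_sd)))
})

test_that("published area pairs give the trapping verdict with recoveries 0.88/0.556/0.50", {
  res <- matrix_effect_assess(c("5" = 25, "12.5" = 180, "25" = 400),
                              c("5" = 22, "12.5" = 100, "25" = 200))
  expect_equal(unname(res$recovery), c(22 / 25, 100 / 180, 0.5),
               tolerance = 1e-12)
  expect_equal(round(unname(res$recovery), 3), c(0.88, 0.556, 0.5))
  expect_true(res$trapping)
})

test_that("identical maps and flat recoveries give a negative verdict", {
  same <- c("5" = 100, "12.5" = 200, "25" = 300)
  res <- matrix_effect_assess(same, same)
  expect_equal(unname(res$recovery), c(1, 1, 1))
  expect_false(res$trapping)
  flat <- matrix_effect_assess(c("1" = 100, "2" = 100, "3" = 100),
                               c("1" = 90, "2" = 88, "3" = 91))
  expect_false(flat$trapping)
  expect_error(matrix_effect_assess(c("1" = 0), c("1" = 1)), "zero")
})
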