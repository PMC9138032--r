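# Calibration fitting, detection limits, forward and inverse prediction.

test_that("exact data are fitted exactly", {
  x <- c(1, 2, 3, 4, 5)
  lin <- fit_calibration(data.frame(conc_um = x, area_au = 2 * x), "linear")
  expect_equal(unname(lin$coefficients[c("a", "b")]), c(0, 2),
               tolerance = 1e-10)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$rmse, 0, tolerance = 1e-10)
  par <- fit_calibration(
    data.frame(conc_um = x, area_au = 1 + 2 * x + 0.5 * x^2), "parabolic")
  expect_equal(unname(par$coefficients), c(1, 2, 0.5), tolerance = 1e-10)
})

test_that("coefficients match a normal-equations oracle on noisy tables", {
  for (s in 1:25) {
    std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                   noise_sd = 0.514, seed = s)
    fit <- fit_calibration(std, "linear")
    oracle <- normal_equations_fit(std$conc_um, std$area_au, 1)
    expect_equal(unname(fit$coefficients[c("a", "b")]), oracle,
                 tolerance = 1e-8)
    stdp <- gen_calibration_dataset(table3_model(), full_levels, 3,
                                    noise_sd = 18, seed = s)
    fitp <- fit_calibration(stdp, "parabolic")
    expect_equal(unname(fitp$coefficients),
                 normal_equations_fit(stdp$conc_um, stdp$area_au, 2),
                 tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_calibration(data.frame(conc_um = c(2, 2, 2),
                                          area_au = c(1, 2, 3)), "linear"),
               "rank-deficient")
  expect_error(fit_calibration(data.frame(conc_um = c(1, 2, 3),
                                          area_au = 1:3), "parabolic"),
               ">= 4")
})

test_that("a parabolic fit of linear data reproduces the linear coefficients", {
  std <- gen_calibration_dataset(table5_model(), c(0.8, 1.6, 3, 6, 12.5), 3,
                                 noise_sd = 0.3, seed = 4)
  lin <- fit_calibration(std, "linear")
  # constraining c to 0 is an OLS fit on the same basis: refit linear data
  # exactly generated from the parabolic fit with c = 0
  par_of_lin <- fit_calibration(
    data.frame(conc_um = std$conc_um,
               area_au = predict_area(lin, std$conc_um,
                                      warn_out_of_range = FALSE)),
    "parabolic")
  expect_equal(par_of_lin$coefficients[["a"]], lin$coefficients[["a"]],
               tolerance = 1e-8)
  expect_equal(par_of_lin$coefficients[["b"]], lin$coefficients[["b"]],
               tolerance = 1e-8)
  expect_equal(par_of_lin$coefficients[["c"]], 0, tolerance = 1e-8)
})

test_that("published linear parameters give LoD 0.5 and LoQ 0.9 uM", {
  lim <- compute_lod_loq(table5_model())
  expect_equal(lim$lod, 3.3 * 0.514 / 3.51, tolerance = 1e-12)
  expect_equal(lim$loq, 6 * 0.514 / 3.51, tolerance = 1e-12)
  expect_equal(lim$lod_reported, 0.5)
  expect_equal(lim$loq_reported, 0.9)
})

test_that("LoQ/LoD is 6/3.3 before rounding, and 0 at zero RMSE", {
  for (rmse in c(0.1, 0.514, 2, 7)) {
    m <- calibration_model("linear", a = 0, b = 2, rmse = rmse)
    lim <- compute_lod_loq(m)
    expect_equal(lim$loq / lim$lod, 6 / 3.3, tolerance = 1e-12)
  }
  m0 <- calibration_model("linear", a = 0, b = 2, rmse = 0)
  expect_equal(compute_lod_loq(m0)$lod, 0)
  expect_equal(compute_lod_loq(m0)$loq, 0)
})

test_that("parabolic models are refused LoD/LoQ with the range-reduction remedy", {
  expect_error(compute_lod_loq(table3_model()), "reduce the concentration range")
})

test_that("forward prediction evaluates the published polynomials", {
  expect_equal(predict_area(table5_model(), 0, warn_out_of_range = FALSE),
               -0.581)
  expect_equal(predict_area(table3_model(), 0, warn_out_of_range = FALSE),
               -13.2)
  m <- calibration_model("linear", a = 0, b = 2)
  expect_equal(predict_area(m, 1), 2)
  expect_warning(predict_area(table3_model(), 60), "outside the fitted range")
})

test_that("inverse prediction inverts the published models", {
  inv <- invert_calibration(table5_model(), 10)
  expect_equal(inv$conc_um, (10 + 0.581) / 3.51, tolerance = 1e-12)
  expect_equal(round(inv$conc_um, 3), 3.015)
  invp <- invert_calibration(table3_model(), 600)
  expect_equal(invp$conc_um, 33.99245, tolerance = 1e-5)
})

test_that("inversion round-trips forward prediction", {
  m <- fit_calibration(gen_calibration_dataset(table5_model(),
                                               reduced_levels, 2), "linear")
  expect_equal(invert_calibration(m, predict_area(m, 4))$conc_um, 4,
               tolerance = 1e-9)
  p <- table3_model()
  expect_equal(invert_calibration(
    p, predict_area(p, 20, warn_out_of_range = FALSE))$conc_um, 20,
    tolerance = 1e-9)
})

test_that("parabolic inversion rejects areas below the vertex", {
  expect_error(invert_calibration(table3_model(), -100), "no real solution")
})

test_that("inverse-prediction sd is minimal at the centroid and grows outward", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                 noise_sd = 0.514, seed = 6)
  m <- fit_calibration(std, "linear")
  areas <- seq(min(std$area_au), max(std$area_au), length.out = 41)
  sds <- invert_calibration(m, areas)$sd_um
  i0 <- which.min(abs(areas - m$centroid_area))
  expect_equal(which.min(sds), i0)
  expect_true(all(diff(sds[i0:length(sds)]) > 0))
  expect_true(all(diff(sds[1:i0]) < 0))
})

test_that("true parameters fall within 3 SE in almost all seeded refits", {
  hits <- vapply(1:500, function(s) {
    std <- gen_calibration_dataset(table5_model(), reduced_levels, 5,
                                   noise_sd = 0.514, n_days = 3, seed = s)
    f <- fit_calibration(std, "linear")
    abs(f$coefficients[["a"]] + 0.581) <= 3 * f$se[["a"]] &&
      abs(f$coefficients[["b"]] - 3.51) <= 3 * f$se[["b"]]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("range reduction keeps the low standards and demands 3 levels", {
  std <- gen_calibration_dataset(table5_model(), full_levels, 2)
  red <- reduce_range(std, 6)
  expect_equal(sort(unique(red$conc_um)), c(0.8, 1.6, 3, 6))
  expect_match(attr(red, "provenance"), "reduced")
  expect_equal(nrow(reduce_range(std, 100)), nrow(std))
  expect_error(reduce_range(std, 0.5), ">= 3")
})

test_that("models survive a JSON round trip", {
  std <- gen_calibration_dataset(table5_model(), reduced_levels, 3,
                                 noise_sd = 0.5, seed = 8)
  m <- fit_calibration(std, "linear")
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  back <- model_from_json(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$rmse, m$rmse, tolerance = 1e-12)
  expect_equal(invert_calibration(back, 10), invert_calibration(m, 10),
               tolerance = 1e-12)
})
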