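# Shared fixtures: the two published calibration parameterisations used as
# known "true" models throughout the suite.

# linear fit over the reduced 0.8-6 uM range: intercept -0.581 AU,
# slope 3.51 AU/uM, RMSE 0.514 AU
table5_model <- function(with_geometry = FALSE) {
  if (with_geometry) {
    calibration_model("linear", a = -0.581, b = 3.51, rmse = 0.514,
                      conc_range = c(0.8, 6), n = 20, sxx = 50,
                      centroid_area = 9.44)
  } else {
    calibration_model("linear", a = -0.581, b = 3.51, rmse = 0.514)
  }
}

# parabolic fit over the full 0.8-50 uM range
table3_model <- function() {
  calibration_model("parabolic", a = -13.2, b = 5.87, c = 0.358,
                    rmse = 18.16, conc_range = c(0.8, 50))
}

reduced_levels <- c(0.8, 1.6, 3, 6)
full_levels <- c(0.8, 1.6, 3, 6, 12.5, 25, 50)

# brute-force normal-equations least squares, the independent oracle for
# fit_calibration
normal_equations_fit <- function(x, y, degree) {
  X <- vapply(0:degree, function(k) x^k, numeric(length(x)))
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
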