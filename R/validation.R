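# Calibration validation: leave-one-out cross-validation with the
# recalculated-vs-experimental conformity line, intra-/inter-day precision
# and the matrix-effect (recovery) assessment.

#' Leave-one-out recalculated responses
#'
#' For each standards row, refits the calibration on all remaining rows and
#' evaluates the subfit at the left-out concentration.  Output order
#' matches input order.
#'
#' @param standards a standards table.
#' @param kind `"linear"` or `"parabolic"`.
#' @return numeric vector of recalculated areas, AU, one per input row.
#' @export
loo_cv <- function(standards, kind = c("linear", "parabolic")) {
  kind <- match.arg(kind)
  standards <- as_standards_table(standards)
  p <- if (kind == "linear") 2L else 3L
  n <- nrow(standards)
  x <- standards$conc_um
  y <- standards$area_au
  # subfits need full rank only (p distinct levels), not the user-facing
  # level minimum of fit_calibration, so refit each fold directly
  vapply(seq_len(n), function(i) {
    if (length(unique(x[-i])) < p) {
      stopf("leaving out row %d makes the %s subfit rank-deficient", i, kind)
    }
    X <- vapply(0:(p - 1L), function(k) x^k, numeric(n))
    cf <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    sum(cf * X[i, ])
  }, numeric(1))
}

#' Conformity regression of recalculated on experimental responses
#'
#' Regresses recalculated areas on experimental areas; the calibration is
#' judged valid when the intercept is not significantly different from 0
#' and the slope not significantly different from 1 (two-sided coefficient
#' t-tests with n-2 df at level `alpha`).  An optional joint F-test on
#' (intercept, slope) = (0, 1) is available.
#'
#' @param experimental observed areas, AU.
#' @param recalculated recalculated areas (LOO or plain fitted values), AU.
#' @param alpha significance level (default 0.05).
#' @param test `"coefficients"` (default: two marginal t-tests) or
#'   `"joint"` (elliptical F-test on both coefficients at once).
#' @return object of class `cv_result`: line coefficients with standard
#'   errors, R^2, RMSE (root mean squared residual), overall p-value and
#'   the `conforms` verdict.
#' @export
validate_recalc_regression <- function(experimental, recalculated,
                                       alpha = 0.05,
                                       test = c("coefficients", "joint")) {
  test <- match.arg(test)
  stopifnot(length(experimental) == length(recalculated),
            length(experimental) >= 3L, alpha > 0, alpha < 1)
  if (stats::var(experimental) == 0) {
    stopf("experimental responses have zero variance")
  }
  fit <- stats::lm(recalculated ~ experimental)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  cf <- stats::coef(sm)
  n <- length(experimental)
  a <- cf[1, 1]; sa <- cf[1, 2]
  b <- cf[2, 1]; sb <- cf[2, 2]
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  # an (essentially) exact recalculation carries no residual information for
  # the t-tests: compare coefficients to (0, 1) directly at working precision
  tiny <- sqrt(.Machine$double.eps) * max(abs(experimental), 1)
  exact <- sqrt(mean(stats::residuals(fit)^2)) <= tiny
  conforms <- if (exact) {
    abs(a) <= tiny && abs(b - 1) <= 1e-8
  } else if (test == "coefficients") {
    abs(a) / sa <= tcrit && abs(b - 1) / sb <= tcrit
  } else {
    X <- cbind(1, experimental)
    beta <- c(a, b) - c(0, 1)
    s2 <- sum(stats::residuals(fit)^2) / (n - 2)
    Fstat <- drop(t(beta) %*% crossprod(X) %*% beta) / (2 * s2)
    Fstat <= stats::qf(1 - alpha, 2, n - 2)
  }
  fstat <- sm$fstatistic
  structure(list(
    recalculated = recalculated,
    line_intercept = a, line_intercept_sd = sa,
    line_slope = b, line_slope_sd = sb,
    r_squared = sm$r.squared,
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    model_p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE)),
    conforms = conforms, alpha = alpha, test = test, n = n),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("conformity line: intercept %.4g (sd %.3g), ",
                     "slope %.4g (sd %.3g), R^2 %.4f\n"),
              x$line_intercept, x$line_intercept_sd,
              x$line_slope, x$line_slope_sd, x$r_squared))
  cat(sprintf("verdict: %s (alpha %g, %s test)\n",
              if (x$conforms) "conforms to (0, 1)" else "does NOT conform",
              x$alpha, x$test))
  invisible(x)
}

#' Run the full cross-validation or calibration-mode conformity check
#'
#' Convenience wrapper: computes recalculated responses — by leave-one-out
#' refits (`mode = "cv"`) or by projecting every point onto the single
#' original fit (`mode = "calibration"`) — then runs
#' [validate_recalc_regression()].
#'
#' @param standards a standards table.
#' @param kind `"linear"` or `"parabolic"`.
#' @param mode `"cv"` or `"calibration"`.
#' @param alpha significance level.
#' @return a `cv_result`.
#' @export
cv_validate <- function(standards, kind = c("linear", "parabolic"),
                        mode = c("cv", "calibration"), alpha = 0.05) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  standards <- as_standards_table(standards)
  recalc <- if (mode == "cv") {
    loo_cv(standards, kind = kind)
  } else {
    fit <- fit_calibration(standards, kind = kind)
    predict_area(fit, standards$conc_um, warn_out_of_range = FALSE)
  }
  validate_recalc_regression(standards$area_au, recalc, alpha = alpha)
}

# Pooled-variance two-sided Student's t-test; returns p (NA on zero
# pooled variance, which callers report as a zero-variance flag).
.pooled_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 == 0) {
    return(list(t = NA_real_, p = NA_real_, zero_variance = TRUE))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat,
       p = 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2),
       zero_variance = FALSE)
}

#' Intra- and inter-day precision study
#'
#' Per concentration level: intra-day scatter is the pooled within-day
#' standard deviation, inter-day scatter is the standard deviation of day
#' means.  Day-1 replicates (the calibration day) are compared against the
#' pooled replicates of the other days by a two-sided pooled-variance
#' Student's t-test; precision "passes" when no level's p-value drops below
#' `alpha`.
#'
#' @param standards a standards table with `day` and `replicate` columns;
#'   >= 2 replicates per level per day.
#' @param alpha significance level (default 0.05).
#' @return object of class `precision_report`: a per-level `data.frame`
#'   (`conc_um`, intra/inter mean, sd, cv_percent, `t_p_value`,
#'   `zero_variance`) plus `passes`, `single_day`, `alpha` attributes.
#' @export
precision_study <- function(standards, alpha = 0.05) {
  standards <- as_standards_table(standards)
  days <- sort(unique(standards$day))
  single_day <- length(days) < 2L
  levels_um <- sort(unique(standards$conc_um))
  rows <- lapply(levels_um, function(lv) {
    sub <- standards[standards$conc_um == lv, ]
    by_day <- split(sub$area_au, sub$day)
    if (any(vapply(by_day, length, 1L) < 2L)) {
      stopf("level %g uM needs >= 2 replicates per day", lv)
    }
    within_var <- sum(vapply(by_day, function(v)
      (length(v) - 1) * stats::var(v), numeric(1))) /
      (length(sub$area_au) - length(by_day))
    intra_sd <- sqrt(within_var)
    intra_mean <- mean(sub$area_au)
    day_means <- vapply(by_day, mean, numeric(1))
    inter_mean <- if (single_day) NA_real_ else mean(day_means)
    inter_sd <- if (single_day) NA_real_ else stats::sd(day_means)
    if (single_day) {
      tt <- list(p = NA_real_, zero_variance = FALSE)
    } else {
      d1 <- sub$area_au[sub$day == days[1]]
      rest <- sub$area_au[sub$day != days[1]]
      tt <- .pooled_t_test(d1, rest)
    }
    data.frame(conc_um = lv,
               intra_mean = intra_mean, intra_sd = intra_sd,
               intra_cv_percent = 100 * intra_sd / abs(intra_mean),
               inter_mean = inter_mean, inter_sd = inter_sd,
               inter_cv_percent = 100 * inter_sd / abs(inter_mean),
               t_p_value = tt$p, zero_variance = isTRUE(tt$zero_variance))
  })
  out <- do.call(rbind, rows)
  structure(list(levels = out,
                 passes = single_day ||
                   all(is.na(out$t_p_value) | out$t_p_value >= alpha),
                 single_day = single_day, alpha = alpha),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("precision study: %s (alpha %g%s)\n",
              if (x$passes) "passes" else "FAILS", x$alpha,
              if (x$single_day) ", single day - inter-day stats absent" else ""))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Assess the serum matrix effect from paired areas
#'
#' Computes per-level recovery = spiked / standard area.  The verdict
#' "concentration-dependent trapping" is returned when recovery falls from
#' the lowest to the highest concentration by more than `tolerance` (in
#' recovery fraction units, default 0.05 = 5 percentage points) and no
#' intermediate step rises by more than `tolerance`.
#'
#' @param standard_areas named numeric, concentration (uM) -> area of the
#'   Na2S standard solution.
#' @param spiked_areas named numeric with the same keys, areas of serum
#'   spiked at the same concentrations.
#' @param tolerance recovery-drop tolerance (default 0.05).
#' @return list with `recovery` (named, ordered by concentration),
#'   `trapping` verdict and `tolerance`.
#' @export
matrix_effect_assess <- function(standard_areas, spiked_areas,
                                 tolerance = 0.05) {
  keys <- names(standard_areas)
  if (is.null(keys) || !setequal(keys, names(spiked_areas))) {
    stopf("standard and spiked maps must share the same concentration keys")
  }
  if (any(standard_areas == 0)) stopf("zero standard area")
  conc <- as.numeric(keys)
  ord <- order(conc)
  rec <- (spiked_areas[keys] / standard_areas)[ord]
  names(rec) <- keys[ord]
  drop_total <- rec[1] - rec[length(rec)]
  rises <- if (length(rec) > 1L) diff(rec) else 0
  trapping <- unname(drop_total > tolerance && all(rises <= tolerance))
  list(recovery = rec, trapping = trapping, tolerance = tolerance)
}
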