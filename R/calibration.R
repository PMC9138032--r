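# Calibration models for SDB peak area vs Na2S concentration: parabolic
# (y = a + b x + c x^2) over the full 0.8-50 uM series, linear (y = a + b x)
# over the reduced 0.8-6 uM range, detection limits, forward prediction and
# inverse prediction with uncertainty.

#' Validate a calibration standards table
#'
#' @param x `data.frame` with columns `conc_um`, `area_au` and optionally
#'   `day`, `replicate` (defaulted to 1 and a running index).
#' @return the table with class `standards_table`.
#' @export
as_standards_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("conc_um", "area_au") %in% names(x))) {
    stopf("standards table needs columns conc_um, area_au")
  }
  if (nrow(x) == 0L) stopf("standards table is empty")
  if (any(x$conc_um <= 0)) stopf("concentrations must be > 0")
  if (anyNA(x$conc_um) || anyNA(x$area_au)) stopf("missing values not allowed")
  if (is.null(x$day)) x$day <- 1L
  if (is.null(x$replicate)) {
    x$replicate <- stats::ave(seq_len(nrow(x)),
                              x$conc_um, x$day, FUN = seq_along)
  }
  class(x) <- c("standards_table", "data.frame")
  x
}

#' Construct a calibration model from known coefficients
#'
#' Used to specify "true" models for simulation or to carry published
#' coefficients (e.g. intercept -0.581 AU, slope 3.51 AU/uM with
#' RMSE 0.514 AU for the linear 0.8-6 uM fit).
#'
#' @param kind `"linear"` or `"parabolic"`.
#' @param a intercept, AU.
#' @param b slope, AU/uM.
#' @param c quadratic coefficient, AU/uM^2 (parabolic only).
#' @param rmse residual scatter, AU (optional).
#' @param conc_range valid concentration range, uM.
#' @param n,sxx,centroid_area optional fit geometry (observation count,
#'   concentration sum of squares, mean response) used by inverse-prediction
#'   uncertainty; left `NA` for purely nominal models.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(kind = c("linear", "parabolic"), a, b, c = NA,
                              rmse = NA, conc_range = c(-Inf, Inf),
                              n = NA, sxx = NA, centroid_area = NA) {
  kind <- match.arg(kind)
  if (kind == "parabolic" && is.na(c)) stopf("parabolic model needs c")
  structure(list(kind = kind,
                 coefficients = c(a = a, b = b,
                                  c = if (kind == "parabolic") c else NA),
                 se = c(a = NA_real_, b = NA_real_, c = NA_real_),
                 r_squared = NA_real_, rmse = rmse,
                 rmse_denominator = "n", model_p_value = NA_real_,
                 conc_range = conc_range, centroid_area = centroid_area,
                 n = n, sxx = sxx, data = NULL),
            class = "calibration_model")
}

#' Fit a calibration model by ordinary least squares
#'
#' All replicate rows enter the fit as individual points (no level
#' averaging, no weighting).  The quadratic term uses the raw polynomial
#' basis so `a`, `b`, `c` are directly interpretable in AU, AU/uM and
#' AU/uM^2.
#'
#' @param standards a [as_standards_table()] table; >= 3 distinct levels for
#'   a linear fit, >= 4 for a parabolic fit.
#' @param kind `"linear"` or `"parabolic"`.
#' @param rmse_denominator `"n"` (default: RMSE is the root of the plain
#'   mean squared residual) or `"n_minus_p"` (the usual residual standard
#'   error).
#' @return a `calibration_model` with coefficients, standard errors, R^2,
#'   RMSE, overall-regression F p-value, the fitted concentration range and
#'   the response centroid (mean fitted area).
#' @export
fit_calibration <- function(standards, kind = c("linear", "parabolic"),
                            rmse_denominator = c("n", "n_minus_p")) {
  kind <- match.arg(kind)
  rmse_denominator <- match.arg(rmse_denominator)
  standards <- as_standards_table(standards)
  x <- standards$conc_um
  y <- standards$area_au
  nlev <- length(unique(x))
  if (nlev < 2L) stopf("rank-deficient design: all concentrations equal")
  need <- if (kind == "linear") 3L else 4L
  if (nlev < need) {
    stopf("%s fit needs >= %d distinct concentration levels, got %d",
          kind, need, nlev)
  }
  fit <- if (kind == "linear") stats::lm(y ~ x) else
    stats::lm(y ~ x + I(x^2))
  # summary.lm warns on exact (noiseless) fits; those are legitimate here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  p <- length(stats::coef(fit))
  n <- length(y)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  denom <- if (rmse_denominator == "n") n else n - p
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  cf <- unname(stats::coef(fit))
  se <- unname(sm$coefficients[, "Std. Error"])
  structure(list(
    kind = kind,
    coefficients = c(a = cf[1], b = cf[2],
                     c = if (kind == "parabolic") cf[3] else NA),
    se = c(a = se[1], b = se[2],
           c = if (kind == "parabolic") se[3] else NA),
    r_squared = 1 - ss_res / ss_tot,
    rmse = sqrt(ss_res / denom),
    rmse_denominator = rmse_denominator,
    model_p_value = pval,
    conc_range = range(x),
    centroid_area = mean(stats::fitted(fit)),
    n = n, sxx = sum((x - mean(x))^2),
    data = standards[, c("conc_um", "area_au", "day", "replicate")]),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cf <- x$coefficients
  eq <- if (x$kind == "linear") {
    sprintf("area = %.4g + %.4g * conc", cf["a"], cf["b"])
  } else {
    sprintf("area = %.4g + %.4g * conc + %.4g * conc^2",
            cf["a"], cf["b"], cf["c"])
  }
  cat(sprintf("<calibration_model: %s> %s\n", x$kind, eq))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 %.4f, RMSE %.4g AU (denominator %s), range %g-%g uM\n",
                x$r_squared, x$rmse, x$rmse_denominator,
                x$conc_range[1], x$conc_range[2]))
  }
  invisible(x)
}

#' Detection and quantification limits of a linear calibration
#'
#' LoD and LoQ are 3.3 and 6 times the ratio of the model RMSE to its
#' slope.  With slope 3.51 AU/uM and RMSE 0.514 AU this gives 0.483 and
#' 0.879 uM, reported as 0.5 and 0.9 uM at one decimal.
#'
#' @param model a linear `calibration_model` with positive slope.
#' @param reporting_decimals decimals for the reported values (default 1).
#' @return object of class `detection_limits` with raw (`lod`, `loq`) and
#'   rounded (`lod_reported`, `loq_reported`) values; `loq/lod` is exactly
#'   `6/3.3` before rounding.
#' @export
compute_lod_loq <- function(model, reporting_decimals = 1L) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$kind != "linear") {
    stopf(paste("LoD/LoQ are defined for the linear model only;",
                "reduce the concentration range (reduce_range) and refit",
                "a linear calibration first"))
  }
  b <- model$coefficients[["b"]]
  if (!is.finite(b) || b <= 0) stopf("slope must be > 0")
  rmse <- model$rmse
  if (is.na(rmse)) stopf("model has no RMSE")
  lod <- 3.3 * rmse / b
  loq <- 6 * rmse / b
  structure(list(lod = lod, loq = loq,
                 lod_reported = round(lod, reporting_decimals),
                 loq_reported = round(loq, reporting_decimals),
                 reporting_decimals = as.integer(reporting_decimals)),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("LoD %.4g uM (reported %.*f), LoQ %.4g uM (reported %.*f)\n",
              x$lod, x$reporting_decimals, x$lod_reported,
              x$loq, x$reporting_decimals, x$loq_reported))
  invisible(x)
}

#' Predict peak area from concentration
#'
#' @param model a `calibration_model`.
#' @param conc concentrations, uM (vectorised).
#' @param warn_out_of_range warn when a concentration falls outside the
#'   model's fitted range (default TRUE).
#' @return predicted areas, AU.
#' @export
predict_area <- function(model, conc, warn_out_of_range = TRUE) {
  stopifnot(inherits(model, "calibration_model"), all(conc >= 0))
  cf <- model$coefficients
  out <- cf[["a"]] + cf[["b"]] * conc
  if (model$kind == "parabolic") out <- out + cf[["c"]] * conc^2
  rng <- model$conc_range
  if (warn_out_of_range && all(is.finite(rng)) &&
      any(conc < rng[1] | conc > rng[2])) {
    warnf("concentration outside the fitted range [%g, %g] uM",
          rng[1], rng[2])
  }
  unname(out)
}

#' Invert a calibration: concentration from peak area
#'
#' Linear models invert as `(area - a) / b`.  Parabolic models solve
#' `c x^2 + b x + (a - area) = 0` and take the root inside the fitted
#' range; when both or neither root qualifies, the larger non-negative real
#' root is returned and flagged out of range.  The inverse-prediction
#' standard deviation for the linear case is
#' `(rmse / b) * sqrt(1/m + 1/n + (area - ybar)^2 / (b^2 * Sxx))`
#' with `m = n_sample_reps`; it is smallest near the response centroid
#' `ybar` and grows towards the edges of the calibrated range.
#'
#' @param model a `calibration_model`.
#' @param area observed areas, AU (vectorised).
#' @param n_sample_reps number of sample injections averaged into each
#'   area (default 1).
#' @return `data.frame(conc_um, sd_um, in_range)`; `in_range` is FALSE when
#'   the concentration leaves the fitted range or falls below the LoQ.
#' @export
invert_calibration <- function(model, area, n_sample_reps = 1L) {
  stopifnot(inherits(model, "calibration_model"), all(is.finite(area)),
            is_count(n_sample_reps))
  cf <- model$coefficients
  a <- cf[["a"]]; b <- cf[["b"]]
  if (model$kind == "linear") {
    if (!is.finite(b) || b <= 0) stopf("slope must be > 0 for inversion")
    conc <- (area - a) / b
    sd_um <- rep(NA_real_, length(area))
    ok <- !is.na(model$rmse) && !is.na(model$n) && !is.na(model$sxx) &&
      !is.na(model$centroid_area)
    if (ok) {
      sd_um <- (model$rmse / b) *
        sqrt(1 / n_sample_reps + 1 / model$n +
               (area - model$centroid_area)^2 / (b^2 * model$sxx))
    }
    loq <- if (!is.na(model$rmse) && b > 0) 6 * model$rmse / b else 0
  } else {
    cc <- cf[["c"]]
    conc <- vapply(area, function(y) {
      disc <- b^2 - 4 * cc * (a - y)
      if (disc < 0) stopf("no real solution for area %.4g AU", y)
      roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * cc))
      rng <- model$conc_range
      inside <- roots >= rng[1] & roots <= rng[2]
      if (sum(inside) == 1L) roots[inside] else {
        pos <- roots[roots >= 0]
        if (length(pos) == 0L) stopf("no non-negative root for area %.4g", y)
        max(pos)
      }
    }, numeric(1))
    sd_um <- rep(NA_real_, length(area))
    loq <- 0
  }
  rng <- model$conc_range
  in_range <- conc >= rng[1] & conc <= rng[2] & conc >= loq
  data.frame(conc_um = unname(conc), sd_um = unname(sd_um),
             in_range = in_range)
}

#' Restrict a standards table to a reduced concentration range
#'
#' The wide-range parabolic model predicts poorly far from its centroid;
#' restricting to the low-concentration levels (here 0.8-6 uM) lets a
#' linear model cover the region where serum samples actually fall.
#'
#' @param standards a standards table.
#' @param max_conc keep rows with `conc_um <= max_conc`.
#' @return the filtered table (>= 3 surviving levels required), with a
#'   `provenance` attribute noting the reduction.
#' @export
reduce_range <- function(standards, max_conc) {
  standards <- as_standards_table(standards)
  stopifnot(is_number(max_conc))
  out <- standards[standards$conc_um <= max_conc, , drop = FALSE]
  nlev <- length(unique(out$conc_um))
  if (nlev < 3L) {
    stopf("only %d level(s) at or below %g uM; need >= 3", nlev, max_conc)
  }
  attr(out, "provenance") <- sprintf(
    "range reduced to conc <= %g uM (%d of %d rows kept)",
    max_conc, nrow(out), nrow(standards))
  out
}

#' Serialize a calibration model to JSON
#'
#' @param model a `calibration_model`.
#' @param path output path.
#' @param extra named list merged into the JSON root (e.g. config, seed).
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "calibration_model"))
  payload <- c(unclass(model), extra)
  # keep coefficient names: named vectors serialize as JSON arrays otherwise
  payload$coefficients <- as.list(payload$coefficients)
  payload$se <- as.list(payload$se)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a calibration model from JSON
#'
#' @param path JSON written by [model_to_json()].
#' @return a `calibration_model`.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) {
    v <- suppressWarnings(as.numeric(unlist(v)))
    if (length(v) == 0L || is.null(v)) NA_real_ else v[1]
  }
  pick <- function(v, nm) num(unlist(v)[nm])
  m <- list(kind = x$kind,
            coefficients = c(a = pick(x$coefficients, "a"),
                             b = pick(x$coefficients, "b"),
                             c = pick(x$coefficients, "c")),
            se = c(a = pick(x$se, "a"), b = pick(x$se, "b"),
                   c = pick(x$se, "c")),
            r_squared = num(x$r_squared), rmse = num(x$rmse),
            rmse_denominator = x$rmse_denominator %||% "n",
            model_p_value = num(x$model_p_value),
            conc_range = as.numeric(x$conc_range),
            centroid_area = num(x$centroid_area),
            n = num(x$n), sxx = num(x$sxx),
            data = if (!is.null(x$data)) as.data.frame(x$data) else NULL)
  structure(m, class = "calibration_model")
}
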