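# Chromatogram container, CSV I/O, peak detection, trapezoidal integration
# and retention-time identity assignment.  Peak areas (LU*min) are the raw
# response every downstream stage consumes.

#' Construct a chromatogram
#'
#' @param time strictly increasing uniform grid, minutes.
#' @param intensity fluorescence intensity, luminescence units (LU).
#' @param metadata named list (detector, wavelengths, run id, ...).
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(time, intensity, metadata = list()) {
  if (length(time) < 2L) stopf("a chromatogram needs at least 2 points")
  if (length(time) != length(intensity)) {
    stopf("time and intensity lengths differ (%d vs %d)",
          length(time), length(intensity))
  }
  if (anyNA(time) || anyNA(intensity)) stopf("missing values not allowed")
  steps <- diff(time)
  if (any(steps <= 0)) {
    stopf("time must be strictly increasing (first violation after index %d)",
          which(steps <= 0)[1])
  }
  step <- steps[1]
  if (any(abs(steps - step) > 1e-9 * max(step, 1))) {
    stopf("time grid is not uniform (relative tolerance 1e-9)")
  }
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 metadata = metadata),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points, %.3f-%.3f min, step %.4g min\n",
              length(x$time), x$time[1], x$time[length(x$time)],
              x$time[2] - x$time[1]))
  invisible(x)
}

#' Write a chromatogram to CSV (with a JSON metadata sidecar)
#'
#' Columns are `time_min,intensity_lu`; metadata goes to `<path>.json`.
#'
#' @param chrom a [chromatogram()].
#' @param path output CSV path.
#' @param sidecar write the JSON metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path, sidecar = TRUE) {
  stopifnot(inherits(chrom, "chromatogram"))
  df <- data.frame(time_min = format(chrom$time, digits = 15, trim = TRUE),
                   intensity_lu = format(chrom$intensity, digits = 15,
                                         trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar && length(chrom$metadata)) {
    jsonlite::write_json(chrom$metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a chromatogram from CSV
#'
#' Expects header `time_min,intensity_lu`.  Malformed (non-numeric or
#' missing) rows and non-monotone time values are rejected with the
#' offending data line number.
#'
#' @param path CSV path (a `<path>.json` sidecar, if present, is loaded as
#'   metadata).
#' @return a [chromatogram()].
#' @export
read_chromatogram <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character")
  if (nrow(raw) == 0L) stopf("empty chromatogram file: %s", path)
  if (!all(c("time_min", "intensity_lu") %in% names(raw))) {
    stopf("expected header 'time_min,intensity_lu' in %s", path)
  }
  time <- suppressWarnings(as.numeric(raw$time_min))
  intensity <- suppressWarnings(as.numeric(raw$intensity_lu))
  bad <- which(is.na(time) | is.na(intensity))
  if (length(bad)) {
    stopf("malformed rows at data line(s) %s of %s",
          paste(utils::head(bad, 5), collapse = ", "), path)
  }
  nonmono <- which(diff(time) <= 0)
  if (length(nonmono)) {
    stopf("time not strictly increasing at data line %d of %s",
          nonmono[1] + 1L, path)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  chromatogram(time, intensity, metadata = meta)
}

#' Integrate a peak window by the trapezoidal rule
#'
#' Integrates intensity minus a baseline estimate over `[start, end]`.
#' The window endpoints are linearly interpolated onto the grid so that
#' integration is exactly additive over adjacent windows.
#'
#' @param chrom a [chromatogram()].
#' @param window numeric length-2: window start and end, minutes.
#' @param baseline `"linear_endpoints"` (default: subtract the chord joining
#'   the two window endpoints), `"constant_min"` (subtract the window
#'   minimum) or `"none"`.
#' @return area in LU*min (may be negative after baseline correction).
#' @export
integrate_peak <- function(chrom, window,
                           baseline = c("linear_endpoints", "constant_min",
                                        "none")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(chrom, "chromatogram"), length(window) == 2L)
  a <- window[1]; b <- window[2]
  if (!(a < b)) stopf("window start must be < end")
  t <- chrom$time
  if (a < t[1] || b > t[length(t)]) {
    stopf("window [%g, %g] outside the time grid [%g, %g]",
          a, b, t[1], t[length(t)])
  }
  inner <- t > a & t < b
  tt <- c(a, t[inner], b)
  yy <- c(stats::approx(t, chrom$intensity, xout = a)$y,
          chrom$intensity[inner],
          stats::approx(t, chrom$intensity, xout = b)$y)
  base <- switch(baseline,
    none = 0,
    constant_min = min(yy),
    linear_endpoints = yy[1] + (yy[length(yy)] - yy[1]) * (tt - a) / (b - a))
  y <- yy - base
  sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Detect peaks in a chromatogram
#'
#' Finds local maxima whose apex rises at least `min_height` above the
#' signal minimum and whose topographic prominence exceeds
#' `min_prominence`.  Window bounds are placed at the lowest point between
#' neighbouring detected peaks (the valley) or at the signal edges.  Peaks
#' whose apices lie closer than `merge_window` are both reported but
#' flagged `overlapping`; no curve deconvolution is attempted.
#'
#' @param chrom a [chromatogram()].
#' @param min_height minimum apex height above the signal minimum, LU.
#' @param min_prominence minimum prominence, LU (default `min_height / 2`).
#' @param merge_window apex spacing below which peaks are flagged
#'   overlapping, minutes.
#' @return a peak table: `data.frame(label, rt_min, area_lu_min, height_lu,
#'   window_start, window_end, overlapping)`; empty for a flat signal.
#' @export
detect_peaks <- function(chrom, min_height, min_prominence = min_height / 2,
                         merge_window = 0.2) {
  stopifnot(inherits(chrom, "chromatogram"), is_number(min_height),
            min_height > 0)
  y <- chrom$intensity
  t <- chrom$time
  n <- length(y)
  floor_lu <- min(y)
  empty <- data.frame(label = character(), rt_min = numeric(),
                      area_lu_min = numeric(), height_lu = numeric(),
                      window_start = numeric(), window_end = numeric(),
                      overlapping = logical())

  # strict local maxima (left-edge of plateaus)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] - floor_lu >= min_height]
  if (length(cand) == 0L) return(empty)

  prominence <- vapply(cand, function(i) {
    lmin <- y[i]; j <- i
    while (j > 1L && y[j - 1L] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    left <- if (j == 1L) min(y[1:i]) else lmin
    rmin <- y[i]; j <- i
    while (j < n && y[j + 1L] <= y[i]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    right <- if (j == n) min(y[i:n]) else rmin
    y[i] - max(left, right)
  }, numeric(1))
  keep <- prominence >= min_prominence
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty)

  # valley-bounded windows between consecutive retained apices
  bounds <- integer(length(cand) + 1L)
  bounds[1] <- 1L
  bounds[length(bounds)] <- n
  if (length(cand) > 1L) {
    for (k in seq_len(length(cand) - 1L)) {
      seg <- cand[k]:cand[k + 1L]
      bounds[k + 1L] <- seg[which.min(y[seg])]
    }
  }

  rows <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    lo <- bounds[k]; hi <- bounds[k + 1L]
    # trim flat tails: walk downhill from the apex and stop where the signal
    # re-crosses 0.1% of the peak height above the valley level (about
    # +/- 3.7 sigma for a Gaussian), so long baseline stretches don't enter
    # the window; bounded by the valley either way
    thr_l <- y[lo] + 0.001 * (y[i] - y[lo])
    j <- i
    while (j > lo && y[j - 1L] > thr_l) j <- j - 1L
    lo <- max(lo, j - 1L)
    thr_r <- y[hi] + 0.001 * (y[i] - y[hi])
    j <- i
    while (j < hi && y[j + 1L] > thr_r) j <- j + 1L
    hi <- min(hi, j + 1L)
    height <- y[i] - (y[lo] + y[hi]) / 2
    data.frame(label = "unknown", rt_min = t[i],
               area_lu_min = integrate_peak(chrom, c(t[lo], t[hi]),
                                            baseline = "linear_endpoints"),
               height_lu = height, window_start = t[lo], window_end = t[hi],
               overlapping = FALSE)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) > 1L) {
    d <- abs(outer(out$rt_min, out$rt_min, "-"))
    diag(d) <- Inf
    out$overlapping <- apply(d < merge_window, 1, any)
  }
  out
}

#' Assign peak identities by retention time
#'
#' Each peak receives the label of the nearest reference retention time
#' within `tolerance`; unmatched peaks are labelled `"unknown"`.  A
#' reference can be claimed by only one peak — the closer apex wins and the
#' displaced peak reverts to `"unknown"`.
#'
#' @param peaks peak table from [detect_peaks()].
#' @param references named numeric of reference retention times, minutes
#'   (default `c(SDB = 11.8, MBB = 12.8)`, the assay's landmarks).
#' @param tolerance matching half-window, minutes (default 0.2).
#' @return the peak table with `label` filled in.
#' @export
assign_identity <- function(peaks, references = c(SDB = 11.8, MBB = 12.8),
                            tolerance = 0.2) {
  stopifnot(is_number(tolerance), tolerance > 0, length(references) > 0)
  peaks$label <- "unknown"
  if (nrow(peaks) == 0L) return(peaks)
  d <- abs(outer(peaks$rt_min, references, "-"))
  d[d > tolerance] <- Inf
  # greedy by increasing distance: closer apex wins each reference
  while (any(is.finite(d))) {
    idx <- arrayInd(which.min(d), dim(d))
    peaks$label[idx[1]] <- names(references)[idx[2]]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
  }
  peaks
}

#' Write a peak table to CSV
#'
#' @param peaks peak table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
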