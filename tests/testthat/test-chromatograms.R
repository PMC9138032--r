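# Chromatogram I/O, peak detection, integration, identity assignment.

test_that("CSV round trip preserves a chromatogram", {
  ch <- chromatogram(c(0, 0.5, 1), c(1.25, 7.5, 2.125),
                     metadata = list(run_id = "rt1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(ch, path)
  back <- read_chromatogram(path)
  expect_equal(back$time, ch$time, tolerance = 1e-12)
  expect_equal(back$intensity, ch$intensity, tolerance = 1e-12)
  expect_equal(back$metadata$run_id, "rt1")
})

test_that("malformed and non-monotone files are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,intensity_lu", "0,1", "2,3", "1,4"), path)
  expect_error(read_chromatogram(path), "line 3")
  writeLines(c("time_min,intensity_lu", "0,1", "abc,2"), path)
  expect_error(read_chromatogram(path), "line.*2")
  writeLines("time_min,intensity_lu", path)
  expect_error(read_chromatogram(path), "empty")
})

test_that("a simulated 23-min run at 5 points/s reads back with 6900 rows", {
  ch <- gen_chromatogram(list(), duration = 23, sampling_rate = 300)
  expect_length(ch$time, 6900)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(ch, path, sidecar = FALSE)
  expect_length(read_chromatogram(path)$time, 6900)
})

test_that("chromatogram construction enforces the uniform-grid invariants", {
  expect_error(chromatogram(1, 1), "at least 2")
  expect_error(chromatogram(c(0, 1, 1.5), c(0, 0, 0)), "not uniform")
  expect_error(chromatogram(c(0, 1, 0.5), c(0, 0, 0)), "increasing")
  expect_error(chromatogram(c(0, 1), c(NA, 0)), "missing")
})

test_that("two constructed Gaussians are detected at their apices", {
  pks <- list(peak_spec(11.8, 100, 0.05, label = "SDB"),
              peak_spec(12.8, 300, 0.05, label = "MBB"))
  ch <- gen_chromatogram(pks, 23, 300)
  found <- detect_peaks(ch, min_height = 10)
  expect_equal(nrow(found), 2)
  step <- 1 / 300
  expect_equal(found$rt_min, c(11.8, 12.8), tolerance = step)
  expect_false(any(found$overlapping))
})

test_that("a flat signal yields an empty peak table", {
  ch <- chromatogram(seq(0, 10, by = 0.01), rep(0, 1001))
  expect_equal(nrow(detect_peaks(ch, min_height = 1)), 0)
})

test_that("seeded signals: detected apices stay within one sample step of truth", {
  rts <- c(4, 8, 12, 16)
  step <- 1 / 40
  for (s in 1:50) {
    specs <- withr::with_seed(s, lapply(rts, function(rt) {
      peak_spec(rt, height = runif(1, 50, 200), width_sigma = runif(1, 0.05, 0.1))
    }))
    ch <- gen_chromatogram(specs, duration = 20, sampling_rate = 40,
                           noise_sd = 1, seed = s + 1000)
    found <- detect_peaks(ch, min_height = 25, min_prominence = 25)
    expect_equal(nrow(found), length(rts))
    expect_true(all(abs(found$rt_min - rts) <= step + 1e-12))
  }
})

test_that("peaks closer than the merge window are flagged overlapping", {
  pks <- list(peak_spec(11.8, 100, 0.04), peak_spec(11.95, 120, 0.04))
  ch <- gen_chromatogram(pks, 23, 600)
  found <- detect_peaks(ch, min_height = 20, min_prominence = 20,
                        merge_window = 0.2)
  expect_equal(nrow(found), 2)
  expect_true(all(found$overlapping))
})

test_that("integration matches the analytic Gaussian and tolerates baselines", {
  pk <- peak_spec(11.8, 100, 0.05)
  analytic <- 100 * 0.05 * sqrt(2 * pi)
  ch0 <- gen_chromatogram(list(pk), 23, 1200)     # 60 samples per sigma
  w <- c(11.8 - 0.2, 11.8 + 0.2)                  # +/- 4 sigma
  expect_equal(integrate_peak(ch0, w, "none"), analytic, tolerance = 1e-3)
  ch5 <- gen_chromatogram(list(pk), 23, 1200, baseline_level = 5)
  expect_equal(integrate_peak(ch5, w, "linear_endpoints"), analytic,
               tolerance = 2e-3)
})

test_that("trapezoid agrees with a 10x-oversampled rectangle-rule oracle", {
  for (s in 1:50) {
    specs <- withr::with_seed(s, lapply(c(5, 10, 15), function(rt) {
      peak_spec(rt + runif(1, -0.5, 0.5), runif(1, 20, 150),
                runif(1, 0.05, 0.2))
    }))
    rate <- 100
    ch <- gen_chromatogram(specs, 20, rate, baseline_level = 2,
                           drift_slope = 0.1)
    fine <- gen_chromatogram(specs, 20, rate * 10, baseline_level = 2,
                             drift_slope = 0.1)
    w <- c(3, 17)
    inside <- fine$time >= w[1] & fine$time < w[2]
    oracle <- sum(fine$intensity[inside]) / (rate * 10)
    got <- integrate_peak(ch, w, "none")
    expect_equal(got, oracle, tolerance = 5e-3)
  }
})

test_that("integration is additive over adjacent windows (baseline none)", {
  ch <- gen_chromatogram(list(peak_spec(10, 80, 0.3)), 20, 100,
                         noise_sd = 1, seed = 3)
  ab <- integrate_peak(ch, c(5, 10.003), "none")
  bc <- integrate_peak(ch, c(10.003, 15), "none")
  ac <- integrate_peak(ch, c(5, 15), "none")
  expect_equal(ab + bc, ac, tolerance = 1e-9)
})

test_that("linear-endpoint baseline removes any constant offset", {
  pk <- peak_spec(10, 100, 0.1)
  ch0 <- gen_chromatogram(list(pk), 20, 500)
  ch9 <- gen_chromatogram(list(pk), 20, 500, baseline_level = 9)
  w <- c(9.5, 10.5)
  expect_equal(integrate_peak(ch0, w, "linear_endpoints"),
               integrate_peak(ch9, w, "linear_endpoints"), tolerance = 1e-9)
})

test_that("windows outside the grid are rejected", {
  ch <- chromatogram(seq(0, 10, 0.1), rep(1, 101))
  expect_error(integrate_peak(ch, c(5, 11)), "outside")
  expect_error(integrate_peak(ch, c(6, 6)), "start must be")
})

test_that("identities are assigned by nearest reference within tolerance", {
  pk <- data.frame(label = "unknown", rt_min = c(11.79, 12.81),
                   area_lu_min = c(10, 20), height_lu = c(5, 8),
                   window_start = c(11.5, 12.5), window_end = c(12.1, 13.1),
                   overlapping = FALSE)
  out <- assign_identity(pk)
  expect_equal(out$label, c("SDB", "MBB"))
  far <- pk[1, ]; far$rt_min <- 10
  expect_equal(assign_identity(far)$label, "unknown")
})

test_that("a reference is claimed only by the closest apex", {
  pk <- data.frame(label = "unknown", rt_min = c(11.75, 11.82),
                   area_lu_min = c(1, 2), height_lu = c(1, 2),
                   window_start = 11.5, window_end = 12.0,
                   overlapping = TRUE)
  out <- assign_identity(pk, references = c(SDB = 11.8, MBB = 12.8))
  expect_equal(out$label, c("unknown", "SDB"))
})
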