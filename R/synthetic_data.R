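# Seeded generators for every input the pipeline consumes: fluorescence
# chromatograms, calibration standards tables, serum speciation cohorts and
# matrix-effect area pairs.  Every generator is a pure function of its
# arguments including the seed, so any downstream result is reproducible
# bit-for-bit.

#' Specify a chromatographic peak for simulation
#'
#' @param retention_time apex position, minutes.
#' @param height peak amplitude, luminescence units (LU).  For the `"emg"`
#'   shape this is the amplitude of the underlying Gaussian before
#'   exponential broadening, so the integrated area is
#'   `height * width_sigma * sqrt(2*pi)` for both shapes.
#' @param width_sigma Gaussian sigma, minutes.
#' @param shape `"gaussian"` or `"emg"` (exponentially modified Gaussian,
#'   for tailing peaks).
#' @param tail_tau exponential tail constant, minutes; required for `"emg"`.
#' @param label free-text identity (e.g. `"SDB"`, `"MBB"`).
#' @return object of class `peak_spec`.
#' @export
peak_spec <- function(retention_time, height, width_sigma,
                      shape = c("gaussian", "emg"), tail_tau = NULL,
                      label = "unknown") {
  shape <- match.arg(shape)
  stopifnot(is_number(retention_time), is_number(height), is_number(width_sigma))
  if (height < 0) stopf("peak '%s': height must be >= 0", label)
  if (width_sigma <= 0) stopf("peak '%s': width_sigma must be > 0", label)
  if (shape == "emg") {
    if (is.null(tail_tau) || !is_number(tail_tau) || tail_tau <= 0) {
      stopf("peak '%s': emg shape requires tail_tau > 0", label)
    }
  }
  structure(list(retention_time = retention_time, height = height,
                 width_sigma = width_sigma, shape = shape,
                 tail_tau = tail_tau, label = label),
            class = "peak_spec")
}

# Evaluate one peak on the time grid.  The EMG uses the standard
# sigma/tau parameterisation whose integral matches the parent Gaussian.
.peak_profile <- function(spec, time) {
  z <- (time - spec$retention_time) / spec$width_sigma
  if (spec$shape == "gaussian") {
    spec$height * exp(-0.5 * z^2)
  } else {
    s <- spec$width_sigma
    tau <- spec$tail_tau
    erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
    arg <- 0.5 * (s / tau)^2 - (time - spec$retention_time) / tau
    spec$height * (s / tau) * sqrt(pi / 2) * exp(arg) *
      erfc((s / tau - (time - spec$retention_time) / s) / sqrt(2))
  }
}

#' Simulate a fluorescence-detector chromatogram
#'
#' Builds a uniform time grid of `ceiling(duration * sampling_rate)` points
#' and superimposes the requested peaks on a (possibly drifting) baseline
#' with optional Gaussian noise.  Identical arguments and seed reproduce
#' the signal exactly.
#'
#' @param peaks list of [peak_spec()] objects (a single `peak_spec` is
#'   accepted).
#' @param duration run length, minutes (default 23, a typical gradient run).
#' @param sampling_rate points per minute.
#' @param baseline_level constant baseline, LU.
#' @param drift_slope linear baseline drift, LU/min.
#' @param noise_sd Gaussian noise SD, LU.
#' @param seed integer seed for the noise draw; `NULL` uses the current
#'   RNG stream.
#' @param metadata named list merged over the default detector settings
#'   (excitation 390 nm, emission 475 nm).
#' @return a [chromatogram()] object.
#' @examples
#' pk <- peak_spec(11.8, height = 100, width_sigma = 0.05, label = "SDB")
#' ch <- gen_chromatogram(list(pk), duration = 23, sampling_rate = 300)
#' @export
gen_chromatogram <- function(peaks, duration = 23, sampling_rate = 300,
                             baseline_level = 0, drift_slope = 0,
                             noise_sd = 0, seed = NULL, metadata = list()) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(is_number(duration), duration > 0,
            is_number(sampling_rate), sampling_rate > 0,
            is_number(noise_sd), noise_sd >= 0)
  for (pk in peaks) {
    if (!inherits(pk, "peak_spec")) stopf("peaks must be peak_spec objects")
    if (pk$retention_time < 0 || pk$retention_time > duration) {
      stopf("peak '%s' at %.3f min lies outside the run [0, %g]",
            pk$label, pk$retention_time, duration)
    }
  }
  n <- ceiling(duration * sampling_rate)
  time <- (seq_len(n) - 1) / sampling_rate
  signal <- baseline_level + drift_slope * time
  for (pk in peaks) signal <- signal + .peak_profile(pk, time)
  if (noise_sd > 0) {
    signal <- signal + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  meta <- utils::modifyList(
    list(detector = "FLD", excitation_nm = 390, emission_nm = 475,
         gradient = paste("water/acetonitrile + 0.1% TFA, 85:15 to 55:45",
                          "over 16 min, 23 min total"),
         noise_sd = noise_sd, seed = seed),
    metadata)
  chromatogram(time, signal, metadata = meta)
}

#' Simulate a calibration standards table
#'
#' Generates peak areas at the given concentration levels from a known
#' ("true") calibration model, with additive per-day offsets and replicate
#' noise.  With both noise terms zero, areas equal model predictions
#' exactly, so refitting recovers the true coefficients.
#'
#' @param true_model a [calibration_model()] (or fitted model) supplying the
#'   response curve.
#' @param conc_levels standard concentrations, uM.  The default is the
#'   assay's seven-level series 0.8-50 uM.
#' @param replicates_per_level replicates per level per day (default 5).
#' @param noise_sd replicate noise SD, area units (AU).
#' @param n_days number of days; each day draws one additive offset.
#' @param day_effect_sd SD of the per-day offsets, AU.
#' @param seed integer seed.
#' @return a standards table: `data.frame(conc_um, area_au, day, replicate)`.
#' @export
gen_calibration_dataset <- function(true_model,
                                    conc_levels = c(0.8, 1.6, 3, 6, 12.5, 25, 50),
                                    replicates_per_level = 5,
                                    noise_sd = 0, n_days = 1,
                                    day_effect_sd = 0, seed = NULL) {
  if (length(conc_levels) == 0L) stopf("conc_levels must be non-empty")
  if (any(conc_levels <= 0)) stopf("concentrations must be > 0")
  stopifnot(is_count(replicates_per_level), is_count(n_days),
            noise_sd >= 0, day_effect_sd >= 0)
  grid <- expand.grid(replicate = seq_len(replicates_per_level),
                      conc_um = conc_levels,
                      day = seq_len(n_days),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- predict_area(true_model, grid$conc_um, warn_out_of_range = FALSE)
  area <- with_seed(seed, {
    day_off <- stats::rnorm(n_days, 0, day_effect_sd)
    mu + day_off[grid$day] + stats::rnorm(nrow(grid), 0, noise_sd)
  })
  out <- data.frame(conc_um = grid$conc_um, area_au = area,
                    day = grid$day, replicate = grid$replicate)
  as_standards_table(out)
}

#' Define a serum-cohort simulation scenario
#'
#' Describes a small clinical cohort sampled at three timepoints (T0 before
#' treatment, T1 immediately after, T2 three days after completion) whose
#' total sulfide rises while free H2S stays flat — the structure seen in
#' serum after inhalation treatment with sulfurous water.
#'
#' @param n_patients number of patients (default 4).
#' @param pool_means_t0 named baseline means, uM, for `free`, `acid_labile`
#'   and `bound_sulfane`.
#' @param t2_total_increase fractional change of total sulfide at T2
#'   (default 0.4, i.e. +40%).
#' @param free_change fractional change of the free pool at T2 (default 0).
#' @param t1_fraction fraction of the T2 effect realised at T1 (default 0.5).
#' @param between_patient_sd per-patient additive offset SD, uM.
#' @param within_replicate_sd per-measurement noise SD, uM.
#' @param seed integer seed.
#' @return object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_patients = 4,
                            pool_means_t0 = c(free = 1.0, acid_labile = 1.5,
                                              bound_sulfane = 2.0),
                            t2_total_increase = 0.4, free_change = 0,
                            t1_fraction = 0.5,
                            between_patient_sd = 0.3,
                            within_replicate_sd = 0.05, seed = 1L) {
  stopifnot(is_count(n_patients), n_patients >= 2)
  pools <- c("free", "acid_labile", "bound_sulfane")
  if (!all(pools %in% names(pool_means_t0))) {
    stopf("pool_means_t0 must name %s", paste(pools, collapse = ", "))
  }
  pool_means_t0 <- pool_means_t0[pools]
  if (any(pool_means_t0 < 0)) stopf("pool means must be >= 0")
  if (t2_total_increase <= -1 || free_change <= -1) {
    stopf("fractional changes must exceed -1")
  }
  stopifnot(between_patient_sd >= 0, within_replicate_sd >= 0,
            t1_fraction >= 0, t1_fraction <= 1)
  structure(list(n_patients = n_patients, pool_means_t0 = pool_means_t0,
                 t2_total_increase = t2_total_increase,
                 free_change = free_change, t1_fraction = t1_fraction,
                 between_patient_sd = between_patient_sd,
                 within_replicate_sd = within_replicate_sd,
                 seed = seed),
            class = "cohort_scenario")
}

# Expected pool means at each timepoint.  The T2 free pool scales by
# (1 + free_change); the remaining total increase is split between the
# acid-labile and bound-sulfane pools in proportion to their baselines.
.scenario_pool_means <- function(scenario) {
  m0 <- scenario$pool_means_t0
  total0 <- sum(m0)
  total2 <- total0 * (1 + scenario$t2_total_increase)
  free2 <- m0[["free"]] * (1 + scenario$free_change)
  rest0 <- m0[c("acid_labile", "bound_sulfane")]
  if (sum(rest0) > 0) {
    rest2 <- (total2 - free2) * rest0 / sum(rest0)
  } else {
    rest2 <- c(acid_labile = (total2 - free2) / 2,
               bound_sulfane = (total2 - free2) / 2)
  }
  m2 <- c(free = free2, rest2)
  m1 <- m0 + scenario$t1_fraction * (m2 - m0)
  rbind(T0 = m0, T1 = m1, T2 = m2)
}

#' Simulate a serum speciation cohort
#'
#' Draws the three sulfide pools (free, acid-labile, bound sulfane) for each
#' patient and timepoint.  Pools are generated and summed — the total is
#' never drawn independently — so free + acid-labile + bound sulfane equals
#' the total for every row by construction.
#'
#' @param scenario a [cohort_scenario()].
#' @return cohort table: `data.frame(patient_id, timepoint, species,
#'   concentration)` with one row per patient x timepoint x pool.
#' @seealso [cohort_add_total()] to append derived total rows.
#' @export
gen_serum_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  mu <- .scenario_pool_means(scenario)      # 3 timepoints x 3 pools
  tps <- rownames(mu)
  pools <- colnames(mu)
  n <- scenario$n_patients
  with_seed(scenario$seed, {
    patient_off <- matrix(stats::rnorm(n * length(pools), 0,
                                       scenario$between_patient_sd),
                          nrow = n, dimnames = list(NULL, pools))
    rows <- expand.grid(patient_id = seq_len(n), timepoint = tps,
                        species = pools, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    conc <- mu[cbind(rows$timepoint, rows$species)] +
      patient_off[cbind(rows$patient_id, match(rows$species, pools))] +
      stats::rnorm(nrow(rows), 0, scenario$within_replicate_sd)
    data.frame(patient_id = paste0("P", rows$patient_id),
               timepoint = rows$timepoint, species = rows$species,
               concentration = conc)
  })
}

#' Append derived total-sulfide rows to a cohort table
#'
#' @param cohort output of [gen_serum_cohort()] (pools only).
#' @return the cohort with additional `species == "total"` rows equal to the
#'   sum of the three pools per patient and timepoint.
#' @export
cohort_add_total <- function(cohort) {
  pools <- c("free", "acid_labile", "bound_sulfane")
  sub <- cohort[cohort$species %in% pools, ]
  tot <- stats::aggregate(concentration ~ patient_id + timepoint, sub, sum)
  tot$species <- "total"
  rbind(cohort, tot[, c("patient_id", "timepoint", "species", "concentration")])
}

#' Matrix-trapping recovery curve
#'
#' Fraction of the standard-solution SDB area retained when the same Na2S
#' concentration is spiked into serum.  The default anchors reproduce the
#' published standard/spiked area pairs 25/22, 180/100 and 400/200 at 5,
#' 12.5 and 25 uM: recovery falls with concentration because part of the
#' added sulfide is trapped by the serum matrix.
#'
#' @param recovery_at_level named numeric: names are concentrations (uM),
#'   values are recovery fractions in (0, 1].
#' @return object of class `matrix_effect_curve`.
#' @export
matrix_effect_curve <- function(recovery_at_level = c("5" = 22 / 25,
                                                      "12.5" = 100 / 180,
                                                      "25" = 200 / 400)) {
  conc <- as.numeric(names(recovery_at_level))
  if (any(is.na(conc))) stopf("curve names must be numeric concentrations")
  if (any(recovery_at_level <= 0 | recovery_at_level > 1)) {
    stopf("recovery fractions must lie in (0, 1]")
  }
  ord <- order(conc)
  structure(list(conc = conc[ord], recovery = unname(recovery_at_level[ord])),
            class = "matrix_effect_curve")
}

#' Interpolate a recovery curve at arbitrary concentrations
#'
#' Log-linear in concentration between anchors; constant beyond the ends.
#'
#' @param curve a [matrix_effect_curve()].
#' @param conc concentrations, uM.
#' @return recovery fractions.
#' @export
recovery_at <- function(curve, conc) {
  stopifnot(inherits(curve, "matrix_effect_curve"), all(conc > 0))
  stats::approx(log(curve$conc), curve$recovery, xout = log(conc),
                rule = 2)$y
}

#' Simulate paired standard-solution and spiked-serum areas
#'
#' @param conc_levels concentrations, uM.
#' @param curve a [matrix_effect_curve()]; default reproduces the published
#'   anchors.
#' @param true_model calibration model giving the standard-solution area;
#'   ignored when `standard_areas` is supplied.
#' @param standard_areas optional explicit standard areas (same length as
#'   `conc_levels`).
#' @param noise_sd optional Gaussian noise on both areas, AU.
#' @param seed integer seed.
#' @return `data.frame(conc_um, standard_area, spiked_area, recovery)`.
#' @export
gen_matrix_effect_pairs <- function(conc_levels,
                                    curve = matrix_effect_curve(),
                                    true_model = NULL,
                                    standard_areas = NULL,
                                    noise_sd = 0, seed = NULL) {
  stopifnot(length(conc_levels) > 0, all(conc_levels > 0))
  rec <- recovery_at(curve, conc_levels)
  if (any(rec <= 0 | rec > 1)) stopf("recovery outside (0, 1]")
  if (is.null(standard_areas)) {
    if (is.null(true_model)) stopf("supply true_model or standard_areas")
    standard_areas <- predict_area(true_model, conc_levels,
                                   warn_out_of_range = FALSE)
  }
  stopifnot(length(standard_areas) == length(conc_levels))
  spiked <- rec * standard_areas
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2L * length(spiked), 0, noise_sd))
    standard_areas <- standard_areas + noise[seq_along(spiked)]
    spiked <- spiked + noise[-seq_along(spiked)]
  }
  data.frame(conc_um = conc_levels, standard_area = standard_areas,
             spiked_area = spiked, recovery = rec)
}
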