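#!/usr/bin/env Rscript
# Step 1 — simulate every input the downstream analyses consume:
# a serum-like FLD chromatogram (SDB at 11.8 min, MBB excess at 12.8 min),
# the seven-level calibration standards table at the assay's fitted noise,
# the published matrix-effect area pairs, and a 4-patient serum cohort.

suppressPackageStartupMessages(library(sdbquant))
seed <- 1234L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

true_model <- calibration_model("linear", a = -0.581, b = 3.51,
                                rmse = 0.514, conc_range = c(0.8, 6))

## chromatogram of a 6 uM standard: SDB plus the late-eluting MBB excess
area_6um <- predict_area(true_model, 6)
h_sdb <- area_6um / (0.05 * sqrt(2 * pi))
chrom <- gen_chromatogram(
  list(peak_spec(11.8, h_sdb, 0.05, label = "SDB"),
       peak_spec(12.8, 2.5 * h_sdb, 0.06, shape = "emg", tail_tau = 0.08,
                 label = "MBB")),
  duration = 23, sampling_rate = 300, baseline_level = 0.5,
  drift_slope = 0.02, noise_sd = 0.05, seed = seed,
  metadata = list(run_id = "standard_6uM"))
write_chromatogram(chrom, file.path(out, "standard_6uM.csv"))
message("chromatogram: ", length(chrom$time), " points, SDB height ",
        round(h_sdb, 1), " LU")

## calibration standards: 7 levels x 5 replicates x 3 days
std <- gen_calibration_dataset(true_model,
                               conc_levels = c(0.8, 1.6, 3, 6, 12.5, 25, 50),
                               replicates_per_level = 5, noise_sd = 0.514,
                               n_days = 3, day_effect_sd = 0.1,
                               seed = seed + 1L)
write.csv(std, file.path(out, "standards.csv"), row.names = FALSE)
message("standards table: ", nrow(std), " rows")

## matrix-effect pairs at the published anchor concentrations
pairs <- gen_matrix_effect_pairs(c(5, 12.5, 25),
                                 standard_areas = c(25, 180, 400))
write.csv(pairs, file.path(out, "matrix_pairs.csv"), row.names = FALSE)

## serum cohort: 4 patients, 3 timepoints, +40% total at T2, free flat
sc <- cohort_scenario(n_patients = 4, t2_total_increase = 0.4,
                      free_change = 0, seed = seed + 2L)
coh <- gen_serum_cohort(sc)
write.csv(coh, file.path(out, "cohort_pools.csv"), row.names = FALSE)
areas <- cohort_to_area_table(coh, true_model, n_injections = 3,
                              area_noise_sd = 0.2, seed = seed + 3L)
write.csv(areas, file.path(out, "cohort_areas.csv"), row.names = FALSE)
message("cohort: ", nrow(coh), " pool rows, ", nrow(areas),
        " injection areas")
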