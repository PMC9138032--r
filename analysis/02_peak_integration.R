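#!/usr/bin/env Rscript
# Step 2 — read the simulated standard chromatogram back from disk, detect
# its peaks, assign identities by retention time against the SDB/MBB
# landmarks and report the baseline-corrected SDB area.

suppressPackageStartupMessages(library(sdbquant))

chrom <- read_chromatogram("results/data/standard_6uM.csv")
peaks <- detect_peaks(chrom, min_height = 2, min_prominence = 2)
peaks <- assign_identity(peaks, references = c(SDB = 11.8, MBB = 12.8),
                         tolerance = 0.2)
write_peak_table(peaks, "results/peaks_standard_6uM.csv")
print(peaks, row.names = FALSE)

sdb <- peaks[peaks$label == "SDB", ]
stopifnot(nrow(sdb) == 1)
true_model <- calibration_model("linear", a = -0.581, b = 3.51,
                                rmse = 0.514, conc_range = c(0.8, 6))
expected <- predict_area(true_model, 6)
message(sprintf("SDB area %.3f LU*min (forward prediction at 6 uM: %.3f)",
                sdb$area_lu_min, expected))
message(sprintf("relative integration error: %.2f%%",
                100 * abs(sdb$area_lu_min - expected) / expected))
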