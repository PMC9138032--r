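#!/usr/bin/env Rscript
# Step 4 — validate the calibration: leave-one-out cross-validation and
# calibration-mode conformity lines, intra-/inter-day precision, and the
# matrix-effect assessment that justifies calibrating with standard
# solutions rather than standard additions to serum.

suppressPackageStartupMessages(library(sdbquant))

std <- as_standards_table(read.csv("results/data/standards.csv"))
red <- reduce_range(std, 6)

for (mode in c("cv", "calibration")) {
  res <- cv_validate(red, "linear", mode = mode)
  cat(sprintf("[%s mode]\n", mode))
  print(res)
}

pr <- precision_study(red, alpha = 0.05)
print(pr)
write.csv(pr$levels, "results/precision_by_level.csv", row.names = FALSE)

pairs <- read.csv("results/data/matrix_pairs.csv")
me <- matrix_effect_assess(
  setNames(pairs$standard_area, pairs$conc_um),
  setNames(pairs$spiked_area, pairs$conc_um))
cat("recoveries:", paste(sprintf("%s uM: %.3f", names(me$recovery),
                                 me$recovery), collapse = ", "), "\n")
cat("matrix verdict:",
    if (me$trapping) "concentration-dependent trapping" else "no trapping",
    "\n")
jsonlite::write_json(me, "results/matrix_effect.json",
                     auto_unbox = TRUE, digits = NA)
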