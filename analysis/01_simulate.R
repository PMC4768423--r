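#!/usr/bin/env Rscript
# Step 1 — simulate a xenograft-like tumor growth study.
#
# Generates the working data set for the analysis: a gompertz-truth volume
# series on the default long-study design (14 measurements over 114 days,
# 10% multiplicative measurement noise), written with its ground truth so
# later steps can score recovery. Edit `seed` to regenerate a different
# replicate; all downstream steps read the files written here.

library(tumorgrowth)

seed <- 1L
dir.create("results", showWarnings = FALSE)

truth <- default_truth("gompertz")
cat("ground truth:\n")
print(truth)
print(clinical_predictions(truth))

gen <- generate_series(truth, v0 = 50, design = study_design(),
                       noise = noise_config(cv = 0.1, seed = seed))
write_series(gen$series, "results/synthetic_series.csv")
write_truth_json(gen, "results/synthetic_truth.json")

cat(sprintf("\nwrote %d observations spanning %.0f days to results/synthetic_series.csv\n",
            nrow(gen$series), max(gen$series$time_days)))
cat(sprintf("early half (first %d points) spans %.1f days\n",
            ceiling(nrow(gen$series) / 2),
            gen$series$time_days[ceiling(nrow(gen$series) / 2)]))
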