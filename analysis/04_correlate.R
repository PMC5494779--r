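#!/usr/bin/env Rscript
# Stage 4: correlate amplitudes and impedances with intraocular pressure.
#
# Pearson correlation on the per-level means (n = 5 pressure levels) with
# exact two-sided small-sample significance, plus ordinary least-squares
# lines, written as a JSON summary.

suppressPackageStartupMessages({
  library(echotonometry)
  library(jsonlite)
})

feat <- read.delim("results/per_iop_features.tsv")
imp <- read.delim("results/per_iop_impedances.tsv")

correlations <- list(
  Z1 = correlate_with_iop(imp$iop_mmHg, imp$Z1_mean_MRayl, "Z1"),
  Z2 = correlate_with_iop(imp$iop_mmHg, imp$Z2_mean_MRayl, "Z2"),
  ant_amp = correlate_with_iop(feat$iop_mmHg, feat$ant_amp_mean, "ant_amp"),
  post_amp = correlate_with_iop(feat$iop_mmHg, feat$post_amp_mean, "post_amp"),
  tof_diff = correlate_with_iop(feat$iop_mmHg, feat$tof_diff_mean_s, "tof_diff")
)

for (cr in correlations) print(cr)

write_json(lapply(correlations, function(cr)
  cr[c("quantity", "r", "n", "t_stat", "df", "p_two_sided",
       "slope", "intercept")]),
  "results/correlations.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/correlations.json")
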