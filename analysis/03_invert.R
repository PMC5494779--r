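#!/usr/bin/env Rscript
# Stage 3: invert echo amplitudes to corneal acoustic impedances.
#
# Rebuilds the calibration constants from the configuration (they are
# deterministic), inverts the anterior echo with the single-interface
# model and the posterior echo with the three-layer model, and aggregates
# per pressure level.

suppressPackageStartupMessages(library(echotonometry))

cfg <- default_config()
cb <- calibrate_endpoints(cfg$calibration$ant_amp_low,
                          cfg$calibration$ant_amp_high,
                          cfg$calibration$post_amp_low)
setup <- reflection_setup(Z0 = cb$Z0, Z3 = cb$Z3, A0 = cb$A0,
                          posterior_gain = cb$posterior_gain)

features <- read.delim("results/features.tsv")
imp <- invert_feature_table(features, setup)
agg <- aggregate_impedances(imp)

write.table(imp, "results/impedances.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(agg, "results/per_iop_impedances.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("per-IOP impedance estimates (MRayl):")
print(agg)
truth <- read.delim("results/truth.tsv")
message(sprintf("max |Z2 - truth| = %.5f MRayl",
                max(abs(agg$Z2_mean_MRayl - truth$Z2_MRayl))))
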