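#!/usr/bin/env Rscript
# Stage 1: generate the synthetic pressure-series experiment.
#
# Calibrates the generator so its linear IOP -> impedance map and its echo
# amplitudes reproduce the published endpoint values, then simulates
# 5 IOP levels (10-50 mmHg) x 3 repeats x 10 A-lines at 1% amplitude noise
# and writes the A-line dataset plus the ground-truth table.

suppressPackageStartupMessages(library(echotonometry))

seed <- 42L
out_dir <- "scratch/alines"   # bulky raw RF records; regenerable from seed

cfg <- default_config(seed = seed)
cb <- calibrate_endpoints(cfg$calibration$ant_amp_low,
                          cfg$calibration$ant_amp_high,
                          cfg$calibration$post_amp_low)
message(sprintf("calibrated constants: Z0 = %.6f MRayl, A0 = %.4f, gain = %.6f",
                cb$Z0, cb$A0, cb$posterior_gain))

sim <- simulate_experiment(cb, aspec = acquisition_spec(seed = seed))
message(sprintf("simulated %d A-lines (noise sd %.5f)",
                length(sim$records), sim$noise_sd))

write_aline_dataset(sim, out_dir)
dir.create("results", showWarnings = FALSE)
write.table(sim$truth, "results/truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote ", out_dir, "/ and results/truth.tsv")
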