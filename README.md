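# echotonometry

Corneal acoustic impedance from pulse-echo ultrasound, and its
correlation with intraocular pressure (IOP).

Rising IOP stiffens the cornea, and because acoustic impedance
`Z = ρc` tracks stiffness while corneal density stays fixed, the
amplitude of the ultrasound echo from each corneal surface carries a
pressure signal. This package implements the full measurement chain for
a single focused high-frequency transducer insonifying the layered stack
saline (`Z0`) / anterior cornea (`Z1`) / posterior cornea (`Z2`) /
aqueous humor (`Z3`):

* anterior echo: `A1/A0 = (Z1 − Z0)/(Z1 + Z0)`, inverted for `Z1`;
* posterior echo: `Ar/A0 = T01 · R23 · T10 · g` with
  `T01·T10 = 4·Z0·Z1/(Z0+Z1)²`, `R23 = (Z3 − Z2)/(Z3 + Z2)`, and a
  scalar geometric gain `g` for the curved interface, inverted for `Z2`;
* incident amplitude `A0` calibrated from a quartz reference echo;
* Pearson correlation of per-pressure means with IOP, with exact
  small-sample two-sided significance via
  `t = r·√((n−2)/(1−r²))`, df = n − 2.

Because no raw RF data from the source experiment is public, a synthetic
A-line generator reproduces its design — 47-MHz pulse, 62% bandwidth,
1-GHz sampling, 10 A-lines × 3 repeats × five IOP levels (10–50 mmHg) —
with ground-truth impedances varying linearly between the published
endpoints. Feature extraction (analytic-signal envelope, parabolic
sub-sample peak fitting) and inversion then recover those impedances.

## Worked example

```r
library(echotonometry)
res <- run_pipeline(default_config(seed = 42L))
res$per_iop_impedances[, 1:5]
#>   iop_mmHg Z1_mean_MRayl  Z1_sd_MRayl Z2_mean_MRayl  Z2_sd_MRayl
#> 1       10      1.539725 0.0001819855      1.539011 0.0004826655
#> 2       20      1.542699 0.0001248169      1.546712 0.0005090917
#> 3       30      1.545701 0.0001673869      1.554343 0.0004070284
#> 4       40      1.548702 0.0002138122      1.561726 0.0004558958
#> 5       50      1.551659 0.0002380749      1.569537 0.0005446313
res$correlations$Z2
#> Z2 vs IOP: r = 1.0000 (n = 5, t = 222.038, df = 3, p = 2.014e-07)
#>   linear fit: slope = 0.00076066 per mmHg, intercept = 1.53145
```

The per-level mean posterior impedance climbs from 1.5390 at 10 mmHg to
1.5695 MRayl at 50 mmHg — within 0.0005 MRayl of the generator's linear
truth at every level — and correlates essentially perfectly with
pressure under the default 1% amplitude noise. The anterior impedance
rises more shallowly (1.5397 to 1.5517 MRayl), reflecting its smaller
calibrated endpoint span.

The same chain can be run stage by stage as scripts, each writing its
tables under `results/` (raw A-line records go to `scratch/`):

```sh
Rscript analysis/01_simulate.R    # calibrate generator, write A-lines + truth
Rscript analysis/02_features.R    # envelope + parabolic fits, per-IOP means
Rscript analysis/03_invert.R      # amplitudes -> Z1, Z2 per A-line and per IOP
Rscript analysis/04_correlate.R   # Pearson r, p, OLS lines -> correlations.json
```

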