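# Shared fixtures: everything is generated in code at test time.

default_calib <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- calibrate_endpoints()
    val
  }
})

# Small noiseless single-A-line acquisition, for fast feature tests.
quiet_aspec <- function(seed = 1L, noise_sd = 0)
  acquisition_spec(n_alines = 1L, n_repeats = 1L, noise_sd = noise_sd,
                   seed = seed)

# Repeated default-noise pipeline runs, cached so several property tests
# can share one set of simulations.
pipeline_runs <- local({
  runs <- NULL
  function(n_seeds = 20L) {
    if (is.null(runs) || length(runs) < n_seeds) {
      runs <<- lapply(seq_len(n_seeds), function(s)
        run_pipeline(default_config(seed = 1000L + s)))
    }
    runs[seq_len(n_seeds)]
  }
})

# Dense-grid argmax of a 100x-upsampled envelope: the independent oracle
# for sub-sample peak location/height (spline interpolation of the
# envelope samples).
upsampled_argmax <- function(envelope, window, dt, factor = 100L) {
  x <- window - 1
  f <- stats::splinefun(x, envelope[window], method = "natural")
  xx <- seq(min(x), max(x), by = 1 / factor)
  yy <- f(xx)
  i <- which.max(yy)
  list(tof = xx[i] * dt, amplitude = yy[i])
}
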