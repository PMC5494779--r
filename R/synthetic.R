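#' Calibrate stack constants from endpoint amplitudes
#'
#' Solves for the three constants that make the forward model consistent
#' with measured endpoint values: the coupling-medium impedance `Z0`, the
#' incident amplitude `A0`, and the posterior geometric gain.
#'
#' Given anterior echo amplitudes at the low and high pressure endpoints
#' and the known impedance endpoints in `cal`, the amplitude ratio depends
#' on `Z0` alone:
#' `R(Z0, Z1_high) / R(Z0, Z1_low) = ant_amp_high / ant_amp_low`,
#' which is solved by 1-D root finding on (0, min(Z1_low, Z1_high)).
#' `A0` then follows from the low endpoint, and the posterior gain from
#' the posterior amplitude at the low endpoint with `Z3 = Z0`.
#'
#' @param ant_amp_low,ant_amp_high Anterior envelope-peak amplitudes at
#'   `cal$iop_low` and `cal$iop_high`, arbitrary units.
#' @param post_amp_low Posterior envelope-peak amplitude at `cal$iop_low`.
#' @param cal An [iop_calibration()].
#' @param cornea_thickness,cornea_speed Geometry passed through to the
#'   returned stacks.
#' @return A list with `Z0`, `Z3` (= `Z0`), `A0`, `posterior_gain`, the
#'   calibration `cal`, and a function `stack_at(iop)` returning the
#'   ground-truth [layer_stack()] at a pressure level.
#' @export
calibrate_endpoints <- function(ant_amp_low = 1.6347,
                                ant_amp_high = 2.1454,
                                post_amp_low = 0.5778,
                                cal = iop_calibration(),
                                cornea_thickness = 0.8e-3,
                                cornea_speed = 1580) {
  stopifnot(inherits(cal, "iop_calibration"))
  if (ant_amp_low <= 0 || ant_amp_high <= 0 || post_amp_low <= 0)
    stop("amplitudes must be positive", call. = FALSE)
  ratio <- ant_amp_high / ant_amp_low
  if (abs(ratio - 1) < 1e-12)
    stop("anterior amplitude ratio must differ from 1", call. = FALSE)
  Z1l <- cal$Z1_low; Z1h <- cal$Z1_high
  upper <- min(Z1l, Z1h)
  fn <- function(Z0) {
    reflection_coefficient(Z0, Z1h) / reflection_coefficient(Z0, Z1l) - ratio
  }
  lo <- upper * 1e-9; hi <- upper * (1 - 1e-9)
  if (fn(lo) * fn(hi) > 0)
    stop("no Z0 root in (0, min(Z1_low, Z1_high)): endpoints inconsistent",
         call. = FALSE)
  Z0 <- stats::uniroot(fn, c(lo, hi), tol = 1e-14)$root
  A0 <- ant_amp_low / reflection_coefficient(Z0, Z1l)
  Z3 <- Z0
  g <- post_amp_low / (A0 * transmission_product(Z0, Z1l) *
                         abs(reflection_coefficient(Z3, cal$Z2_low)))
  stack_at <- function(iop) {
    z <- iop_to_impedances(iop, cal)
    layer_stack(Z0 = Z0, Z1 = z[["Z1"]], Z2 = z[["Z2"]], Z3 = Z3,
                cornea_thickness = cornea_thickness,
                cornea_speed = cornea_speed,
                posterior_gain = g, A0 = A0)
  }
  list(Z0 = Z0, Z3 = Z3, A0 = A0, posterior_gain = g, cal = cal,
       stack_at = stack_at)
}

# Gaussian temporal sigma (s) giving a -6 dB full spectral width of
# fractional_bandwidth * center_frequency.
pulse_sigma_t <- function(tspec) {
  bw <- tspec$fractional_bandwidth * tspec$center_frequency
  sigma_f <- bw / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

#' Gaussian-enveloped reference pulse
#'
#' The transmit pulse is modelled as a cosine at the center frequency under
#' a Gaussian envelope whose -6 dB spectral full width equals the
#' fractional bandwidth times the center frequency. The envelope peaks at
#' exactly 1 at the pulse center.
#'
#' @param tspec A [transducer_spec()].
#' @param dt Sampling interval in s; must satisfy
#'   `1/dt >= 4 * center_frequency`.
#' @param n_sigma Half-duration of the returned support in units of the
#'   envelope sigma (default 5).
#' @return A list with `samples` (the waveform), `t` (times, s, centered
#'   on 0) and `sigma_t` (envelope sigma, s).
#' @export
gaussian_pulse <- function(tspec, dt, n_sigma = 5) {
  stopifnot(inherits(tspec, "transducer_spec"))
  if (1 / dt < 4 * tspec$center_frequency)
    stop("sampling rate below 4x center frequency", call. = FALSE)
  sigma_t <- pulse_sigma_t(tspec)
  half <- ceiling(n_sigma * sigma_t / dt)
  t <- seq(-half, half) * dt
  s <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * tspec$center_frequency * t)
  list(samples = s, t = t, sigma_t = sigma_t)
}

# Evaluate the pulse at arbitrary (possibly sub-sample) delay tau on the
# record's time grid; amplitude `a` is signed.
pulse_at <- function(t, tau, a, f0, sigma_t) {
  u <- t - tau
  a * exp(-u^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * u)
}

#' Simulate one A-line
#'
#' Builds a noiseless record with two echoes — the anterior-surface echo of
#' signed amplitude `A0 * R(Z0, Z1)` at `anterior_arrival`, and the
#' posterior-surface echo of signed amplitude
#' `A0 * T01 T10 * R(Z3, Z2) * posterior_gain` delayed by the two-way
#' corneal transit time `2 * thickness / speed` — then adds independent
#' white Gaussian noise of standard deviation `aspec$noise_sd` per sample.
#'
#' Randomness is drawn from the current RNG state; callers that need
#' reproducibility set the seed (as [simulate_experiment()] does).
#'
#' @param stack A [layer_stack()].
#' @param tspec A [transducer_spec()].
#' @param aspec An [acquisition_spec()]; `noise_sd` must be resolved
#'   (non-`NA`) by this point.
#' @param iop Pressure label attached to the record, mmHg.
#' @param eye_id,repeat_id,aline_id Provenance identifiers.
#' @return An `aline_record`: list with `samples`, `dt`, `iop`, `eye_id`,
#'   `repeat_id`, `aline_id`.
#' @export
simulate_aline <- function(stack, tspec, aspec, iop,
                           eye_id = 1L, repeat_id = 1L, aline_id = 1L) {
  stopifnot(inherits(stack, "layer_stack"), inherits(tspec, "transducer_spec"),
            inherits(aspec, "acquisition_spec"))
  dt <- 1 / aspec$sampling_rate
  sigma_t <- pulse_sigma_t(tspec)
  tau_sep <- 2 * stack$cornea_thickness / stack$cornea_speed
  # resolvability: echo separation must exceed the pulse duration
  if (tau_sep <= 2 * 5 * sigma_t)
    stop("echoes unresolvable: two-way corneal transit time ",
         "does not exceed the pulse duration", call. = FALSE)
  tau_a <- aspec$anterior_arrival
  tau_p <- tau_a + tau_sep
  t <- (seq_len(aspec$record_length) - 1L) * dt
  if (tau_p + 5 * sigma_t > t[length(t)])
    stop("record too short for the posterior echo", call. = FALSE)
  a_ant <- stack$A0 * reflection_coefficient(stack$Z0, stack$Z1)
  # wave travels inside the cornea (Z2) and reflects off the aqueous (Z3):
  # R23 = (Z3 - Z2)/(Z3 + Z2), negative when the cornea is denser
  a_post <- stack$A0 * transmission_product(stack$Z0, stack$Z1) *
    reflection_coefficient(stack$Z2, stack$Z3) * stack$posterior_gain
  f0 <- tspec$center_frequency
  s <- pulse_at(t, tau_a, a_ant, f0, sigma_t) +
    pulse_at(t, tau_p, a_post, f0, sigma_t)
  noise_sd <- aspec$noise_sd
  if (is.na(noise_sd))
    stop("noise_sd is unresolved; set it or use simulate_experiment()",
         call. = FALSE)
  if (noise_sd > 0)
    s <- s + stats::rnorm(length(s), sd = noise_sd)
  structure(list(samples = s, dt = dt, iop = iop,
                 eye_id = eye_id, repeat_id = repeat_id, aline_id = aline_id),
            class = "aline_record")
}

#' Simulate a full pressure-series experiment
#'
#' Generates `n_repeats * n_alines` A-lines at each requested pressure
#' level, with ground-truth impedances from the calibration's linear map.
#' If `aspec$noise_sd` is `NA` it is resolved to 1% of the anterior echo
#' amplitude at the lowest calibrated pressure. The RNG seed is taken from
#' `aspec$seed`, so the whole dataset is reproducible from the
#' configuration alone.
#'
#' @param calib Result of [calibrate_endpoints()] (or a compatible list
#'   with a `stack_at(iop)` function and `cal`).
#' @param tspec A [transducer_spec()].
#' @param aspec An [acquisition_spec()].
#' @param iops Pressure levels in mmHg (default 10 to 50 by 10).
#' @param eye_id Identifier attached to all records.
#' @return A list with `records` (list of `aline_record`), `truth` (data
#'   frame of per-IOP ground-truth impedances and amplitudes), and
#'   `noise_sd` (the resolved value).
#' @export
simulate_experiment <- function(calib, tspec = transducer_spec(),
                                aspec = acquisition_spec(),
                                iops = seq(10, 50, by = 10),
                                eye_id = 1L) {
  stopifnot(length(iops) >= 1)
  if (any(iops < calib$cal$iop_low | iops > calib$cal$iop_high))
    stop("all iops must lie in the calibrated range", call. = FALSE)
  noise_sd <- aspec$noise_sd
  if (is.na(noise_sd)) {
    amps <- forward_amplitudes(calib$stack_at(calib$cal$iop_low))
    noise_sd <- 0.01 * amps[["A1"]]
  }
  aspec$noise_sd <- noise_sd
  set.seed(aspec$seed)
  records <- vector("list", length(iops) * aspec$n_repeats * aspec$n_alines)
  truth <- do.call(rbind, lapply(iops, function(p) {
    st <- calib$stack_at(p)
    a <- forward_amplitudes(st)
    data.frame(iop_mmHg = p, Z1_MRayl = st$Z1, Z2_MRayl = st$Z2,
               ant_amp = a[["A1"]], post_amp = a[["Ar"]],
               tof_diff_s = 2 * st$cornea_thickness / st$cornea_speed)
  }))
  k <- 0L
  for (p in iops) {
    st <- calib$stack_at(p)
    for (rep_i in seq_len(aspec$n_repeats)) {
      for (al in seq_len(aspec$n_alines)) {
        k <- k + 1L
        records[[k]] <- simulate_aline(st, tspec, aspec, iop = p,
                                       eye_id = eye_id, repeat_id = rep_i,
                                       aline_id = al)
      }
    }
  }
  list(records = records, truth = truth, noise_sd = noise_sd)
}

#' Simulate the quartz reference echo
#'
#' A single echo from a quartz flat of impedance
#' `Zq = density * speed`, with peak amplitude
#' `A0 * (Zq - Z0)/(Zq + Z0)`, used to calibrate the incident amplitude.
#' Noiseless by construction (the reference is averaged in practice).
#'
#' @param quartz_density Density in kg/m^3.
#' @param quartz_speed Longitudinal speed in m/s.
#' @param stack A [layer_stack()] supplying `Z0` and `A0`.
#' @param tspec A [transducer_spec()].
#' @param aspec An [acquisition_spec()].
#' @return An `aline_record` with `iop = NA`.
#' @export
simulate_reference_echo <- function(quartz_density = 2650,
                                    quartz_speed = 5750,
                                    stack, tspec = transducer_spec(),
                                    aspec = acquisition_spec()) {
  if (quartz_density <= 0 || quartz_speed <= 0)
    stop("density and speed must be positive", call. = FALSE)
  Zq <- quartz_density * quartz_speed / 1e6
  a <- stack$A0 * reflection_coefficient(stack$Z0, Zq)
  dt <- 1 / aspec$sampling_rate
  sigma_t <- pulse_sigma_t(tspec)
  t <- (seq_len(aspec$record_length) - 1L) * dt
  s <- pulse_at(t, aspec$anterior_arrival, a, tspec$center_frequency, sigma_t)
  structure(list(samples = s, dt = dt, iop = NA_real_,
                 eye_id = 0L, repeat_id = 0L, aline_id = 0L),
            class = "aline_record")
}

#' Write an A-line dataset to disk
#'
#' One tab-delimited file per record (columns `sample_index`, `amplitude`)
#' plus a JSON manifest holding `dt`, provenance ids, and an MD5 checksum
#' per file.
#'
#' @param dataset Result of [simulate_experiment()] or a list of
#'   `aline_record`s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_aline_dataset <- function(dataset, dir) {
  records <- if (!is.null(dataset$records)) dataset$records else dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    fn <- sprintf("aline_iop%03d_rep%02d_al%02d.tsv",
                  as.integer(round(r$iop)), r$repeat_id, r$aline_id)
    path <- file.path(dir, fn)
    utils::write.table(
      data.frame(sample_index = seq_along(r$samples) - 1L,
                 amplitude = formatC(r$samples, digits = 17, format = "g")),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
    entries[[i]] <- list(file = fn, dt = r$dt, iop = r$iop,
                         eye_id = r$eye_id, repeat_id = r$repeat_id,
                         aline_id = r$aline_id,
                         md5 = unname(tools::md5sum(path)))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read an A-line dataset written by [write_aline_dataset()]
#'
#' @param dir Directory containing `manifest.json` and the per-record
#'   files.
#' @param verify Check MD5 checksums against the manifest.
#' @return A list of `aline_record`s.
#' @export
read_aline_dataset <- function(dir, verify = TRUE) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest))
    stop("no manifest.json in ", dir, call. = FALSE)
  entries <- jsonlite::read_json(manifest)
  lapply(entries, function(e) {
    path <- file.path(dir, e$file)
    if (verify && !identical(unname(tools::md5sum(path)), e$md5))
      stop("checksum mismatch for ", e$file, call. = FALSE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    structure(list(samples = as.numeric(tab$amplitude), dt = e$dt,
                   iop = if (is.null(e$iop)) NA_real_ else e$iop,
                   eye_id = e$eye_id, repeat_id = e$repeat_id,
                   aline_id = e$aline_id),
              class = "aline_record")
  })
}
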