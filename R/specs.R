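#' Transducer specification
#'
#' Describes the single-element pulse-echo transducer by its center
#' frequency and fractional bandwidth (full spectral width at -6 dB divided
#' by center frequency). Defaults correspond to a 47-MHz transducer with
#' 62% bandwidth.
#'
#' @param center_frequency Center frequency in Hz. Must be positive.
#' @param fractional_bandwidth Dimensionless fractional bandwidth at -6 dB,
#'   in (0, 2).
#' @return An object of class `transducer_spec`.
#' @export
transducer_spec <- function(center_frequency = 4.7e7,
                            fractional_bandwidth = 0.62) {
  stopifnot(is.numeric(center_frequency), length(center_frequency) == 1L,
            is.numeric(fractional_bandwidth), length(fractional_bandwidth) == 1L)
  if (center_frequency <= 0)
    stop("center_frequency must be positive", call. = FALSE)
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional_bandwidth must lie in (0, 2)", call. = FALSE)
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth),
            class = "transducer_spec")
}

#' Acquisition specification
#'
#' Describes how A-lines are recorded: sampling rate, record length, the
#' number of A-lines per acquisition and repeats per eye, additive noise
#' level, the nominal arrival time of the anterior echo, and the RNG seed.
#'
#' @param sampling_rate Sampling rate in Hz (default 1 GHz).
#' @param record_length Number of samples per record.
#' @param n_alines A-lines per acquisition (default 10).
#' @param n_repeats Repeated acquisitions per eye (default 3).
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   the same arbitrary units as the recorded amplitude. `NA` means
#'   "resolve at simulation time to 1% of the anterior echo amplitude at
#'   the lowest pressure".
#' @param anterior_arrival Nominal arrival time of the anterior-surface
#'   echo in seconds (placement of the first echo inside the record).
#' @param seed Integer seed used by the simulator.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate = 1e9,
                             record_length = 2048L,
                             n_alines = 10L,
                             n_repeats = 3L,
                             noise_sd = NA_real_,
                             anterior_arrival = 0.5e-6,
                             seed = 1L) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (record_length < 2) stop("record_length must be at least 2", call. = FALSE)
  if (n_alines < 1) stop("n_alines must be >= 1", call. = FALSE)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (!is.na(noise_sd) && noise_sd < 0)
    stop("noise_sd must be nonnegative", call. = FALSE)
  if (anterior_arrival <= 0)
    stop("anterior_arrival must be positive", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 record_length = as.integer(record_length),
                 n_alines = as.integer(n_alines),
                 n_repeats = as.integer(n_repeats),
                 noise_sd = noise_sd,
                 anterior_arrival = anterior_arrival,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Layered acoustic model of the pulse path
#'
#' Impedances of the four media traversed by the pulse (coupling saline
#' `Z0`, anterior cornea `Z1`, posterior cornea `Z2`, aqueous humor `Z3`,
#' all in MRayl), the corneal thickness and longitudinal sound speed that
#' set the echo time separation, the incident amplitude `A0`, and a scalar
#' geometric gain applied to the posterior echo (curvature/defocus of the
#' non-planar posterior interface, lumped into one multiplicative factor).
#'
#' @param Z0,Z1,Z2,Z3 Acoustic impedances in MRayl; all positive.
#' @param cornea_thickness Corneal thickness in m.
#' @param cornea_speed Longitudinal sound speed in the cornea, m/s.
#' @param posterior_gain Dimensionless gain multiplying the posterior echo.
#' @param A0 Incident amplitude, arbitrary units.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(Z0, Z1, Z2, Z3 = Z0,
                        cornea_thickness = 0.8e-3,
                        cornea_speed = 1580,
                        posterior_gain = 1,
                        A0 = 1) {
  z <- c(Z0 = Z0, Z1 = Z1, Z2 = Z2, Z3 = Z3)
  if (any(!is.finite(z)) || any(z <= 0))
    stop("all impedances must be positive and finite", call. = FALSE)
  if (cornea_thickness <= 0) stop("cornea_thickness must be positive", call. = FALSE)
  if (cornea_speed <= 0) stop("cornea_speed must be positive", call. = FALSE)
  if (posterior_gain <= 0) stop("posterior_gain must be positive", call. = FALSE)
  if (A0 <= 0) stop("A0 must be positive", call. = FALSE)
  structure(list(Z0 = Z0, Z1 = Z1, Z2 = Z2, Z3 = Z3,
                 cornea_thickness = cornea_thickness,
                 cornea_speed = cornea_speed,
                 posterior_gain = posterior_gain,
                 A0 = A0),
            class = "layer_stack")
}

#' Linear IOP-to-impedance calibration
#'
#' The ground-truth anterior (`Z1`) and posterior (`Z2`) corneal impedances
#' are taken to vary linearly with intraocular pressure between two
#' endpoints. Defaults are the study endpoints over 10-50 mmHg: anterior
#' 1.5399 to 1.5519 MRayl, posterior 1.5393 to 1.5698 MRayl.
#'
#' @param iop_low,iop_high Pressure endpoints in mmHg, `iop_low < iop_high`.
#' @param Z1_low,Z1_high Anterior impedance at the two endpoints, MRayl.
#' @param Z2_low,Z2_high Posterior impedance at the two endpoints, MRayl.
#' @return An object of class `iop_calibration`.
#' @export
iop_calibration <- function(iop_low = 10, iop_high = 50,
                            Z1_low = 1.5399, Z1_high = 1.5519,
                            Z2_low = 1.5393, Z2_high = 1.5698) {
  if (!(iop_low < iop_high)) stop("iop_low must be < iop_high", call. = FALSE)
  z <- c(Z1_low, Z1_high, Z2_low, Z2_high)
  if (any(z <= 0)) stop("impedance endpoints must be positive", call. = FALSE)
  structure(list(iop_low = iop_low, iop_high = iop_high,
                 Z1_low = Z1_low, Z1_high = Z1_high,
                 Z2_low = Z2_low, Z2_high = Z2_high),
            class = "iop_calibration")
}

#' Map an IOP level to ground-truth corneal impedances
#'
#' Linear interpolation of the anterior and posterior impedance between the
#' calibration endpoints.
#'
#' @param iop Intraocular pressure in mmHg; must lie within the calibrated
#'   range.
#' @param cal An [iop_calibration()].
#' @return Named numeric vector `c(Z1 = ..., Z2 = ...)` in MRayl.
#' @export
iop_to_impedances <- function(iop, cal = iop_calibration()) {
  stopifnot(inherits(cal, "iop_calibration"))
  if (any(iop < cal$iop_low | iop > cal$iop_high))
    stop(sprintf("iop must lie within [%g, %g] mmHg", cal$iop_low, cal$iop_high),
         call. = FALSE)
  w <- (iop - cal$iop_low) / (cal$iop_high - cal$iop_low)
  c(Z1 = cal$Z1_low + w * (cal$Z1_high - cal$Z1_low),
    Z2 = cal$Z2_low + w * (cal$Z2_high - cal$Z2_low))
}
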