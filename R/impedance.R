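#' Normal-incidence pressure reflection coefficient
#'
#' Reflection coefficient for a wave travelling from a medium of impedance
#' `Z_a` into one of impedance `Z_b`: `(Z_b - Z_a) / (Z_b + Z_a)`. Signed;
#' antisymmetric in its arguments.
#'
#' @param Z_a,Z_b Acoustic impedances (any consistent unit), positive.
#' @return Dimensionless coefficient in (-1, 1).
#' @export
reflection_coefficient <- function(Z_a, Z_b) {
  if (any(Z_a <= 0) || any(Z_b <= 0))
    stop("impedances must be positive", call. = FALSE)
  (Z_b - Z_a) / (Z_b + Z_a)
}

#' Two-way transmission product across one interface
#'
#' Product of the forward and return pressure transmission coefficients
#' across the saline/anterior-cornea interface,
#' `T01 * T10 = 4 Z0 Z1 / (Z0 + Z1)^2`. Equals one minus the squared
#' reflection coefficient of the same interface.
#'
#' @param Z0,Z1 Acoustic impedances, positive.
#' @return Dimensionless product in (0, 1].
#' @export
transmission_product <- function(Z0, Z1) {
  if (any(Z0 <= 0) || any(Z1 <= 0))
    stop("impedances must be positive", call. = FALSE)
  4 * Z0 * Z1 / (Z0 + Z1)^2
}

#' Reflection setup for amplitude inversion
#'
#' Constants needed to turn measured echo amplitudes into impedances: the
#' coupling-medium impedance `Z0`, the aqueous-humor impedance `Z3`, the
#' incident amplitude `A0`, the posterior geometric gain, and the sign
#' convention for the posterior reflection.
#'
#' @param Z0,Z3 Impedances in MRayl, positive.
#' @param A0 Incident amplitude, arbitrary units, positive.
#' @param posterior_gain Scalar gain on the posterior echo, positive.
#' @param posterior_sign One of `"auto"` (assume the posterior cornea is
#'   denser than the aqueous humor, so the reflection coefficient is
#'   negative), `+1`, or `-1`.
#' @return An object of class `reflection_setup`.
#' @export
reflection_setup <- function(Z0, Z3 = Z0, A0, posterior_gain = 1,
                             posterior_sign = "auto") {
  if (Z0 <= 0 || Z3 <= 0) stop("impedances must be positive", call. = FALSE)
  if (A0 <= 0) stop("A0 must be positive", call. = FALSE)
  if (posterior_gain <= 0) stop("posterior_gain must be positive", call. = FALSE)
  if (!(identical(posterior_sign, "auto") || posterior_sign %in% c(-1, 1)))
    stop("posterior_sign must be 'auto', +1 or -1", call. = FALSE)
  structure(list(Z0 = Z0, Z3 = Z3, A0 = A0,
                 posterior_gain = posterior_gain,
                 posterior_sign = posterior_sign),
            class = "reflection_setup")
}

#' Incident amplitude from a quartz reference echo
#'
#' The incident amplitude `A0` is obtained from the echo of a quartz flat
#' of known density and longitudinal speed: its impedance is
#' `Zq = density * speed`, and the reference peak equals
#' `A0 * (Zq - Z0)/(Zq + Z0)`, so `A0 = reference_amp * (Zq + Z0)/(Zq - Z0)`.
#'
#' @param reference_amp Measured reference peak amplitude, arbitrary units.
#' @param quartz_density Density in kg/m^3.
#' @param quartz_speed Longitudinal sound speed in m/s.
#' @param Z0 Coupling-medium impedance in MRayl.
#' @return The incident amplitude `A0` in the same units as
#'   `reference_amp`.
#' @export
calibrate_A0 <- function(reference_amp, quartz_density, quartz_speed, Z0) {
  if (reference_amp <= 0 || quartz_density <= 0 || quartz_speed <= 0 || Z0 <= 0)
    stop("all inputs must be positive", call. = FALSE)
  Zq <- quartz_density * quartz_speed / 1e6   # Rayl -> MRayl
  if (abs(Zq - Z0) < .Machine$double.eps * max(Zq, Z0) * 4)
    stop("quartz impedance equals Z0: reference reflection vanishes",
         call. = FALSE)
  reference_amp * (Zq + Z0) / (Zq - Z0)
}

#' Anterior corneal impedance from the anterior echo amplitude
#'
#' Inverts the single-interface reflection relation
#' `A1/A0 = (Z1 - Z0)/(Z1 + Z0)` for `Z1`. `polarity = +1` selects the
#' branch `Z1 > Z0` (cornea denser than saline, the usual case);
#' `polarity = -1` the branch `Z1 < Z0`.
#'
#' @param A1 Anterior envelope-peak amplitude (nonnegative, less than `A0`).
#' @param setup A [reflection_setup()].
#' @param polarity `+1` or `-1`, sign of the anterior reflection.
#' @return `Z1` in MRayl.
#' @export
invert_anterior <- function(A1, setup, polarity = 1) {
  stopifnot(inherits(setup, "reflection_setup"))
  if (any(A1 < 0)) stop("A1 must be nonnegative", call. = FALSE)
  if (any(A1 >= setup$A0))
    stop("A1 >= A0: implied reflection coefficient >= 1", call. = FALSE)
  if (!all(polarity %in% c(-1, 1)))
    stop("polarity must be +1 or -1", call. = FALSE)
  r <- polarity * A1 / setup$A0
  setup$Z0 * (1 + r) / (1 - r)
}

#' Posterior corneal impedance from the posterior echo amplitude
#'
#' Inverts the three-layer relation
#' `Ar/A0 = T01 * R23 * T10 * g`, where `T01 T10` is the two-way
#' transmission through the anterior interface (a function of `Z0` and the
#' already-estimated `Z1`), `R23 = (Z3 - Z2)/(Z3 + Z2)` the reflection at
#' the posterior surface, and `g` the geometric gain. The measured `Ar` is
#' an envelope magnitude, so the sign of `R23` comes from the setup's sign
#' convention: `"auto"` assumes `Z2 > Z3` (negative `R23`).
#'
#' @param Ar Posterior envelope-peak amplitude, nonnegative.
#' @param Z1 Anterior impedance in MRayl (sets the transmission loss).
#' @param setup A [reflection_setup()].
#' @return `Z2` in MRayl.
#' @export
invert_posterior <- function(Ar, Z1, setup) {
  stopifnot(inherits(setup, "reflection_setup"))
  if (any(Ar < 0)) stop("Ar must be nonnegative", call. = FALSE)
  if (any(Z1 <= 0)) stop("Z1 must be positive", call. = FALSE)
  sgn <- if (identical(setup$posterior_sign, "auto")) -1 else setup$posterior_sign
  tt <- transmission_product(setup$Z0, Z1)
  R23 <- sgn * Ar / (setup$A0 * tt * setup$posterior_gain)
  if (any(abs(R23) >= 1))
    stop("implied |R23| >= 1: amplitude inconsistent with the model",
         call. = FALSE)
  setup$Z3 * (1 - R23) / (1 + R23)
}

#' Forward echo amplitudes from a layer stack
#'
#' The amplitudes the two-interface model predicts for a given stack:
#' anterior `A1 = A0 |R(Z0, Z1)|` and posterior
#' `Ar = A0 * T01 T10 * |R(Z3, Z2)| * posterior_gain`.
#'
#' @param stack A [layer_stack()].
#' @return Named numeric vector `c(A1 = ..., Ar = ...)`.
#' @export
forward_amplitudes <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  A1 <- stack$A0 * abs(reflection_coefficient(stack$Z0, stack$Z1))
  Ar <- stack$A0 * transmission_product(stack$Z0, stack$Z1) *
    abs(reflection_coefficient(stack$Z3, stack$Z2)) * stack$posterior_gain
  c(A1 = A1, Ar = Ar)
}

#' Invert a feature table to an impedance table
#'
#' Applies [invert_anterior()] then [invert_posterior()] row-wise to a
#' feature table produced by [extract_features()].
#'
#' @param features Data frame with columns `iop_mmHg`, `eye_id`,
#'   `repeat_id`, `aline_id`, `ant_amp`, `post_amp` (and optionally
#'   `polarity_post`).
#' @param setup A [reflection_setup()].
#' @return Data frame with columns `iop_mmHg`, `eye_id`, `repeat_id`,
#'   `aline_id`, `Z1_MRayl`, `Z2_MRayl`.
#' @export
invert_feature_table <- function(features, setup) {
  needed <- c("iop_mmHg", "eye_id", "repeat_id", "aline_id",
              "ant_amp", "post_amp")
  if (!all(needed %in% names(features)))
    stop("feature table is missing columns: ",
         paste(setdiff(needed, names(features)), collapse = ", "),
         call. = FALSE)
  Z1 <- invert_anterior(features$ant_amp, setup)
  Z2 <- invert_posterior(features$post_amp, Z1, setup)
  data.frame(iop_mmHg = features$iop_mmHg,
             eye_id = features$eye_id,
             repeat_id = features$repeat_id,
             aline_id = features$aline_id,
             Z1_MRayl = Z1, Z2_MRayl = Z2)
}
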