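#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the input checks the pipeline
#' relies on: equal lengths, at least 3 pairs, neither variable constant.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided significance of a Pearson correlation
#'
#' Exact small-sample test via the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom, two-sided. For `|r| = 1` the limit `p = 0`
#' is returned with attribute `degenerate = TRUE`.
#'
#' @param r Correlation coefficient, `|r| <= 1`.
#' @param n Number of pairs, `n >= 3`.
#' @return The two-sided p-value.
#' @export
pearson_p_two_sided <- function(r, n) {
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (abs(r) > 1) stop("|r| must not exceed 1", call. = FALSE)
  if (abs(r) == 1) return(structure(0, degenerate = TRUE))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Ordinary least-squares line through a pressure series
#'
#' @param iops Pressures in mmHg, not all equal, length >= 2.
#' @param values Response values, same length.
#' @return A list with `slope`, `intercept`, and `fitted` values.
#' @export
linear_fit <- function(iops, values) {
  if (length(iops) != length(values)) stop("length mismatch", call. = FALSE)
  if (length(iops) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(iops) == 0) stop("degenerate design: constant iops", call. = FALSE)
  fit <- stats::lm(values ~ iops)
  cf <- stats::coef(fit)
  list(slope = cf[[2]], intercept = cf[[1]],
       fitted = unname(stats::fitted(fit)))
}

#' Laplace-law hoop stress in a thin spherical shell
#'
#' `sigma = P * R / (2 t)` with the pressure converted from mmHg to Pa
#' (1 mmHg = 133.322 Pa). Used to relate intraocular pressure to the wall
#' stress that drives the corneal stiffening.
#'
#' @param P_mmHg Intraocular pressure in mmHg.
#' @param R_m Corneal radius of curvature in m.
#' @param t_m Corneal thickness in m.
#' @return Stress in Pa.
#' @export
laplace_stress <- function(P_mmHg, R_m, t_m) {
  if (any(P_mmHg < 0)) stop("pressure must be nonnegative", call. = FALSE)
  if (any(R_m <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(t_m <= 0)) stop("thickness must be positive", call. = FALSE)
  P_mmHg * 133.322 * R_m / (2 * t_m)
}

#' Correlate a per-pressure series with IOP
#'
#' Combines [pearson_r()], [pearson_p_two_sided()] and [linear_fit()] into
#' one result for a per-IOP series of means (impedance, amplitude, or
#' time-of-flight difference).
#'
#' @param iops Pressures in mmHg, strictly increasing, length >= 3.
#' @param values Per-pressure means, same length.
#' @param quantity Label carried into the result.
#' @return A list of class `correlation_result`: `quantity`, `r`, `n`,
#'   `t_stat`, `df`, `p_two_sided`, `slope`, `intercept`.
#' @export
correlate_with_iop <- function(iops, values, quantity = "value") {
  if (is.unsorted(iops, strictly = TRUE))
    stop("iops must be strictly increasing", call. = FALSE)
  r <- pearson_r(iops, values)
  n <- length(iops)
  p <- pearson_p_two_sided(r, n)
  t_stat <- if (abs(r) == 1) Inf else r * sqrt((n - 2) / (1 - r^2))
  fit <- linear_fit(iops, values)
  structure(list(quantity = quantity, r = r, n = n, t_stat = t_stat,
                 df = n - 2L, p_two_sided = as.numeric(p),
                 slope = fit$slope, intercept = fit$intercept),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s vs IOP: r = %.4f (n = %d, t = %.3f, df = %d, p = %.4g)\n",
              x$quantity, x$r, x$n, x$t_stat, x$df, x$p_two_sided))
  cat(sprintf("  linear fit: slope = %.6g per mmHg, intercept = %.6g\n",
              x$slope, x$intercept))
  invisible(x)
}
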