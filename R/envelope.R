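#' Analytic-signal envelope of a record
#'
#' Magnitude of the analytic signal, computed in the frequency domain:
#' negative frequencies are zeroed and positive ones doubled before the
#' inverse transform. Parameter-free, nonnegative, and invariant to a sign
#' flip of the input.
#'
#' @param x An `aline_record` or a numeric vector of samples.
#' @return Numeric vector of envelope samples, same length as the input.
#' @export
analytic_envelope <- function(x) {
  s <- if (inherits(x, "aline_record")) x$samples else as.numeric(x)
  n <- length(s)
  if (n == 0L) stop("empty record", call. = FALSE)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(s) * h, inverse = TRUE) / n)
}

#' Locate the anterior and posterior echo windows
#'
#' Finds the two largest, temporally separated envelope peaks and returns
#' disjoint analysis windows around them, earlier (anterior) first. The
#' second peak must be at least `min_separation` away from the first and
#' rise above `floor_frac` of the global envelope maximum; otherwise a
#' detection error reports how many echoes were found.
#'
#' @param envelope Numeric envelope samples.
#' @param dt Sampling interval in s.
#' @param min_separation Minimum echo separation in s (default 0.2 us).
#' @param floor_frac Minimum peak height as a fraction of the global
#'   maximum (default 0.05).
#' @return A list with integer index vectors `anterior` and `posterior`
#'   (each a window of half-width `min_separation / 2`).
#' @export
detect_echoes <- function(envelope, dt, min_separation = 0.2e-6,
                          floor_frac = 0.05) {
  n <- length(envelope)
  sep <- max(1L, as.integer(round(min_separation / dt)))
  half <- max(1L, sep %/% 2L)
  i1 <- which.max(envelope)
  masked <- envelope
  masked[max(1L, i1 - sep + 1L):min(n, i1 + sep - 1L)] <- -Inf
  i2 <- which.max(masked)
  if (!is.finite(masked[i2]) || envelope[i2] < floor_frac * envelope[i1])
    stop("echo detection failed: found 1 resolvable echo, need 2",
         call. = FALSE)
  idx <- sort(c(i1, i2))
  win <- function(i) max(1L, i - half):min(n, i + half)
  list(anterior = win(idx[1L]), posterior = win(idx[2L]))
}

#' Parabolic sub-sample peak fit on an envelope window
#'
#' Least-squares parabola through the envelope samples at and around the
#' window maximum (those at or above `window_frac` of it, contiguous with
#' it; at least 3 points). The vertex gives the echo amplitude and a
#' sub-sample time of flight.
#'
#' @param envelope Numeric envelope samples of the full record.
#' @param window Integer index vector (from [detect_echoes()]).
#' @param dt Sampling interval in s.
#' @param window_frac Inclusion threshold relative to the window maximum
#'   (default 0.7).
#' @param signal Optional raw samples; if given, the echo polarity is the
#'   sign of the raw signal at the sample nearest the vertex.
#' @return A list of class `echo_feature`: `amplitude`, `tof` (s),
#'   `polarity`, `fit_window` (indices used), `r2_of_fit`.
#' @export
parabolic_peak_fit <- function(envelope, window, dt, window_frac = 0.7,
                               signal = NULL) {
  w <- envelope[window]
  imax <- which.max(w)
  if (imax == 1L || imax == length(w))
    stop("window maximum lies on the window edge", call. = FALSE)
  thr <- window_frac * w[imax]
  keep <- w >= thr
  # contiguous run containing the maximum
  lo <- imax; while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < length(w) && keep[hi + 1L]) hi <- hi + 1L
  if (hi - lo + 1L < 3L)
    stop("fewer than 3 samples above the fit threshold", call. = FALSE)
  idx <- window[lo:hi]                   # absolute sample indices (1-based)
  x <- idx - 1                           # time in samples from record start
  y <- envelope[idx]
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  a <- cf[[3]]; b <- cf[[2]]; c0 <- cf[[1]]
  if (!is.finite(a) || a >= 0)
    stop("degenerate parabola (non-concave fit)", call. = FALSE)
  xv <- -b / (2 * a)
  amp <- c0 - b^2 / (4 * a)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  pol <- 1
  if (!is.null(signal)) {
    i0 <- min(max(1L, as.integer(round(xv)) + 1L), length(signal))
    pol <- if (signal[i0] < 0) -1 else 1
  }
  structure(list(amplitude = amp, tof = xv * dt, polarity = pol,
                 fit_window = idx, r2_of_fit = r2),
            class = "echo_feature")
}

#' Extract anterior/posterior echo features from records
#'
#' For each A-line: envelope, echo detection, and parabolic peak fits for
#' both echoes. Returns the per-A-line feature table.
#'
#' @param records A list of `aline_record`s (or a [simulate_experiment()]
#'   result).
#' @param min_separation Minimum echo separation in s.
#' @param window_frac Parabolic-fit inclusion threshold.
#' @return Data frame with columns `iop_mmHg`, `eye_id`, `repeat_id`,
#'   `aline_id`, `ant_amp`, `ant_tof_s`, `post_amp`, `post_tof_s`,
#'   `tof_diff_s`, `polarity_post`.
#' @export
extract_features <- function(records, min_separation = 0.2e-6,
                             window_frac = 0.7) {
  if (!is.null(records$records)) records <- records$records
  rows <- lapply(records, function(r) {
    env <- analytic_envelope(r)
    wins <- detect_echoes(env, r$dt, min_separation)
    ant <- parabolic_peak_fit(env, wins$anterior, r$dt, window_frac,
                              signal = r$samples)
    post <- parabolic_peak_fit(env, wins$posterior, r$dt, window_frac,
                               signal = r$samples)
    data.frame(iop_mmHg = r$iop, eye_id = r$eye_id, repeat_id = r$repeat_id,
               aline_id = r$aline_id,
               ant_amp = ant$amplitude, ant_tof_s = ant$tof,
               post_amp = post$amplitude, post_tof_s = post$tof,
               tof_diff_s = post$tof - ant$tof,
               polarity_post = post$polarity)
  })
  do.call(rbind, rows)
}

#' Aggregate features per pressure level
#'
#' Pools the A-lines within each repeat, averages the repeat means with
#' equal weight (the design is balanced, so this coincides with the grand
#' mean), and reports per-IOP means and standard deviations of the
#' anterior and posterior amplitudes and of the time-of-flight difference.
#' The standard deviation is taken over all A-lines at the level.
#'
#' @param features Feature table from [extract_features()].
#' @return Data frame with one row per IOP level: means and sds of
#'   `ant_amp`, `post_amp`, `tof_diff_s`, plus `n` (A-lines pooled).
#' @export
aggregate_features <- function(features) {
  if (nrow(features) == 0L) stop("empty feature table", call. = FALSE)
  split_iop <- split(features, features$iop_mmHg)
  out <- lapply(split_iop, function(g) {
    rep_mean <- function(col)
      mean(tapply(g[[col]], g$repeat_id, mean))
    data.frame(iop_mmHg = g$iop_mmHg[1L],
               ant_amp_mean = rep_mean("ant_amp"),
               ant_amp_sd = stats::sd(g$ant_amp),
               post_amp_mean = rep_mean("post_amp"),
               post_amp_sd = stats::sd(g$post_amp),
               tof_diff_mean_s = rep_mean("tof_diff_s"),
               tof_diff_sd_s = stats::sd(g$tof_diff_s),
               n = nrow(g))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$iop_mmHg), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aggregate an impedance table per pressure level
#'
#' Same pooling scheme as [aggregate_features()], applied to the
#' `Z1_MRayl` / `Z2_MRayl` columns of [invert_feature_table()] output.
#'
#' @param impedances Impedance table.
#' @return Data frame with per-IOP means and sds of both impedances.
#' @export
aggregate_impedances <- function(impedances) {
  if (nrow(impedances) == 0L) stop("empty impedance table", call. = FALSE)
  split_iop <- split(impedances, impedances$iop_mmHg)
  out <- lapply(split_iop, function(g) {
    rep_mean <- function(col) mean(tapply(g[[col]], g$repeat_id, mean))
    data.frame(iop_mmHg = g$iop_mmHg[1L],
               Z1_mean_MRayl = rep_mean("Z1_MRayl"),
               Z1_sd_MRayl = stats::sd(g$Z1_MRayl),
               Z2_mean_MRayl = rep_mean("Z2_MRayl"),
               Z2_sd_MRayl = stats::sd(g$Z2_MRayl),
               n = nrow(g))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$iop_mmHg), , drop = FALSE]
  rownames(res) <- NULL
  res
}
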