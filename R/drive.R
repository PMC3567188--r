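#' Oscillatory drive specification
#'
#' Describes the shared sinusoidal intensity of a population of input spike
#' trains, \eqn{r(t) = r_0 + r_1\cos(2\pi f_{mod}(t - t_0))}: every input is
#' an independent realisation of the same inhomogeneous Poisson process, so
#' inputs are correlated only through this common rate modulation (no
#' higher-order spike-timing correlations). Non-negativity of the intensity
#' requires \eqn{0 \le r_1 \le r_0}.
#'
#' @param r0 mean rate in spikes/s.
#' @param r1 modulation amplitude in spikes/s (default 5, the modulation
#'   depth used throughout the training protocols).
#' @param f_mod modulation frequency in Hz.
#' @param t0 phase delay of the modulation in seconds (default 0).
#' @return an object of class `drive_spec`.
#' @export
drive_spec <- function(r0 = 20, r1 = 5, f_mod = 120, t0 = 0) {
  if (r1 < 0 || r1 > r0) stop("need 0 <= r1 <= r0 (non-negative intensity)")
  if (f_mod < 0) stop("f_mod must be non-negative")
  structure(list(r0 = r0, r1 = r1, f_mod = f_mod, t0 = t0),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  cat(sprintf("oscillatory drive: %g + %g cos(2pi %g (t - %g)) spikes/s\n",
              x$r0, x$r1, x$f_mod, x$t0))
  invisible(x)
}

#' Two-group oscillatory drive
#'
#' Same-frequency sinusoidal drive for two input groups, with the second
#' group's oscillation lagging the first by `t_lag` seconds:
#' group 1 has phase delay `t0`, group 2 has `t0 + t_lag`.
#'
#' @param base a [drive_spec] shared by both groups.
#' @param t_lag time lag of group 2 behind group 1, in seconds
#'   (e.g. `6.5e-3` for the 6.5 ms lag of the two-group training protocol).
#' @return an object of class `two_group_drive_spec`.
#' @export
two_group_drive_spec <- function(base = drive_spec(f_mod = 60), t_lag = 6.5e-3) {
  stopifnot(inherits(base, "drive_spec"))
  structure(list(base = base, t_lag = t_lag), class = "two_group_drive_spec")
}

#' Feed-forward connection specification (analytic model)
#'
#' In the rate-ensemble model the feed-forward pathway is summarised by its
#' total gain `j_ff` (the integral of the feed-forward delay profile; with
#' `j_ff = 1` the output rate of an isolated neuron equals the input rate,
#' because the EPSP kernel has unit area) and a common axonal delay `d_in`.
#'
#' @param j_ff total feed-forward weight (dimensionless gain, >= 0).
#' @param d_in input axonal delay in ms (default 1).
#' @return an object of class `feedforward_spec`.
#' @export
feedforward_spec <- function(j_ff = 1, d_in = 1) {
  if (j_ff < 0 || d_in < 0) stop("j_ff and d_in must be non-negative")
  structure(list(j_ff = j_ff, d_in = d_in), class = "feedforward_spec")
}

#' Line spectrum of the input pair-correlation function
#'
#' For any pair of distinct oscillatory inputs the correlation function is
#' \eqn{C(u) = r_0^2 + (r_1^2/2)\cos(2\pi f_{mod} u)}, whose Fourier
#' transform is a line spectrum: a DC mass \eqn{r_0^2} at 0 and symmetric
#' masses \eqn{r_1^2/4} at \eqn{\pm f_{mod}}.
#'
#' @param drive a [drive_spec].
#' @return an object of class `line_spectrum`: a data frame with columns
#'   `frequency` (Hz) and `mass` (spikes^2/s^2).
#' @export
input_correlation_lines <- function(drive) {
  stopifnot(inherits(drive, "drive_spec"))
  df <- data.frame(frequency = 0, mass = drive$r0^2)
  if (drive$r1 > 0 && drive$f_mod > 0) {
    df <- rbind(df,
                data.frame(frequency = c(-drive$f_mod, drive$f_mod),
                           mass = drive$r1^2 / 4))
  }
  df <- df[order(df$frequency), ]
  rownames(df) <- NULL
  class(df) <- c("line_spectrum", "data.frame")
  df
}

#' Input correlation transform evaluated at a frequency
#'
#' Returns the line mass of the input pair-correlation spectrum at `f`
#' (0 unless `f` coincides with a spectral line; the spectrum is symmetric
#' under `f -> -f` because the correlation function is even).
#'
#' @param drive a [drive_spec].
#' @param f frequency in Hz (vectorised).
#' @param tol matching tolerance in Hz.
#' @return numeric vector of line masses (spikes^2/s^2).
#' @export
input_correlation_ft <- function(drive, f, tol = 1e-9) {
  lines <- input_correlation_lines(drive)
  vapply(f, function(fi) {
    hit <- abs(lines$frequency - fi) < tol
    if (any(hit)) sum(lines$mass[hit]) else 0
  }, numeric(1))
}

#' Input correlation function in the time domain
#'
#' @param drive a [drive_spec].
#' @param u lag in seconds (vectorised).
#' @return \eqn{C(u)} in spikes^2/s^2.
#' @export
input_correlation_fun <- function(drive, u) {
  drive$r0^2 + drive$r1^2 / 2 * cos(2 * pi * drive$f_mod * u)
}
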