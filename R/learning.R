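#' Correlation-driven learning term over axonal delay
#'
#' The Fourier-domain prediction of how additive STDP changes the mean
#' weight of recurrent connections with axonal delay \eqn{d} (deviation
#' about the homeostatic mean), for a network driven by inputs whose rate
#' is modulated at \eqn{f_{mod}}. Because all network neurons share the
#' same rate modulation, the oscillatory component of the pair correlation
#' between any pre/post pair is
#' \eqn{(r_1^2/2)\,J_{ff}^2\,|\tilde\varepsilon(f)|^2 \cos(2\pi f u)}
#' (the EPSP phases of pre and post cancel), and convolving it with the
#' learning window shifted by the axonal delay gives
#' \deqn{\dot J_{dev}(d) \propto \tfrac{r_1^2}{2} J_{ff}^2\,
#'   |\tilde\varepsilon(f)|^2\, |\tilde W(f)| \cos(2\pi f d - \phi_W(f)),}
#' an \eqn{f_{mod}}-periodic function of \eqn{d} whose phase is set by the
#' window transform alone. The EPSP rise/decay times only scale the learning
#' rate, never which delays are selected. The result includes the window's
#' learning rate `eta` and is in weight per second of drive exposure.
#'
#' @param d axonal delay in ms (vectorised).
#' @param drive a [drive_spec].
#' @param ff a [feedforward_spec].
#' @param epsp an [epsp_params].
#' @param window an [stdp_window].
#' @return deviation growth rate (weight/s) at each delay.
#' @export
learning_term_axonal <- function(d, drive, ff = feedforward_spec(),
                                 epsp = epsp_params("medium"),
                                 window = stdp_window()) {
  stopifnot(inherits(drive, "drive_spec"), inherits(ff, "feedforward_spec"))
  f <- drive$f_mod
  if (drive$r1 == 0 || f == 0) return(rep(0, length(d)))
  wft <- window_ft(window, f)
  eft <- epsp_ft(epsp, f)
  amp <- drive$r1^2 / 2 * ff$j_ff^2 * eft$amplitude^2 * wft$amplitude
  amp * cos(2 * pi * f * d / 1000 - wft$phase)
}

#' Shortest resonant delay selected by STDP at a modulation frequency
#'
#' Closed form for the shortest positive maximiser of
#' [learning_term_axonal]: the cosine peaks where
#' \eqn{2\pi f d = \phi_W(f) \ (\mathrm{mod}\ 2\pi)}, so
#' \deqn{d^*(f) = \frac{\phi_W(f) \bmod 2\pi}{2\pi f},}
#' independent of the EPSP kernel and strictly decreasing in \eqn{f}.
#' Longer resonant delays sit at \eqn{d^* + k/f}.
#'
#' @param f_mod modulation frequency in Hz (> 0, vectorised).
#' @param window an [stdp_window].
#' @return shortest resonant delay in ms.
#' @seealso [resonant_delays], [learnable_frequency_bounds]
#' @export
selected_delay <- function(f_mod, window = stdp_window()) {
  if (any(f_mod <= 0)) stop("f_mod must be positive")
  ph <- window_ft(window, f_mod)$phase %% (2 * pi)
  1000 * ph / (2 * pi * f_mod)
}

#' All resonant delays within a delay range
#'
#' Enumerates \eqn{d^*(f) + k/f} for integer \eqn{k \ge 0} inside
#' `delay_range`. The analytic deviation dynamics potentiate all of them
#' equally; in spiking simulations the shortest eventually wins.
#'
#' @param f_mod modulation frequency in Hz.
#' @param window an [stdp_window].
#' @param delay_range `[d_min, d_max]` in ms.
#' @return numeric vector of resonant delays (ms), possibly empty.
#' @export
resonant_delays <- function(f_mod, window = stdp_window(),
                            delay_range = c(1, 10)) {
  d0 <- selected_delay(f_mod, window)
  period <- 1000 / f_mod
  k <- seq(0, ceiling((delay_range[2] - d0) / period))
  dd <- d0 + k * period
  dd[dd >= delay_range[1] & dd <= delay_range[2]]
}

#' Learnable frequency band of a delay range
#'
#' Inverts [selected_delay] by root bracketing: the maximum recurrent delay
#' sets the minimum learnable modulation frequency (`f_min` solves
#' `selected_delay(f) = d_max`) and the minimum delay sets the maximum
#' (`f_max` solves `selected_delay(f) = d_min`). With the standard window
#' and the 1-10 ms delay range this gives approximately 76-750 Hz.
#'
#' @param d_min,d_max delay range bounds in ms, `0 < d_min < d_max`.
#' @param window an [stdp_window].
#' @param f_search frequency interval searched, in Hz.
#' @return named numeric vector `c(f_min, f_max)` in Hz.
#' @export
learnable_frequency_bounds <- function(d_min, d_max, window = stdp_window(),
                                       f_search = c(5, 5000)) {
  if (!(0 < d_min && d_min < d_max)) stop("need 0 < d_min < d_max")
  invert <- function(target) {
    g <- function(f) selected_delay(f, window) - target
    if (g(f_search[1]) * g(f_search[2]) > 0)
      stop("selected delay does not bracket ", target,
           " ms on the searched frequency interval")
    stats::uniroot(g, f_search, tol = 1e-10)$root
  }
  c(f_min = invert(d_max), f_max = invert(d_min))
}

#' Two-dimensional learning term over axonal and dendritic delay
#'
#' With both delay kinds, a somatic pre/post pair with time difference
#' \eqn{u} meets the synapse at the shifted argument
#' \eqn{u + d_d - d_a}: increasing the dendritic delay shifts pairings
#' toward potentiation, increasing the axonal delay toward depression. The
#' correlation learning term therefore depends on the delays only through
#' their difference,
#' \eqn{LT_2(d_a, d_d) = LT_1(d_a - d_d)}, so its potentiation ridges are
#' lines of slope 1.0 in the (dendritic, axonal) plane and the term is
#' invariant under \eqn{(d_a, d_d) \to (d_a+\delta, d_d+\delta)}.
#'
#' @param d_a axonal delay in ms (vectorised).
#' @param d_d dendritic delay in ms (vectorised, recycled against `d_a`).
#' @inheritParams learning_term_axonal
#' @return deviation growth rate (weight/s).
#' @export
learning_term_2d <- function(d_a, d_d, drive, ff = feedforward_spec(),
                             epsp = epsp_params("medium"),
                             window = stdp_window()) {
  learning_term_axonal(d_a - d_d, drive, ff, epsp, window)
}

#' Learning term for the four connection classes of a two-group network
#'
#' With group 2's input oscillation lagging group 1's by `t_lag`, the
#' oscillatory pair correlation between groups is shifted by the lag, so the
#' between-group learning terms are the single-group term evaluated at a
#' shifted delay: connections from group 2 into group 1 follow
#' \eqn{LT_1(d + T_{lag})}, from group 1 into group 2 \eqn{LT_1(d - T_{lag})},
#' and within-group connections follow \eqn{LT_1(d)} unchanged. At
#' `t_lag = 0` all four classes coincide with the single-group term.
#'
#' @param target_group,source_group group indices in `{1, 2}` (connection
#'   runs from `source_group` into `target_group`).
#' @param d axonal delay in ms (vectorised).
#' @param drive2 a [two_group_drive_spec].
#' @inheritParams learning_term_axonal
#' @return deviation growth rate (weight/s).
#' @export
two_group_learning_term <- function(target_group, source_group, d, drive2,
                                    ff = feedforward_spec(),
                                    epsp = epsp_params("slow"),
                                    window = stdp_window()) {
  stopifnot(inherits(drive2, "two_group_drive_spec"),
            target_group %in% 1:2, source_group %in% 1:2)
  lag_ms <- drive2$t_lag * 1000
  shift <- if (target_group == source_group) 0
           else if (target_group == 1) lag_ms else -lag_ms
  learning_term_axonal(d + shift, drive2$base, ff, epsp, window)
}

# stationary network rate of the linear Poisson model at mean recurrent
# weight J (per-connection), fan-in k: nu = j_ff r0 / (1 - k J)
linear_network_rate <- function(j_av, drive, ff, n_connections) {
  g <- n_connections * j_av
  if (any(g >= 1)) stop("recurrent gain >= 1: no stationary rate")
  ff$j_ff * drive$r0 / (1 - g)
}

#' Homeostatic equilibrium of the mean recurrent weight
#'
#' The rate-based part of the STDP rule (per-spike increments `w_in`,
#' `w_out` plus the net window bias \eqn{\tilde W(0) = \int W < 0}) drives
#' the mean recurrent weight toward a fixed point \eqn{J^*} of
#' \deqn{\dot J_{av} \propto \eta\,(w_{in} + w_{out})\,\nu(J_{av})
#'   + \nu(J_{av})^2 \int W,}
#' where \eqn{\nu(J_{av}) = J_{ff} r_0 / (1 - k\,J_{av})} is the stationary
#' network rate under recurrent gain \eqn{k\,J_{av}}. With the default
#' `w_in > 0`, `w_out < 0`, `w_in + w_out > 0` and the net-depressing
#' standard window, the drift is positive at low weight and negative at
#' high weight, giving a stable interior equilibrium. The deviation
#' dynamics of [evolve_profile] are integrated about this mean.
#'
#' @param drive a [drive_spec].
#' @param ff a [feedforward_spec].
#' @param window an [stdp_window].
#' @param n_connections recurrent fan-in per neuron.
#' @param j_max upper weight bound (per connection).
#' @param rate_fn optional function `J -> rate` overriding the linear
#'   Poisson network rate.
#' @return the equilibrium mean weight `J*` (per connection), strictly
#'   inside `(0, j_max)` for the default configuration.
#' @export
homeostatic_equilibrium <- function(drive, ff = feedforward_spec(),
                                    window = stdp_window(),
                                    n_connections = 100, j_max = 0.015,
                                    rate_fn = NULL) {
  if (is.null(rate_fn))
    rate_fn <- function(j) linear_network_rate(j, drive, ff, n_connections)
  drift <- function(j) {
    nu <- rate_fn(j)
    window$eta * (window$w_in + window$w_out) * nu +
      nu^2 * window_integral(window)
  }
  hi <- min(j_max, 0.999999 / n_connections)
  lo <- 1e-12
  if (drift(lo) * drift(hi) > 0) {
    if (drift(lo) < 0) return(0)        # monotone depression: lower bound
    stop("no equilibrium: rate-based drift never changes sign on [0, j_max]")
  }
  stats::uniroot(drift, c(lo, hi), tol = 1e-14)$root
}

#' Mean-weight drift of the rate-based learning terms
#'
#' The drift evaluated by [homeostatic_equilibrium]; exposed for stability
#' checks (negative above the equilibrium, positive below it).
#'
#' @inheritParams homeostatic_equilibrium
#' @param j_av mean recurrent weight (vectorised).
#' @return drift in weight/s.
#' @export
homeostatic_drift <- function(j_av, drive, ff = feedforward_spec(),
                              window = stdp_window(), n_connections = 100,
                              rate_fn = NULL) {
  if (is.null(rate_fn))
    rate_fn <- function(j) linear_network_rate(j, drive, ff, n_connections)
  nu <- rate_fn(j_av)
  window$eta * (window$w_in + window$w_out) * nu +
    nu^2 * window_integral(window)
}

#' Pair-correlation line spectrum of recurrent network neurons
#'
#' Weak-coupling (first order in the recurrent gain) approximation of the
#' average pair-correlation transform for two distinct network neurons.
#' Both neurons inherit the input oscillation through the common transfer
#' \eqn{H(f) = J_{ff}\tilde\varepsilon(f)e^{-2\pi i f d_{in}}
#' (1 + \tilde J(f)\tilde\varepsilon(f))}, where \eqn{\tilde J} is the
#' recurrent gain transform of the delay profile, so the correlation
#' spectrum is the input line spectrum filtered by \eqn{|H(f)|^2}, plus the
#' DC mass \eqn{\bar\nu^2}. Signals an error outside the weak-coupling
#' regime (DC recurrent gain >= 1).
#'
#' @param drive a [drive_spec].
#' @param ff a [feedforward_spec].
#' @param profile a [delay_profile] of the recurrent connections.
#' @param epsp an [epsp_params].
#' @return a `line_spectrum` data frame (columns `frequency`, `mass`).
#' @export
recurrent_correlation_lines <- function(drive, ff, profile,
                                        epsp = epsp_params("medium")) {
  g0 <- profile$n_connections * profile_mean_weight(profile)
  if (g0 >= 1) stop("mean recurrent gain >= 1: outside weak-coupling regime")
  nu <- ff$j_ff * drive$r0 / (1 - g0)
  df <- data.frame(frequency = 0, mass = nu^2)
  if (drive$r1 > 0 && drive$f_mod > 0) {
    f <- drive$f_mod
    h <- ff$j_ff * epsp_ft(epsp, f)$z * exp(-2i * pi * f * ff$d_in / 1000) *
      (1 + profile_gain_ft(profile, f)$z * epsp_ft(epsp, f)$z)
    df <- rbind(df, data.frame(frequency = c(-f, f),
                               mass = drive$r1^2 / 4 * Mod(h)^2))
  }
  df <- df[order(df$frequency), ]
  rownames(df) <- NULL
  class(df) <- c("line_spectrum", "data.frame")
  df
}

#' @rdname recurrent_correlation_lines
#' @param f frequency in Hz (vectorised); returns the line mass at `f`.
#' @param tol line-matching tolerance in Hz.
#' @export
recurrent_correlation_ft <- function(drive, ff, profile,
                                     epsp = epsp_params("medium"),
                                     f = drive$f_mod, tol = 1e-9) {
  lines <- recurrent_correlation_lines(drive, ff, profile, epsp)
  vapply(f, function(fi) {
    hit <- abs(lines$frequency - fi) < tol
    if (any(hit)) sum(lines$mass[hit]) else 0
  }, numeric(1))
}

#' Recurrent pair-correlation function in the time domain
#'
#' Inverse transform of [recurrent_correlation_lines]:
#' \eqn{C(u) = \bar\nu^2 + 2 m \cos(2\pi f_{mod} u)} with line mass `m`.
#' Used to cross-check empirical correlograms from Poisson-network
#' simulations.
#'
#' @inheritParams recurrent_correlation_lines
#' @param u lag in seconds (vectorised).
#' @return correlation values in spikes^2/s^2.
#' @export
recurrent_correlation_fun <- function(drive, ff, profile,
                                      epsp = epsp_params("medium"), u) {
  lines <- recurrent_correlation_lines(drive, ff, profile, epsp)
  dc <- lines$mass[lines$frequency == 0]
  osc <- lines$mass[lines$frequency > 0]
  out <- rep(dc, length(u))
  if (length(osc) == 1)
    out <- out + 2 * osc * cos(2 * pi * drive$f_mod * u)
  out
}

#' Evolve a delay profile under the correlation learning term
#'
#' Forward-Euler integration of the deviation dynamics about the
#' homeostatic mean: each step adds
#' `dt * (LT(d) - mean(LT))` (a zero-mean deviation increment, so the mean
#' weight is conserved exactly while the bounds are inactive) and then
#' clips to `[0, j_max]`. With sufficient duration the weight mass
#' concentrates on a narrow band around [selected_delay] and its
#' `+k/f_mod` images inside the delay range; the analytic model potentiates
#' all images equally.
#'
#' @param initial a [delay_profile] (typically flat at the homeostatic
#'   equilibrium).
#' @param drive a [drive_spec].
#' @param ff a [feedforward_spec].
#' @param epsp an [epsp_params].
#' @param window an [stdp_window].
#' @param duration modeled learning time in seconds.
#' @param dt_learn integration step in seconds (> 0).
#' @param snapshot_every snapshot interval in seconds (default: 5 snapshots).
#' @return an object of class `profile_evolution`: list with `times` (s) and
#'   `snapshots` (list of [delay_profile]), the last entry being the final
#'   profile.
#' @export
evolve_profile <- function(initial, drive, ff = feedforward_spec(),
                           epsp = epsp_params("medium"),
                           window = stdp_window(),
                           duration, dt_learn = 1,
                           snapshot_every = NULL) {
  stopifnot(inherits(initial, "delay_profile"))
  if (duration < 0) stop("duration must be non-negative")
  if (dt_learn <= 0) stop("dt_learn must be positive")
  if (is.null(snapshot_every)) snapshot_every <- max(duration / 5, dt_learn)
  lt <- learning_term_axonal(initial$delay_grid, drive, ff, epsp, window)
  lt_dev <- lt - mean(lt)
  w <- initial$weights
  times <- 0
  snaps <- list(initial)
  n_steps <- if (duration == 0) 0 else ceiling(duration / dt_learn)
  next_snap <- snapshot_every
  t <- 0
  for (s in seq_len(n_steps)) {
    dt <- min(dt_learn, duration - t)
    w <- pmin(pmax(w + dt * lt_dev, 0), initial$j_max)
    t <- t + dt
    if (t >= next_snap - 1e-9 || s == n_steps) {
      times <- c(times, t)
      snaps[[length(snaps) + 1]] <-
        delay_profile(initial$delay_grid, w, initial$j_max,
                      initial$delay_range, initial$n_connections)
      next_snap <- next_snap + snapshot_every
    }
  }
  structure(list(times = times, snapshots = snaps),
            class = "profile_evolution")
}

#' @export
print.profile_evolution <- function(x, ...) {
  cat(sprintf("profile evolution: %d snapshots over %g s\n",
              length(x$snapshots), max(x$times)))
  invisible(x)
}
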