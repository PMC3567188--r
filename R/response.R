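#' Amplitude of a sum of cosines
#'
#' The amplitude of \eqn{\sum_i a_i\cos(\theta + \phi_i)} over \eqn{\theta}
#' is the modulus of the phasor sum, \eqn{|\sum_i a_i e^{i\phi_i}|}.
#'
#' @param components a two-column matrix or data frame (amplitude, phase in
#'   radians), or a list of length-2 vectors. Amplitudes must be >= 0.
#' @return the summed amplitude; 0 for an empty list.
#' @examples
#' cosine_sum_amplitude(rbind(c(1, 0), c(1, pi)))  # cancellation -> 0
#' @export
cosine_sum_amplitude <- function(components) {
  if (is.list(components) && !is.data.frame(components))
    components <- do.call(rbind, components)
  if (is.null(components) || NROW(components) == 0) return(0)
  components <- as.matrix(components)
  a <- components[, 1]; ph <- components[, 2]
  if (any(a < 0)) stop("component amplitudes must be non-negative")
  Mod(sum(a * exp(1i * ph)))
}

#' Gaussian delay-profile summary
#'
#' Post-learning recurrent connectivity summarised as a Gaussian profile
#' over total conduction delay: mean `mu` (ms), width `sigma` (ms) and
#' total recurrent gain `j_rec` (the fan-in-weighted mean recurrent weight;
#' the network is sub-critical while `j_rec < 1`). The profile's gain
#' transform has the closed form
#' \eqn{\tilde J(f) = J_{rec}\,e^{-2\pi^2\sigma^2 f^2}\,e^{-2\pi i f\mu}}.
#'
#' @param mu mean total delay in ms.
#' @param sigma profile width in ms (>= 0).
#' @param j_rec total recurrent gain (>= 0).
#' @return an object of class `gaussian_profile_spec`.
#' @export
gaussian_profile_spec <- function(mu, sigma = 0.5, j_rec = 0.5) {
  if (sigma < 0 || j_rec < 0) stop("sigma and j_rec must be non-negative")
  structure(list(mu = mu, sigma = sigma, j_rec = j_rec),
            class = "gaussian_profile_spec")
}

#' @export
print.gaussian_profile_spec <- function(x, ...) {
  cat(sprintf("Gaussian delay profile: mu %g ms, sigma %g ms, gain %g\n",
              x$mu, x$sigma, x$j_rec))
  invisible(x)
}

# complex recurrent loop gain of a Gaussian profile at frequency f (Hz)
gaussian_gain <- function(profile, epsp, f) {
  mu <- profile$mu / 1000; sig <- profile$sigma / 1000
  profile$j_rec * epsp_ft(epsp, f)$z *
    exp(-2 * pi^2 * sig^2 * f^2) * exp(-2i * pi * f * mu)
}

#' Oscillatory response amplitude of a trained network
#'
#' Amplitude of the network's population-rate oscillation when driven at
#' frequency `f` after learning, for a Gaussian recurrent delay profile.
#' The oscillatory component of the rate obeys
#' \eqn{\hat\nu = F(f) + G(f)\hat\nu} with feed-forward phasor
#' \eqn{F = r_1 J_{ff}\tilde\varepsilon(f)e^{-2\pi i f d_{in}}} and loop
#' gain \eqn{G = J_{rec}\tilde\varepsilon(f) e^{-2\pi^2\sigma^2f^2}
#' e^{-2\pi i f \mu}}. The default second-order expansion gives
#' \eqn{\hat A(f) = |F|\,|1 + G + G^2|}; `order = Inf` resums the full
#' geometric series \eqn{|F|/|1-G|} (used internally as an oracle and to
#' illustrate the divergence at criticality). The truncation error of the
#' second order is bounded by \eqn{|G|^3/(1-|G|)} relative.
#'
#' @param f test frequency in Hz (vectorised).
#' @param profile a [gaussian_profile_spec].
#' @param ff a [feedforward_spec].
#' @param epsp an [epsp_params].
#' @param r1 input modulation amplitude in spikes/s.
#' @param order `1`, `2` (default) or `Inf` (full resummation).
#' @return response amplitude in spikes/s.
#' @export
response_amplitude <- function(f, profile, ff = feedforward_spec(),
                               epsp = epsp_params("medium"), r1 = 5,
                               order = 2) {
  stopifnot(inherits(profile, "gaussian_profile_spec"))
  g <- gaussian_gain(profile, epsp, f)
  if (any(Mod(g) >= 1))
    stop("super-critical configuration: recurrent loop gain >= 1")
  ffph <- r1 * ff$j_ff * epsp_ft(epsp, f)$z *
    exp(-2i * pi * f * ff$d_in / 1000)
  series <- if (is.infinite(order)) 1 / (1 - g)
            else Reduce(`+`, lapply(0:order, function(n) g^n))
  Mod(ffph * series)
}

#' Response curve over a frequency grid
#'
#' @param f_grid test frequencies in Hz.
#' @inheritParams response_amplitude
#' @return an object of class `response_curve`: data frame with columns
#'   `frequency` and `amplitude` (spikes/s).
#' @export
response_curve <- function(f_grid, profile, ff = feedforward_spec(),
                           epsp = epsp_params("medium"), r1 = 5, order = 2) {
  df <- data.frame(
    frequency = f_grid,
    amplitude = response_amplitude(f_grid, profile, ff, epsp, r1, order))
  class(df) <- c("response_curve", "data.frame")
  df
}

#' Peak response frequency of a trained network
#'
#' Location of the dominant interior local maximum of
#' [response_amplitude] above a low-frequency cutoff (the response always
#' has a peak at 0 Hz, which is excluded; the cutoff defaults to 10 Hz).
#' Returns `NA` when no interior peak exists in the searched interval —
#' slow kernels or wide profiles suppress all interior structure.
#'
#' Search: 1 Hz grid scan, then golden-section refinement of the bracketed
#' maximum. Among multiple interior maxima the highest is returned (the
#' truncated second-order series can produce a shallow spurious ripple
#' near the anti-resonance, which the full resummation does not have; the
#' dominant peak tracks the genuine resonance).
#'
#' @param profile a [gaussian_profile_spec].
#' @param ff a [feedforward_spec].
#' @param epsp an [epsp_params].
#' @param r1 input modulation amplitude in spikes/s.
#' @param f_search search interval in Hz; must exclude 0.
#' @return peak frequency in Hz, or `NA_real_` if no interior peak.
#' @export
peak_response_frequency <- function(profile, ff = feedforward_spec(),
                                    epsp = epsp_params("medium"), r1 = 5,
                                    f_search = c(10, 1000)) {
  if (length(f_search) != 2 || f_search[1] <= 0 || f_search[2] <= f_search[1])
    stop("invalid search interval (must exclude 0 Hz and be increasing)")
  grid <- seq(f_search[1], f_search[2], by = 1)
  a <- response_amplitude(grid, profile, ff, epsp, r1)
  n <- length(a)
  interior <- which(a[2:(n - 1)] >= a[1:(n - 2)] &
                    a[2:(n - 1)] >= a[3:n]) + 1
  interior <- interior[interior > 1 & interior < n]
  if (length(interior) == 0) return(NA_real_)
  i <- interior[which.max(a[interior])]
  opt <- stats::optimize(
    function(f) response_amplitude(f, profile, ff, epsp, r1),
    lower = grid[i - 1], upper = grid[i + 1], maximum = TRUE,
    tol = 1e-6)
  opt$maximum
}

#' Weight scale factor at criticality
#'
#' The smallest multiplicative scaling of the recurrent weights at which
#' the linear recurrent loop gain reaches 1 at some frequency:
#' \eqn{s^* = 1 / \max_f |G(f)|/s}. Trained networks are placed "just
#' below criticality" by scaling to slightly less than this factor. A
#' network with zero recurrent gain is never critical (`Inf`).
#'
#' @param profile a [gaussian_profile_spec] or [delay_profile].
#' @param epsp an [epsp_params].
#' @param f_grid frequencies (Hz) over which the gain is maximised.
#' @return the critical scale factor (possibly `Inf`).
#' @export
critical_weight <- function(profile, epsp = epsp_params("medium"),
                            f_grid = seq(0, 1000, by = 1)) {
  gain <- if (inherits(profile, "gaussian_profile_spec")) {
    Mod(gaussian_gain(profile, epsp, f_grid))
  } else if (inherits(profile, "delay_profile")) {
    Mod(profile_gain_ft(profile, f_grid)$z * epsp_ft(epsp, f_grid)$z)
  } else stop("profile must be a gaussian_profile_spec or delay_profile")
  m <- max(gain)
  if (m <= 0) Inf else 1 / m
}

#' Oscillatory response amplitudes of two coupled groups
#'
#' After two-group learning the within-group connections are fully
#' depressed, so each group's oscillation is its feed-forward drive plus
#' the other group's oscillation fed through the between-group Gaussian
#' profile. With group 2's input lagging by `t_lag`, the second-order
#' phasor sums are
#' \deqn{\hat A_1 = |F_1 + G_{12}F_2 + G_{12}G_{21}F_1|, \qquad
#'       \hat A_2 = |F_2 + G_{21}F_1 + G_{21}G_{12}F_2|,}
#' with \eqn{F_2 = F_1 e^{-2\pi i f T_{lag}}} and \eqn{G_{kl}} the loop
#' gain of the profile from group \eqn{l} into group \eqn{k}. Amplitudes
#' are periodic in `t_lag` with period `1/f` and maximal (and equal, for
#' mirrored profiles) at the trained lag.
#'
#' @param f test frequency in Hz.
#' @param t_lag time lag of group 2's inputs behind group 1's, in ms.
#' @param between_profiles list of two [gaussian_profile_spec]s:
#'   `p12` (from group 2 into group 1) and `p21` (from group 1 into
#'   group 2).
#' @param ff a [feedforward_spec].
#' @param epsp an [epsp_params].
#' @param r1 input modulation amplitude in spikes/s.
#' @param order expansion order (`1`, `2`, or `Inf`).
#' @return named numeric vector `c(amplitude1, amplitude2)` in spikes/s.
#' @export
two_group_response <- function(f, t_lag, between_profiles,
                               ff = feedforward_spec(),
                               epsp = epsp_params("slow"), r1 = 5,
                               order = 2) {
  p12 <- between_profiles[[1]]; p21 <- between_profiles[[2]]
  g12 <- gaussian_gain(p12, epsp, f)
  g21 <- gaussian_gain(p21, epsp, f)
  if (Mod(g12 * g21) >= 1)
    stop("super-critical configuration: between-group loop gain >= 1")
  f1 <- r1 * ff$j_ff * epsp_ft(epsp, f)$z * exp(-2i * pi * f * ff$d_in / 1000)
  f2 <- f1 * exp(-2i * pi * f * t_lag / 1000)
  if (is.infinite(order)) {
    a1 <- Mod((f1 + g12 * f2) / (1 - g12 * g21))
    a2 <- Mod((f2 + g21 * f1) / (1 - g12 * g21))
  } else {
    a1 <- f1; a2 <- f2
    if (order >= 1) { a1 <- a1 + g12 * f2; a2 <- a2 + g21 * f1 }
    if (order >= 2) { a1 <- a1 + g12 * g21 * f1; a2 <- a2 + g21 * g12 * f2 }
    a1 <- Mod(a1); a2 <- Mod(a2)
  }
  c(amplitude1 = a1, amplitude2 = a2)
}

#' Two-group response surface over frequency and lag
#'
#' Mean of the two group response amplitudes on a (frequency, lag) grid —
#' the heat-map summary of lag- and frequency-selectivity after two-group
#' learning.
#'
#' @param f_grid test frequencies in Hz.
#' @param lag_grid test lags in ms.
#' @inheritParams two_group_response
#' @return an object of class `response_surface`: list with `f_grid`,
#'   `lag_grid` and `amplitude` matrix (rows = frequencies).
#' @export
two_group_response_surface <- function(f_grid, lag_grid, between_profiles,
                                       ff = feedforward_spec(),
                                       epsp = epsp_params("slow"), r1 = 5,
                                       order = 2) {
  amp <- matrix(NA_real_, length(f_grid), length(lag_grid))
  for (i in seq_along(f_grid)) for (j in seq_along(lag_grid)) {
    amp[i, j] <- mean(two_group_response(f_grid[i], lag_grid[j],
                                         between_profiles, ff, epsp, r1,
                                         order))
  }
  structure(list(f_grid = f_grid, lag_grid = lag_grid, amplitude = amp),
            class = "response_surface")
}

#' Write a response curve or surface as delimited text
#'
#' @param x a `response_curve` or `response_surface`.
#' @param path file path.
#' @param header optional named list echoed into `#` header comments.
#' @return `path`, invisibly.
#' @export
write_response <- function(x, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header))
    writeLines(sprintf("# %s=%s", nm, format(header[[nm]])), con)
  if (inherits(x, "response_curve")) {
    writeLines("# frequency_hz\tamplitude", con)
    utils::write.table(x, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else if (inherits(x, "response_surface")) {
    writeLines("# frequency_hz\tlag_ms\tamplitude", con)
    df <- expand.grid(frequency = x$f_grid, lag = x$lag_grid)
    df$amplitude <- as.vector(x$amplitude)
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
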