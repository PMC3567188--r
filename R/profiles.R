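#' Weighted axonal delay profile
#'
#' The central learned object of the model: the mean synaptic weight
#' \eqn{J(d)} of recurrent connections as a function of their axonal delay
#' \eqn{d}, on an ascending grid. For connections whose delays are sampled
#' uniformly from `delay_range`, the profile integrates (trapezoidally) to
#' `mean weight x (d_max - d_min)`.
#'
#' `n_connections` is the recurrent fan-in the profile summarises; the total
#' recurrent gain of the network (which must stay below 1 for stable rates)
#' is `n_connections x mean weight` because the EPSP kernel has unit area.
#'
#' @param delay_grid ascending axonal delays in ms.
#' @param weights mean weight per delay, same length as `delay_grid`,
#'   all in `[0, j_max]`.
#' @param j_max hard upper weight bound of the additive STDP rule.
#' @param delay_range length-2 range `[d_min, d_max]` in ms (defaults to the
#'   grid range).
#' @param n_connections recurrent fan-in represented by the profile.
#' @return an object of class `delay_profile`.
#' @export
delay_profile <- function(delay_grid, weights, j_max,
                          delay_range = range(delay_grid),
                          n_connections = 100) {
  if (is.unsorted(delay_grid, strictly = TRUE))
    stop("delay_grid must be strictly ascending")
  if (length(weights) != length(delay_grid))
    stop("weights and delay_grid lengths differ")
  if (any(weights < -1e-12) || any(weights > j_max + 1e-12))
    stop("weights must lie in [0, j_max]")
  structure(list(delay_grid = delay_grid,
                 weights = pmin(pmax(weights, 0), j_max),
                 j_max = j_max,
                 delay_range = delay_range,
                 n_connections = n_connections),
            class = "delay_profile")
}

#' Flat delay profile at a given mean weight
#'
#' @param mean_weight the uniform weight value.
#' @param j_max upper weight bound.
#' @param delay_range `[d_min, d_max]` in ms.
#' @param delay_step grid spacing in ms (0.1 ms, the resolution at which
#'   selected delays are reported).
#' @param n_connections recurrent fan-in.
#' @return a [delay_profile].
#' @export
flat_delay_profile <- function(mean_weight, j_max,
                               delay_range = c(1, 10), delay_step = 0.1,
                               n_connections = 100) {
  grid <- seq(delay_range[1], delay_range[2], by = delay_step)
  delay_profile(grid, rep(mean_weight, length(grid)), j_max,
                delay_range, n_connections)
}

#' @export
print.delay_profile <- function(x, ...) {
  cat(sprintf(
    "delay profile: %d delays in [%g, %g] ms, mean weight %.4g (j_max %g)\n",
    length(x$delay_grid), x$delay_range[1], x$delay_range[2],
    mean(x$weights), x$j_max))
  invisible(x)
}

#' Mean weight of a delay profile
#' @param profile a [delay_profile].
#' @return the mean weight over the grid.
#' @export
profile_mean_weight <- function(profile) mean(profile$weights)

# trapezoidal integral of the profile over the delay grid (ms units)
profile_integral <- function(profile) {
  d <- profile$delay_grid
  w <- profile$weights
  sum(diff(d) * (utils::head(w, -1) + utils::tail(w, -1)) / 2)
}

#' Fourier transform of the recurrent gain of a delay profile
#'
#' Treats the profile as a delay density carrying a total recurrent gain of
#' `n_connections x mean weight`; returns
#' \eqn{\tilde J(f) = g \int p(d)\,e^{-2\pi i f d}\,dd} where \eqn{p} is the
#' weight density normalised to 1 and \eqn{g} the total gain. At `f = 0`
#' this is the total gain itself.
#'
#' @param profile a [delay_profile].
#' @param f frequency in Hz (vectorised).
#' @return a [spectrum_value].
#' @export
profile_gain_ft <- function(profile, f) {
  d <- profile$delay_grid / 1000
  w <- profile$weights
  tw <- profile_integral(profile) / 1000          # weight x s
  gain <- profile$n_connections * mean(w)
  z <- vapply(f, function(fi) {
    if (tw <= 0) return(0 + 0i)
    ph <- exp(-2i * pi * fi * d)
    num <- sum(diff(d) * (utils::head(w * ph, -1) + utils::tail(w * ph, -1)) / 2)
    gain * num / tw
  }, complex(1))
  spectrum_value(z, f)
}

#' Gaussian fit to a learned delay profile
#'
#' Moment-matches a Gaussian to the weight mass above the profile's
#' baseline (its minimum): the fitted mean and SD are the mean and SD of
#' the delay distribution weighted by `weights - min(weights)`. Used to
#' summarise post-learning profiles for the closed-form response formulas.
#'
#' @param profile a [delay_profile].
#' @param j_rec total recurrent gain to assign; defaults to the profile's
#'   `n_connections x mean weight`.
#' @return a [gaussian_profile_spec].
#' @export
gaussian_fit_profile <- function(profile, j_rec = NULL) {
  w <- profile$weights - min(profile$weights)
  if (sum(w) <= 0) stop("profile has no mass above baseline")
  d <- profile$delay_grid
  mu <- sum(d * w) / sum(w)
  sigma <- sqrt(sum((d - mu)^2 * w) / sum(w))
  if (is.null(j_rec)) j_rec <- profile$n_connections * mean(profile$weights)
  gaussian_profile_spec(mu = mu, sigma = sigma, j_rec = j_rec)
}

#' Two-dimensional (axonal x dendritic) delay profile
#'
#' @param axonal_grid ascending axonal delays in ms.
#' @param dendritic_grid ascending dendritic delays in ms.
#' @param weights matrix of mean weights, rows = axonal, cols = dendritic,
#'   bounded in `[0, j_max]`.
#' @param j_max upper weight bound.
#' @return an object of class `delay_profile_2d`.
#' @export
delay_profile_2d <- function(axonal_grid, dendritic_grid, weights, j_max) {
  stopifnot(nrow(weights) == length(axonal_grid),
            ncol(weights) == length(dendritic_grid))
  if (any(weights < -1e-12) || any(weights > j_max + 1e-12))
    stop("weights must lie in [0, j_max]")
  structure(list(axonal_grid = axonal_grid, dendritic_grid = dendritic_grid,
                 weights = weights, j_max = j_max),
            class = "delay_profile_2d")
}

#' Group-indexed matrix of delay profiles
#'
#' Container for the four connection classes of a two-group network:
#' `profiles[[k]][[l]]` is the [delay_profile] for connections from group
#' `l` into group `k`.
#'
#' @param p11,p12,p21,p22 [delay_profile] objects (`pKL` = from group L
#'   into group K).
#' @return an object of class `group_profile_matrix`.
#' @export
group_profile_matrix <- function(p11, p12, p21, p22) {
  for (p in list(p11, p12, p21, p22)) stopifnot(inherits(p, "delay_profile"))
  structure(list(profiles = list(list(p11, p12), list(p21, p22))),
            class = "group_profile_matrix")
}

#' Write / read a delay profile as two-column text
#'
#' Plain-text serialisation: header comments (`#`) carrying the grid
#' metadata, then `delay_ms<TAB>mean_weight` rows.
#'
#' @param profile a [delay_profile].
#' @param path file path.
#' @return `write_delay_profile` returns `path` invisibly;
#'   `read_delay_profile` returns a [delay_profile].
#' @export
write_delay_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# delay_profile j_max=%.17g", profile$j_max),
    sprintf("# delay_range=%.17g,%.17g n_connections=%d",
            profile$delay_range[1], profile$delay_range[2],
            as.integer(profile$n_connections)),
    "# delay_ms\tmean_weight"), con)
  utils::write.table(
    data.frame(profile$delay_grid, profile$weights), con,
    sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_delay_profile
#' @export
read_delay_profile <- function(path) {
  hdr <- readLines(path, n = 3)
  j_max <- as.numeric(sub(".*j_max=", "", hdr[1]))
  rng <- as.numeric(strsplit(sub(".*delay_range=([^ ]+).*", "\\1", hdr[2]),
                             ",")[[1]])
  k <- as.integer(sub(".*n_connections=", "", hdr[2]))
  d <- utils::read.table(path, comment.char = "#", sep = "\t")
  delay_profile(d[[1]], d[[2]], j_max, rng, k)
}
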