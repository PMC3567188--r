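#' Spike train set
#'
#' Container for per-source spike times: a list of strictly increasing
#' numeric vectors (seconds) over a common duration.
#'
#' @param trains list of numeric vectors of spike times in `[0, duration)`.
#' @param duration total duration in seconds.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration) {
  for (tr in trains) {
    if (length(tr) > 1 && any(diff(tr) <= 0))
      stop("spike times must be strictly increasing per source")
    if (length(tr) && (min(tr) < 0 || max(tr) >= duration))
      stop("spike times must lie in [0, duration)")
  }
  structure(list(trains = trains, duration = duration,
                 n_sources = length(trains)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- sum(lengths(x$trains))
  cat(sprintf(
    "spike trains: %d sources, %g s, %d spikes (mean rate %.2f /s)\n",
    x$n_sources, x$duration, n, n / (x$n_sources * x$duration)))
  invisible(x)
}

#' Mean firing rate of a spike train set
#' @param x a [spike_train_set].
#' @return spikes per second per source.
#' @export
mean_rate <- function(x) {
  sum(lengths(x$trains)) / (x$n_sources * x$duration)
}

# thinning sampler for one source; own RNG substream so any single train can
# be regenerated independently of the others
thin_one <- function(drive, duration, seed_i) {
  set.seed(seed_i)
  rmax <- drive$r0 + drive$r1
  n_cand <- stats::rpois(1, rmax * duration)
  if (n_cand == 0) return(numeric(0))
  t_cand <- unique(sort(stats::runif(n_cand, 0, duration)))
  accept <- stats::runif(length(t_cand)) * rmax <
    drive$r0 + drive$r1 * cos(2 * pi * drive$f_mod * (t_cand - drive$t0))
  t_cand[accept]
}

#' Generate oscillatory Poisson spike trains
#'
#' Each train is an independent realisation of the inhomogeneous Poisson
#' process with intensity
#' \eqn{r(t) = r_0 + r_1\cos(2\pi f_{mod}(t - t_0))}, sampled by thinning
#' against the homogeneous bound \eqn{r_0 + r_1} (exact, O(expected
#' spikes)). Sources share only this rate modulation: no spike-timing
#' correlations beyond second order are introduced. Each source draws from
#' its own seeded RNG substream, so the output is bit-reproducible per seed
#' and any single train can be regenerated in isolation.
#'
#' @param n number of sources.
#' @param drive a [drive_spec] (requires `r1 <= r0`).
#' @param duration duration in seconds (> 0).
#' @param seed integer seed.
#' @return a [spike_train_set].
#' @export
generate_oscillatory_trains <- function(n, drive, duration, seed) {
  stopifnot(inherits(drive, "drive_spec"))
  if (duration <= 0) stop("duration must be positive")
  trains <- lapply(seq_len(n), function(i) {
    thin_one(drive, duration, (seed + 1000003 * i) %% 2147483629L)
  })
  spike_train_set(trains, duration)
}

#' Generate two groups of out-of-phase oscillatory trains
#'
#' Group 1 oscillates with phase delay `t0`, group 2 with `t0 + t_lag`.
#' Sources are independent within and across groups.
#'
#' @param n_per_group sources per group.
#' @param drive2 a [two_group_drive_spec].
#' @param duration duration in seconds.
#' @param seed integer seed.
#' @return list of two [spike_train_set]s, `group1` and `group2`.
#' @export
generate_two_group_trains <- function(n_per_group, drive2, duration, seed) {
  stopifnot(inherits(drive2, "two_group_drive_spec"))
  b <- drive2$base
  d2 <- drive_spec(b$r0, b$r1, b$f_mod, b$t0 + drive2$t_lag)
  list(group1 = generate_oscillatory_trains(n_per_group, b, duration, seed),
       group2 = generate_oscillatory_trains(n_per_group, d2, duration,
                                            seed + 777))
}

#' Estimate a pair-averaged spike-train correlogram
#'
#' Unbiased estimate of the second-order correlation function
#' \eqn{C(u)} over lag bins, in rate-product units (spikes^2/s^2): pair
#' counts of time differences are divided by the number of pairs, the bin
#' width, and the boundary-corrected overlap `duration - |lag|`. For
#' independent homogeneous trains at rate r the estimate is flat at
#' \eqn{r^2}; for shared sinusoidal rate modulation it converges to
#' \eqn{r_0^2 + (r_1^2/2)\cos(2\pi f_{mod} u)}.
#'
#' In autocorrelation mode (`b` omitted) each train is paired with itself;
#' the self-spike delta mass at zero lag is excluded from the binned
#' density and reported separately as `zero_lag_rate` (the mean firing
#' rate, the weight of the \eqn{\bar r\,\delta(u)} term).
#'
#' @param a a [spike_train_set].
#' @param b optional second [spike_train_set]; omit for autocorrelation.
#' @param bin lag bin width in seconds (> 0).
#' @param max_lag maximum lag in seconds (rounded to a multiple of `bin`).
#' @param max_pairs maximum number of source pairs sampled (cross mode).
#' @param seed seed for pair sampling.
#' @return an object of class `correlogram`: list with `lag_bins` (bin
#'   centers, s), `density` (spikes^2/s^2), `n_pairs`, and
#'   `zero_lag_rate` (autocorrelation mode only, else `NA`).
#' @export
estimate_correlogram <- function(a, b = NULL, bin = 1e-3, max_lag = 50e-3,
                                 max_pairs = 1000, seed = 1) {
  stopifnot(inherits(a, "spike_train_set"))
  if (bin <= 0) stop("bin must be positive")
  if (a$n_sources == 0 || sum(lengths(a$trains)) == 0)
    stop("empty train set")
  n_half <- round(max_lag / bin)
  lag_bins <- seq(-n_half, n_half) * bin
  counts <- integer(2 * n_half + 1)
  auto <- is.null(b)
  if (auto) {
    pairs <- cbind(seq_len(a$n_sources), seq_len(a$n_sources))
    b <- a
  } else {
    stopifnot(inherits(b, "spike_train_set"))
    if (b$n_sources == 0 || sum(lengths(b$trains)) == 0)
      stop("empty train set")
    pairs <- as.matrix(expand.grid(i = seq_len(a$n_sources),
                                   j = seq_len(b$n_sources)))
    if (identical(a, b))       # cross-correlation within one set: drop self
      pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > max_pairs) {
      set.seed(seed)
      pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
    }
  }
  for (r in seq_len(nrow(pairs))) {
    counts <- counts + cpp_crosscorr_counts(
      a$trains[[pairs[r, 1]]], b$trains[[pairs[r, 2]]],
      bin, n_half, exclude_zero = auto)
  }
  overlap <- pmax(a$duration - abs(lag_bins), bin)
  density <- counts / (nrow(pairs) * bin * overlap)
  structure(list(lag_bins = lag_bins, density = density,
                 n_pairs = nrow(pairs),
                 zero_lag_rate = if (auto) mean_rate(a) else NA_real_),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("correlogram: %d lag bins, %d pairs\n",
              length(x$lag_bins), x$n_pairs))
  invisible(x)
}

#' Write / read spike trains as two-column delimited text
#'
#' Format: `#` header comments (duration, n_sources), then
#' `source_id<TAB>time_s` rows sorted by time.
#'
#' @param x a [spike_train_set].
#' @param path file path.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a [spike_train_set].
#' @export
write_spike_trains <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spike_train_set duration=%.17g n_sources=%d",
                       x$duration, x$n_sources),
               "# source_id\ttime_s"), con)
  df <- data.frame(
    id = rep.int(seq_along(x$trains), lengths(x$trains)),
    t = unlist(x$trains, use.names = FALSE))
  df <- df[order(df$t), ]
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  hdr <- readLines(path, n = 1)
  duration <- as.numeric(sub(".*duration=([^ ]+).*", "\\1", hdr))
  n_sources <- as.integer(sub(".*n_sources=", "", hdr))
  df <- utils::read.table(path, comment.char = "#", sep = "\t",
                          col.names = c("id", "t"))
  trains <- lapply(seq_len(n_sources),
                   function(i) sort(df$t[df$id == i]))
  spike_train_set(trains, duration)
}
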