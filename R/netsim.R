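#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane constants paired with the three EPSP presets: faster synapses
#' come with faster membranes (20/10/5 ms for slow/medium/fast). The
#' synaptic reversal potential sits far above threshold, so the
#' conductance-style drive is near-current-like in the sub-threshold range.
#' `syn_gain` is the dimensionless weight-to-conductance calibration factor
#' (see [calibrate_lif_gain]); `NA` means "not yet calibrated".
#'
#' @param epsp_preset `"slow"`, `"medium"` or `"fast"` (sets `tau_m`).
#' @param tau_m membrane time constant in ms (overrides the preset pairing).
#' @param v_thresh,v_rest,v_reset,e_syn potentials in mV.
#' @param t_refr absolute refractory period in ms.
#' @param syn_gain weight-to-conductance scale (dimensionless).
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(epsp_preset = "medium", tau_m = NULL,
                       v_thresh = -50, v_rest = -65, v_reset = -65,
                       e_syn = 0, t_refr = 1, syn_gain = NA_real_) {
  if (is.null(tau_m))
    tau_m <- c(slow = 20, medium = 10, fast = 5)[[epsp_preset]]
  if (!(v_reset <= v_rest && v_rest < v_thresh))
    stop("need v_reset <= v_rest < v_thresh")
  if (tau_m <= 0 || t_refr < 0) stop("invalid time constants")
  structure(list(tau_m = tau_m, v_thresh = v_thresh, v_rest = v_rest,
                 v_reset = v_reset, e_syn = e_syn, t_refr = t_refr,
                 syn_gain = syn_gain),
            class = "lif_params")
}

# sample k distinct values from pool (excluding `exclude`) for each of n rows
sample_fanin <- function(n, pool, k, exclude = NULL) {
  t(vapply(seq_len(n), function(i) {
    p <- if (is.null(exclude)) pool else setdiff(pool, exclude[i])
    sample(p, k)
  }, integer(k)))
}

new_network_model <- function(n_inputs, n_neurons, groups, input_groups,
                              synapses, neuron_kind, epsp, lif, j_max,
                              delay_range, dt, seed) {
  structure(list(n_inputs = n_inputs, n_neurons = n_neurons,
                 group_assignment = groups, input_groups = input_groups,
                 synapses = synapses, neuron_kind = neuron_kind,
                 epsp = epsp, lif = lif, j_max = j_max,
                 delay_range = delay_range, dt = dt, seed = seed),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "network: %d %s neurons (%d groups), %d inputs, %d synapses (%d plastic)\n",
    x$n_neurons, x$neuron_kind, length(unique(x$group_assignment)),
    x$n_inputs, nrow(x$synapses), sum(x$synapses$plastic)))
  invisible(x)
}

# snap delays to the dt grid (delays live on a circular delay-line buffer)
snap_delay <- function(d_ms, dt) round(d_ms / 1000 / dt) * dt * 1000

#' Build a single-group recurrent network
#'
#' Random fan-in wiring of the single-group topology: `n_neurons` neurons,
#' each receiving `k_ff` feed-forward synapses from distinct randomly
#' chosen inputs (fixed weight `j_ff`, common axonal delay `d_in`, zero
#' dendritic delay) and `k_rec` plastic recurrent synapses from distinct
#' other neurons (initial weight `j0`, axonal delays i.i.d. uniform on
#' `delay_range`, dendritic delays uniform on `dendritic_range`, default
#' degenerate at 0). At most one synapse per ordered (pre, post) pair and
#' no self-connections. Delays are snapped to the `dt` grid.
#'
#' Defaults follow the reference configuration: fan-ins of 100, recurrent
#' axonal delays on 1-10 ms, per-synapse `j_ff = 1/k_ff` so the total
#' feed-forward gain is 1 (output rate of an isolated neuron matches the
#' input rate), and `j0 = j_max/2` so that recurrence raises the rate well
#' above the feed-forward-only rate while staying sub-critical
#' (`k_rec * j0 = 0.75 < 1`).
#'
#' @param n_neurons number of neurons.
#' @param n_inputs number of input sources (default `n_neurons`).
#' @param k_ff,k_rec feed-forward and recurrent fan-in per neuron.
#' @param delay_range recurrent axonal delay range in ms.
#' @param dendritic_range recurrent dendritic delay range in ms.
#' @param j_ff feed-forward weight per synapse.
#' @param j0 initial recurrent weight per synapse.
#' @param j_max hard upper bound for plastic weights.
#' @param neuron_kind `"poisson"` or `"lif"`.
#' @param epsp an [epsp_params] or preset name.
#' @param lif a [lif_params]; defaults to the pairing for the EPSP preset.
#' @param d_in input axonal delay in ms.
#' @param dt simulation step in seconds (0.1 ms default).
#' @param seed integer seed for wiring.
#' @return an object of class `network_model`.
#' @export
build_single_group <- function(n_neurons = 1000, n_inputs = n_neurons,
                               k_ff = 100, k_rec = 100,
                               delay_range = c(1, 10),
                               dendritic_range = c(0, 0),
                               j_ff = 1 / k_ff, j0 = j_max / 2,
                               j_max = 0.015,
                               neuron_kind = c("poisson", "lif"),
                               epsp = "medium", lif = NULL,
                               d_in = 1, dt = 1e-4, seed = 1) {
  neuron_kind <- match.arg(neuron_kind)
  if (k_ff > n_inputs) stop("infeasible fan-in: k_ff > n_inputs")
  if (k_rec >= n_neurons) stop("infeasible fan-in: k_rec >= n_neurons")
  epsp <- resolve_epsp(epsp)
  if (is.null(lif)) lif <- lif_params(epsp$preset_name)
  set.seed(seed)
  ff_pre <- sample_fanin(n_neurons, seq_len(n_inputs), k_ff)
  rec_pre <- sample_fanin(n_neurons, seq_len(n_neurons), k_rec,
                          exclude = seq_len(n_neurons))
  n_rec <- n_neurons * k_rec
  syn <- rbind(
    data.frame(pre = as.vector(t(ff_pre)),
               post = rep(seq_len(n_neurons), each = k_ff),
               weight = j_ff,
               d_axonal = snap_delay(d_in, dt), d_dendritic = 0,
               plastic = FALSE),
    data.frame(pre = n_inputs + as.vector(t(rec_pre)),
               post = rep(seq_len(n_neurons), each = k_rec),
               weight = j0,
               d_axonal = snap_delay(
                 stats::runif(n_rec, delay_range[1], delay_range[2]), dt),
               d_dendritic = snap_delay(
                 stats::runif(n_rec, dendritic_range[1], dendritic_range[2]),
                 dt),
               plastic = TRUE))
  new_network_model(n_inputs, n_neurons, rep(1L, n_neurons),
                    rep(1L, n_inputs), syn, neuron_kind, epsp, lif,
                    j_max, delay_range, dt, seed)
}

#' Build a two-group recurrent network
#'
#' Two neuron groups each fed block-diagonally from their own input group
#' (a neuron's feed-forward sources all lie in its own group's inputs);
#' recurrent synapses are drawn uniformly from the whole network, so
#' within- and between-group recurrent counts follow the hypergeometric
#' sampling distribution.
#'
#' @param n_per_group neurons per group.
#' @param n_inputs_per_group inputs per group (default `n_per_group`).
#' @inheritParams build_single_group
#' @return an object of class `network_model` with `group_assignment` in
#'   `{1, 2}`.
#' @export
build_two_groups <- function(n_per_group = 500,
                             n_inputs_per_group = n_per_group,
                             k_ff = 100, k_rec = 100,
                             delay_range = c(1, 10),
                             dendritic_range = c(0, 0),
                             j_ff = 1 / k_ff, j0 = j_max / 2,
                             j_max = 0.015,
                             neuron_kind = c("poisson", "lif"),
                             epsp = "slow", lif = NULL,
                             d_in = 1, dt = 1e-4, seed = 1) {
  neuron_kind <- match.arg(neuron_kind)
  n_neurons <- 2L * n_per_group
  n_inputs <- 2L * n_inputs_per_group
  if (k_ff > n_inputs_per_group)
    stop("infeasible fan-in: k_ff > n_inputs_per_group")
  if (k_rec >= n_neurons) stop("infeasible fan-in")
  epsp <- resolve_epsp(epsp)
  if (is.null(lif)) lif <- lif_params(epsp$preset_name)
  groups <- rep(1:2, each = n_per_group)
  input_groups <- rep(1:2, each = n_inputs_per_group)
  set.seed(seed)
  ff_pre <- t(vapply(seq_len(n_neurons), function(i) {
    pool <- which(input_groups == groups[i])
    sample(pool, k_ff)
  }, integer(k_ff)))
  rec_pre <- sample_fanin(n_neurons, seq_len(n_neurons), k_rec,
                          exclude = seq_len(n_neurons))
  n_rec <- n_neurons * k_rec
  syn <- rbind(
    data.frame(pre = as.vector(t(ff_pre)),
               post = rep(seq_len(n_neurons), each = k_ff),
               weight = j_ff,
               d_axonal = snap_delay(d_in, dt), d_dendritic = 0,
               plastic = FALSE),
    data.frame(pre = n_inputs + as.vector(t(rec_pre)),
               post = rep(seq_len(n_neurons), each = k_rec),
               weight = j0,
               d_axonal = snap_delay(
                 stats::runif(n_rec, delay_range[1], delay_range[2]), dt),
               d_dendritic = snap_delay(
                 stats::runif(n_rec, dendritic_range[1], dendritic_range[2]),
                 dt),
               plastic = TRUE))
  new_network_model(n_inputs, n_neurons, groups, input_groups, syn,
                    neuron_kind, epsp, lif, j_max, delay_range, dt, seed)
}

# coerce input spike trains (one set or a list of sets) to sorted (step, id)
inputs_to_events <- function(inputs, dt, n_inputs) {
  if (inherits(inputs, "spike_train_set")) inputs <- list(inputs)
  trains <- do.call(c, lapply(inputs, function(s) s$trains))
  if (length(trains) != n_inputs)
    stop("inputs provide ", length(trains), " sources; network expects ",
         n_inputs)
  ids <- rep.int(seq_along(trains), lengths(trains))
  steps <- floor(unlist(trains, use.names = FALSE) / dt)
  o <- order(steps, ids)
  list(steps = steps[o], ids = ids[o] - 1L,
       duration = max(vapply(inputs, function(s) s$duration, numeric(1))))
}

#' Simulate a network
#'
#' Steps the network at resolution `dt`. Poisson neurons emit a spike in a
#' step with probability `intensity * dt`, where the intensity is the
#' delayed, weighted sum of unit-area EPSP kernels of pre-synaptic spikes
#' (zero spontaneous rate); a warning is raised if that probability ever
#' exceeds 0.1 (step too coarse; the realised maximum is returned as
#' `max_poisson_p`). LIF neurons follow an Euler update of
#' the membrane equation with conductance-style drive toward `e_syn`,
#' threshold/reset, and an absolute refractory clamp. With
#' `plasticity_on`, recurrent synapses are updated online by the additive
#' STDP rule of [stdp_window] (all-to-all pairing at synaptic event times,
#' hard clipping to `[0, j_max]`); feed-forward weights are always fixed.
#'
#' A runaway guard aborts the run when the population rate exceeds
#' `runaway_rate` (default 10x the mean input rate) sustained over 100 ms.
#'
#' @param model a [network_model].
#' @param inputs a [spike_train_set] (or list of sets for two groups)
#'   covering `[0, duration)`.
#' @param duration simulated time in seconds (defaults to the input
#'   duration).
#' @param plasticity_on logical; apply STDP to recurrent synapses.
#' @param stdp an [stdp_window].
#' @param snapshot_every seconds between weight snapshots (NULL = none).
#' @param seed integer seed for the neurons' stochasticity.
#' @param record_spikes keep individual spike times (else only the
#'   population rate).
#' @param runaway_rate population-rate ceiling in spikes/s (NA disables).
#' @return an object of class `sim_result`: `spikes` ([spike_train_set] of
#'   the neurons, if recorded), `pop_rate` (per-step ensemble rate,
#'   spikes/s), `weights` (final synapse weights), `weight_snapshots`
#'   (matrix synapses x snapshots) with `snapshot_times`, `model` (with
#'   final weights), `runaway` flag, `max_poisson_p`.
#' @export
simulate_network <- function(model, inputs, duration = NULL,
                             plasticity_on = FALSE, stdp = stdp_window(),
                             snapshot_every = NULL, seed = 1,
                             record_spikes = TRUE, runaway_rate = NULL) {
  stopifnot(inherits(model, "network_model"))
  dt <- model$dt
  ev <- inputs_to_events(inputs, dt, model$n_inputs)
  if (is.null(duration)) duration <- ev$duration
  n_steps <- round(duration / dt)
  lif <- model$lif
  if (model$neuron_kind == "lif" && !is.finite(lif$syn_gain))
    stop("LIF model has no synaptic gain calibration; ",
         "run calibrate_lif_gain() first")
  if (is.null(runaway_rate)) {
    in_rate <- length(ev$steps) / (model$n_inputs * ev$duration)
    runaway_rate <- 10 * in_rate
  }
  syn <- model$synapses
  set.seed(seed)
  res <- cpp_simulate(
    model$n_inputs, model$n_neurons,
    if (model$neuron_kind == "poisson") 0L else 1L,
    as.integer(syn$pre) - 1L, as.integer(syn$post) - 1L,
    syn$weight,
    as.integer(round(syn$d_axonal / 1000 / dt)),
    as.integer(round(syn$d_dendritic / 1000 / dt)),
    syn$plastic,
    ev$steps, ev$ids,
    dt, n_steps,
    model$epsp$tau_rise / 1000, model$epsp$tau_decay / 1000,
    c(lif$tau_m / 1000, lif$v_thresh, lif$v_rest, lif$v_reset, lif$e_syn,
      round(lif$t_refr / 1000 / dt),
      if (is.finite(lif$syn_gain)) lif$syn_gain else 1),
    plasticity_on,
    c(stdp$eta, stdp$c_pot, stdp$c_dep, stdp$tau_pot / 1000,
      stdp$tau_dep / 1000, stdp$w_in, stdp$w_out, model$j_max),
    if (is.null(snapshot_every)) 0L
    else as.integer(round(snapshot_every / dt)),
    record_spikes,
    if (is.na(runaway_rate)) -1 else runaway_rate,
    as.integer(round(0.1 / dt)))
  if (model$neuron_kind == "poisson" && res$max_poisson_p > 0.1)
    warning(sprintf(
      "poisson step too coarse: max spike probability %.3g > 0.1",
      res$max_poisson_p))
  spikes <- NULL
  if (record_spikes) {
    tms <- (res$spike_step + 0.5) * dt
    trains <- split(tms, factor(res$spike_id + 1L,
                                levels = seq_len(model$n_neurons)))
    spikes <- spike_train_set(lapply(trains, as.numeric), duration)
  }
  model$synapses$weight <- res$weights
  ns <- res$n_snapshots
  structure(list(
    spikes = spikes,
    pop_rate = res$step_counts / (model$n_neurons * dt),
    dt = dt, duration = duration,
    weights = res$weights,
    weight_snapshots = if (ns > 0) res$snapshots[, seq_len(ns), drop = FALSE]
                       else NULL,
    snapshot_times = if (ns > 0) res$snapshot_steps[seq_len(ns)] * dt
                     else NULL,
    model = model,
    runaway = res$runaway,
    runaway_time = if (res$runaway) res$runaway_step * dt else NA_real_,
    max_poisson_p = res$max_poisson_p),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulation: %g s, mean population rate %.2f /s%s\n",
              x$duration, mean(x$pop_rate),
              if (x$runaway) sprintf(" [RUNAWAY at %.3f s]", x$runaway_time)
              else ""))
  invisible(x)
}

#' Offline additive STDP weight change for one synapse (reference rule)
#'
#' Exact all-to-all pairing: every (pre, post) somatic spike pair
#' contributes \eqn{W(t_{post} + d_d - t_{pre} - d_a)}, every pre spike
#' adds \eqn{\eta w_{in}} and every post spike \eqn{\eta w_{out}}. No
#' clipping is applied (the online rule clips after each event); use small
#' rates when comparing against [simulate_network].
#'
#' @param pre_times,post_times somatic spike times in seconds.
#' @param d_axonal,d_dendritic delays in ms.
#' @param stdp an [stdp_window].
#' @return total weight change (dimensionless).
#' @export
apply_stdp <- function(pre_times, post_times, d_axonal = 0, d_dendritic = 0,
                       stdp = stdp_window()) {
  dw <- stdp$eta * (stdp$w_in * length(pre_times) +
                    stdp$w_out * length(post_times))
  if (length(pre_times) && length(post_times)) {
    u <- outer(post_times + d_dendritic / 1000,
               pre_times + d_axonal / 1000, `-`) * 1000   # ms
    dw <- dw + sum(window_value(stdp, u))
  }
  dw
}

#' Measure the weighted delay profile of a network
#'
#' Mean recurrent weight per delay bin. `by = "axonal"` gives a 1D
#' [delay_profile] (weights `NA` for empty bins); `"axonal_dendritic"` a
#' [delay_profile_2d]; `"group"` a [group_profile_matrix] of per-class 1D
#' profiles.
#'
#' @param model a [network_model] (or a `sim_result`, whose final model is
#'   used).
#' @param bin_width delay bin width in ms.
#' @param by profile kind.
#' @return see above.
#' @export
delay_profile_from_network <- function(model, bin_width = 0.25,
                                       by = c("axonal", "axonal_dendritic",
                                              "group")) {
  by <- match.arg(by)
  if (inherits(model, "sim_result")) model <- model$model
  syn <- model$synapses[model$synapses$plastic, ]
  rng <- model$delay_range
  mids <- seq(rng[1] + bin_width / 2, rng[2], by = bin_width)
  bin_of <- function(d) pmin(pmax(ceiling((d - rng[1]) / bin_width), 1),
                             length(mids))
  prof_1d <- function(s) {
    idx <- bin_of(s$d_axonal)
    w <- vapply(seq_along(mids), function(b) {
      if (any(idx == b)) mean(s$weight[idx == b]) else NA_real_
    }, numeric(1))
    delay_profile(mids, ifelse(is.na(w), 0, w), model$j_max, rng,
                  n_connections = round(nrow(s) / model$n_neurons))
  }
  if (by == "axonal") {
    prof_1d(syn)
  } else if (by == "axonal_dendritic") {
    dd_max <- max(syn$d_dendritic, bin_width)
    mids_d <- seq(bin_width / 2, dd_max, by = bin_width)
    bin_d <- pmin(pmax(ceiling(syn$d_dendritic / bin_width), 1),
                  length(mids_d))
    bin_a <- bin_of(syn$d_axonal)
    w <- matrix(NA_real_, length(mids), length(mids_d))
    for (b in seq_along(mids)) for (bd in seq_along(mids_d)) {
      sel <- bin_a == b & bin_d == bd
      if (any(sel)) w[b, bd] <- mean(syn$weight[sel])
    }
    delay_profile_2d(mids, mids_d, ifelse(is.na(w), 0, w), model$j_max)
  } else {
    gr <- model$group_assignment
    pre_gr <- gr[syn$pre - model$n_inputs]
    post_gr <- gr[syn$post]
    p <- function(k, l) prof_1d(syn[post_gr == k & pre_gr == l, ])
    group_profile_matrix(p(1, 1), p(1, 2), p(2, 1), p(2, 2))
  }
}

#' Oscillatory population response of a simulation
#'
#' Cycle-folds the ensemble-averaged population rate at the test period
#' (discarding a warm-up) and returns the amplitude of the fundamental
#' Fourier component together with the peak of the cycle-averaged
#' waveform — the peak periodic response, the metric of choice for LIF
#' networks whose periodic response is no longer sinusoidal.
#'
#' @param result a `sim_result`.
#' @param f_test drive frequency in Hz.
#' @param warmup seconds discarded at the start (default 1).
#' @return named vector `c(amplitude, peak_rate, mean_rate)` in spikes/s.
#' @export
population_response <- function(result, f_test, warmup = 1) {
  dt <- result$dt
  rate <- result$pop_rate
  n <- length(rate)
  i0 <- min(round(warmup / dt) + 1, n)
  period_steps <- 1 / (f_test * dt)
  n_cycles <- floor((n - i0 + 1) / period_steps)
  if (n_cycles < 10) stop("need at least 10 drive cycles after warm-up")
  keep <- i0:(i0 + floor(n_cycles * period_steps) - 1)
  r <- rate[keep]
  t <- (keep - 1) * dt
  z <- 2 * mean(r * exp(-2i * pi * f_test * t))
  phase_bins <- pmax(8, min(round(period_steps), 72))
  ph <- floor((t * f_test) %% 1 * phase_bins) + 1
  folded <- tapply(r, ph, mean)
  c(amplitude = Mod(z), peak_rate = max(folded), mean_rate = mean(r))
}

#' Scale the recurrent weights of a network
#'
#' Uniform multiplicative scaling of all plastic (recurrent) weights;
#' feed-forward weights are untouched. Used to probe criticality and
#' frequency selectivity as a function of distance from the critical
#' point.
#'
#' @param model a [network_model].
#' @param factor non-negative scale factor.
#' @return the scaled [network_model].
#' @export
scale_weights <- function(model, factor) {
  if (factor < 0) stop("factor must be non-negative")
  sel <- model$synapses$plastic
  model$synapses$weight[sel] <- model$synapses$weight[sel] * factor
  model
}

#' Find the critical recurrent weight scale by bisection
#'
#' Bisects on the runaway criterion (population rate above `runaway_rate`,
#' default 10x the probe input rate, sustained 100 ms during a short probe
#' simulation with unmodulated Poisson drive): returns the largest tested
#' scale that stays stable. Trained networks are typically run at 0.99 of
#' this factor ("just below criticality").
#'
#' @param model a [network_model].
#' @param drive a [drive_spec] for the probe (modulation is ignored;
#'   `r0` is used).
#' @param probe_duration seconds per probe simulation.
#' @param bracket initial scale bracket.
#' @param tol bisection tolerance on the scale.
#' @param seed seed for probe inputs and neurons.
#' @return the critical scale factor.
#' @export
find_critical_scale <- function(model, drive, probe_duration = 1.5,
                                bracket = c(0.02, 8), tol = 0.02, seed = 99) {
  probe_drive <- drive_spec(drive$r0, 0, 0)
  inputs <- generate_oscillatory_trains(model$n_inputs, probe_drive,
                                        probe_duration, seed)
  stable <- function(scale) {
    # super-critical probes legitimately blow up; silence the step warning
    r <- suppressWarnings(
      simulate_network(scale_weights(model, scale), inputs,
                       probe_duration, plasticity_on = FALSE,
                       seed = seed, record_spikes = FALSE,
                       runaway_rate = 10 * drive$r0))
    !r$runaway
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (!stable(lo)) stop("network unstable at the lower bracket scale")
  if (stable(hi)) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stable(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Calibrate the LIF weight-to-conductance gain
#'
#' The mapping from dimensionless synaptic weight to membrane conductance
#' is fixed by the reference rule that, without recurrence, the temporally
#' averaged firing rate of the neurons approximately equals that of the
#' inputs. Bisects the gain on a short feed-forward-only simulation.
#'
#' @param model a [network_model] with `neuron_kind == "lif"`.
#' @param drive a [drive_spec]; the target rate is `drive$r0`.
#' @param duration probe duration in seconds.
#' @param bracket gain bracket searched.
#' @param seed probe seed.
#' @return the model with `lif$syn_gain` set.
#' @export
calibrate_lif_gain <- function(model, drive, duration = 2,
                               bracket = c(0.01, 30), seed = 7) {
  stopifnot(model$neuron_kind == "lif")
  ff_only <- model
  ff_only$synapses$weight[ff_only$synapses$plastic] <- 0
  inputs <- generate_oscillatory_trains(
    model$n_inputs, drive_spec(drive$r0, 0, 0), duration, seed)
  rate_at <- function(g) {
    ff_only$lif$syn_gain <- g
    r <- simulate_network(ff_only, inputs, duration, seed = seed,
                          record_spikes = FALSE, runaway_rate = NA)
    mean(r$pop_rate[-(1:round(0.2 / model$dt))])
  }
  f <- function(g) rate_at(g) - drive$r0
  if (f(bracket[1]) > 0) stop("gain bracket too high at lower end")
  if (f(bracket[2]) < 0) stop("gain bracket too low at upper end")
  g <- stats::uniroot(f, bracket, tol = 1e-4)$root
  model$lif$syn_gain <- g
  model
}

#' Write / read a network's synapse table as delimited text
#'
#' @param model a [network_model].
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` is not
#'   provided (networks are rebuilt from seeds; the table serves analysis
#'   and interchange).
#' @export
write_network <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# network_model kind=%s n_neurons=%d n_inputs=%d j_max=%.17g",
            model$neuron_kind, model$n_neurons, model$n_inputs, model$j_max),
    sprintf("# delay_range=%g,%g dt=%g seed=%d", model$delay_range[1],
            model$delay_range[2], model$dt, model$seed),
    "# pre\tpost\tweight\td_axonal_ms\td_dendritic_ms\tplastic"), con)
  utils::write.table(model$synapses, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
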