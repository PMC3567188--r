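#' Experiment configuration
#'
#' Loads (from a YAML file or a list) and validates the configuration of a
#' reproducible experiment run. Two scale presets are provided: `"desk"`
#' (small networks and short modeled durations, the default used by the
#' test suite) and `"paper"` (the full-scale protocol: 10,000 neurons and
#' tens of thousands of seconds of learning). All seeds are explicit.
#'
#' @param x path to a YAML file, or a named list.
#' @param preset `"desk"` or `"paper"`; overrides the config's own value.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(x, preset = NULL) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.null(preset)) cfg$preset <- preset
  if (is.null(cfg$preset)) cfg$preset <- "desk"
  if (!cfg$preset %in% c("desk", "paper")) stop("unknown preset")
  scale <- if (cfg$preset == "desk") {
    list(n_neurons = 1000, duration = 200, respond_duration = 4,
         n_per_group = 250, twogroup_duration = 100)
  } else {
    list(n_neurons = 10000, duration = 20000, respond_duration = 10,
         n_per_group = 5000, twogroup_duration = 20000)
  }
  defaults <- list(
    kind = "train", kernel = "medium",
    drive = list(r0 = 20, r1 = 5, f_mod = 120, t0 = 0),
    network = list(n_neurons = scale$n_neurons, k_ff = 100, k_rec = 100,
                   delay_range = c(1, 10), j_max = 0.015,
                   neuron_kind = "poisson"),
    train = list(duration = scale$duration, snapshot_every = NULL,
                 eta = 2e-4),
    respond = list(f_from = 50, f_to = 300, f_by = 5,
                   duration = scale$respond_duration, warmup = 1,
                   auto_scale = TRUE),
    twogroup = list(t_lag_ms = 6.5, n_per_group = scale$n_per_group,
                    duration = scale$twogroup_duration,
                    lag_from = 0, lag_to = 16, lag_by = 1),
    seeds = list(wiring = 1, inputs = 2, sim = 3),
    out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
    }
  }
  if (!cfg$kind %in% c("train", "respond", "twogroup", "analytic"))
    stop("unknown experiment kind: ", cfg$kind)
  resolve_epsp(cfg$kernel)  # validate preset exists
  structure(cfg, class = "experiment_config")
}

write_manifest <- function(cfg, dir, extra = list()) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- c(list(config = unclass(cfg),
                package_version =
                  as.character(utils::packageVersion("stdpdelay"))),
           extra)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

cfg_drive <- function(cfg) do.call(drive_spec, cfg$drive)

cfg_model <- function(cfg, two_group = FALSE) {
  nw <- cfg$network
  if (two_group) {
    build_two_groups(n_per_group = cfg$twogroup$n_per_group,
                     k_ff = min(nw$k_ff, cfg$twogroup$n_per_group),
                     k_rec = min(nw$k_rec, 2 * cfg$twogroup$n_per_group - 1),
                     delay_range = nw$delay_range, j_max = nw$j_max,
                     neuron_kind = nw$neuron_kind, epsp = cfg$kernel,
                     seed = cfg$seeds$wiring)
  } else {
    build_single_group(n_neurons = nw$n_neurons, k_ff = nw$k_ff,
                       k_rec = nw$k_rec, delay_range = nw$delay_range,
                       j_max = nw$j_max, neuron_kind = nw$neuron_kind,
                       epsp = cfg$kernel, seed = cfg$seeds$wiring)
  }
}

#' Run a training experiment
#'
#' Simulates the configured network with plasticity on under oscillatory
#' drive, snapshotting the recurrent delay profile and mean weight over
#' time. Artifacts (delay profiles per snapshot, mean-weight trace,
#' manifest) are written to `out_dir` when configured.
#'
#' @param cfg an [experiment_config] (kind `"train"`), or something
#'   coercible to one.
#' @return list with `result` (`sim_result`), `profile` (final
#'   [delay_profile]), `mean_weight` (data frame over time).
#' @export
run_training <- function(cfg) {
  cfg <- experiment_config(cfg)
  drive <- cfg_drive(cfg)
  model <- cfg_model(cfg)
  if (model$neuron_kind == "lif")
    model <- calibrate_lif_gain(model, drive)
  dur <- cfg$train$duration
  inputs <- generate_oscillatory_trains(model$n_inputs, drive, dur,
                                        cfg$seeds$inputs)
  snap <- cfg$train$snapshot_every
  if (is.null(snap)) snap <- dur / 5
  res <- simulate_network(model, inputs, dur, plasticity_on = TRUE,
                          stdp = stdp_window(eta = cfg$train$eta),
                          snapshot_every = snap, seed = cfg$seeds$sim,
                          record_spikes = FALSE)
  if (res$runaway)
    warning(sprintf("runaway activity at %.2f s; artifacts are partial",
                    res$runaway_time))
  prof <- delay_profile_from_network(res)
  mw <- data.frame(
    time = res$snapshot_times,
    mean_weight = colMeans(
      res$weight_snapshots[res$model$synapses$plastic, , drop = FALSE]))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_delay_profile(prof, file.path(cfg$out_dir, "profile_final.tsv"))
    utils::write.table(mw, file.path(cfg$out_dir, "mean_weight.tsv"),
                       sep = "\t", row.names = FALSE)
    write_manifest(cfg, cfg$out_dir)
  }
  list(result = res, profile = prof, mean_weight = mw)
}

#' Run a response (testing-frequency) sweep
#'
#' Drives a fixed network (plasticity off) at each test frequency and
#' records the peak periodic response and fundamental amplitude. With
#' `auto_scale`, the recurrent weights are first scaled to 0.99 of the
#' critical scale found by [find_critical_scale].
#'
#' @param cfg an [experiment_config] (kind `"respond"`).
#' @param model a [network_model] (e.g. from a training run); defaults to
#'   a freshly built network from the config.
#' @return a data frame with columns `frequency`, `peak_rate`,
#'   `amplitude`, `mean_rate`.
#' @export
run_response_sweep <- function(cfg, model = NULL) {
  cfg <- experiment_config(cfg)
  drive <- cfg_drive(cfg)
  if (is.null(model)) model <- cfg_model(cfg)
  if (model$neuron_kind == "lif" && !is.finite(model$lif$syn_gain))
    model <- calibrate_lif_gain(model, drive)
  if (isTRUE(cfg$respond$auto_scale)) {
    crit <- find_critical_scale(model, drive, seed = cfg$seeds$sim + 11)
    model <- scale_weights(model, 0.99 * crit)
  }
  f_grid <- seq(cfg$respond$f_from, cfg$respond$f_to, by = cfg$respond$f_by)
  dur <- cfg$respond$duration + cfg$respond$warmup
  rows <- lapply(seq_along(f_grid), function(i) {
    f <- f_grid[i]
    dr <- drive_spec(drive$r0, drive$r1, f)
    inputs <- generate_oscillatory_trains(model$n_inputs, dr, dur,
                                          cfg$seeds$inputs + i)
    r <- simulate_network(model, inputs, dur, plasticity_on = FALSE,
                          seed = cfg$seeds$sim + i, record_spikes = FALSE)
    pr <- population_response(r, f, warmup = cfg$respond$warmup)
    data.frame(frequency = f, peak_rate = pr[["peak_rate"]],
               amplitude = pr[["amplitude"]], mean_rate = pr[["mean_rate"]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(cfg$out_dir, "response_sweep.tsv"),
                       sep = "\t", row.names = FALSE)
    write_manifest(cfg, cfg$out_dir)
  }
  out
}

#' Run a two-group training and lag-sweep experiment
#'
#' Trains the two-group network at the configured frequency and lag, then
#' sweeps test lags at the training frequency, recording each group's peak
#' periodic response.
#'
#' @param cfg an [experiment_config] (kind `"twogroup"`).
#' @return list with `profiles` ([group_profile_matrix]), `model` (trained),
#'   `lag_sweep` (data frame `lag_ms`, `peak1`, `peak2`).
#' @export
run_twogroup <- function(cfg) {
  cfg <- experiment_config(cfg)
  drive2 <- two_group_drive_spec(cfg_drive(cfg),
                                 t_lag = cfg$twogroup$t_lag_ms / 1000)
  model <- cfg_model(cfg, two_group = TRUE)
  if (model$neuron_kind == "lif")
    model <- calibrate_lif_gain(model, drive2$base)
  dur <- cfg$twogroup$duration
  inputs <- generate_two_group_trains(model$n_inputs / 2, drive2, dur,
                                      cfg$seeds$inputs)
  res <- simulate_network(model, inputs, dur, plasticity_on = TRUE,
                          stdp = stdp_window(eta = cfg$train$eta),
                          seed = cfg$seeds$sim, record_spikes = FALSE)
  trained <- res$model
  profiles <- delay_profile_from_network(trained, by = "group")
  lags <- seq(cfg$twogroup$lag_from, cfg$twogroup$lag_to,
              by = cfg$twogroup$lag_by)
  test_dur <- cfg$respond$duration + cfg$respond$warmup
  sweep <- lapply(seq_along(lags), function(i) {
    d2 <- two_group_drive_spec(drive2$base, t_lag = lags[i] / 1000)
    ins <- generate_two_group_trains(model$n_inputs / 2, d2, test_dur,
                                     cfg$seeds$inputs + 100 + i)
    r <- simulate_network(trained, ins, test_dur, plasticity_on = FALSE,
                          seed = cfg$seeds$sim + i, record_spikes = TRUE)
    g <- trained$group_assignment
    peak_of <- function(grp) {
      sel <- which(g == grp)
      tms <- unlist(r$spikes$trains[sel], use.names = FALSE)
      rate <- tabulate(floor(tms / trained$dt) + 1,
                       nbins = length(r$pop_rate)) /
        (length(sel) * trained$dt)
      rr <- r
      rr$pop_rate <- rate
      population_response(rr, drive2$base$f_mod,
                          warmup = cfg$respond$warmup)[["peak_rate"]]
    }
    data.frame(lag_ms = lags[i], peak1 = peak_of(1), peak2 = peak_of(2))
  })
  lag_sweep <- do.call(rbind, sweep)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- profiles$profiles
    for (k in 1:2) for (l in 1:2)
      write_delay_profile(p[[k]][[l]],
                          file.path(cfg$out_dir,
                                    sprintf("profile_%dfrom%d.tsv", k, l)))
    utils::write.table(lag_sweep, file.path(cfg$out_dir, "lag_sweep.tsv"),
                       sep = "\t", row.names = FALSE)
    write_manifest(cfg, cfg$out_dir)
  }
  list(profiles = profiles, model = trained, lag_sweep = lag_sweep)
}

#' Run the analytic pipeline
#'
#' Deterministic evaluation of the analytic modules on the configured
#' grids: the axonal learning term over delay, selected delays over
#' frequency, post-learning response curves per EPSP preset (with a
#' `"none"` sentinel where no interior response peak exists), the 2D
#' learning-term heat map and its ridge slope, and the two-group response
#' surface. Writes delimited-text tables when `out_dir` is set.
#'
#' @param cfg an [experiment_config] (kind `"analytic"`).
#' @return a named list of data frames / objects.
#' @export
run_analytic <- function(cfg) {
  cfg <- experiment_config(cfg)
  drive <- cfg_drive(cfg)
  epsp <- resolve_epsp(cfg$kernel)
  window <- stdp_window()
  d_grid <- seq(cfg$network$delay_range[1], cfg$network$delay_range[2],
                by = 0.1)
  lt <- data.frame(
    delay_ms = d_grid,
    term = learning_term_axonal(d_grid, drive, window = window))
  lt$term <- lt$term / max(abs(lt$term))  # arbitrary units: peak |term| = 1
  f_grid <- seq(cfg$respond$f_from, cfg$respond$f_to, by = cfg$respond$f_by)
  sel <- data.frame(f_mod = f_grid,
                    selected_delay_ms = selected_delay(f_grid, window))
  resp <- lapply(c("slow", "medium", "fast"), function(pn) {
    ep <- epsp_params(pn)
    prof <- gaussian_profile_spec(mu = selected_delay(drive$f_mod, window),
                                  sigma = 0.5, j_rec = 0.5)
    pk <- peak_response_frequency(prof, epsp = ep, r1 = drive$r1)
    list(preset = pn,
         curve = response_curve(f_grid, prof, epsp = ep, r1 = drive$r1),
         peak = if (is.na(pk)) "none" else pk)
  })
  names(resp) <- c("slow", "medium", "fast")
  ridge <- ridge_slope_2d(drive, epsp = epsp, window = window)
  surf <- two_group_response_surface(
    f_grid = seq(max(20, cfg$respond$f_from), min(120, cfg$respond$f_to),
                 by = cfg$respond$f_by),
    lag_grid = seq(cfg$twogroup$lag_from, cfg$twogroup$lag_to,
                   by = cfg$twogroup$lag_by),
    between_profiles = list(
      gaussian_profile_spec(
        mu = selected_delay(60, window) - cfg$twogroup$t_lag_ms,
        sigma = 0.5, j_rec = 0.9),
      gaussian_profile_spec(
        mu = (selected_delay(60, window) + cfg$twogroup$t_lag_ms) %% (1000 / 60),
        sigma = 0.5, j_rec = 0.9)),
    epsp = epsp_params("custom", tau_rise = 1, tau_decay = 3),
    r1 = drive$r1)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(lt, file.path(cfg$out_dir, "learning_term.tsv"),
                       sep = "\t", row.names = FALSE)
    utils::write.table(sel, file.path(cfg$out_dir, "selected_delays.tsv"),
                       sep = "\t", row.names = FALSE)
    for (pn in names(resp)) {
      write_response(resp[[pn]]$curve,
                     file.path(cfg$out_dir, sprintf("response_%s.tsv", pn)),
                     header = list(peak = resp[[pn]]$peak))
    }
    write_response(surf, file.path(cfg$out_dir, "twogroup_surface.tsv"))
    write_manifest(cfg, cfg$out_dir,
                   extra = list(ridge_slope = ridge$slope))
  }
  list(learning_term = lt, selected_delays = sel, responses = resp,
       ridge = ridge, surface = surf)
}
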