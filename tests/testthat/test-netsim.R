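test_that("single-group builder wires the configured topology", {
  m <- build_single_group(n_neurons = 80, n_inputs = 120, k_ff = 30,
                          k_rec = 20, seed = 5)
  syn <- m$synapses
  rec <- syn[syn$plastic, ]
  ff <- syn[!syn$plastic, ]
  expect_equal(nrow(rec), 80 * 20)
  expect_equal(nrow(ff), 80 * 30)
  # no self-connections, no duplicate ordered pairs
  expect_true(all(rec$pre - m$n_inputs != rec$post))
  expect_false(any(duplicated(syn[, c("pre", "post")])))
  # feed-forward: common delay, fixed weight, zero dendritic delay
  expect_true(all(ff$d_axonal == 1 & ff$d_dendritic == 0))
  expect_equal(unique(ff$weight), 1 / 30)
  # recurrent axonal delays uniform on [1, 10] (chi-square on 9 bins)
  h <- table(cut(rec$d_axonal, seq(1, 10, by = 1), include.lowest = TRUE))
  expect_gt(chisq.test(h)$p.value, 0.01)
  # same seed twice: identical wiring
  expect_identical(m$synapses,
                   build_single_group(n_neurons = 80, n_inputs = 120,
                                      k_ff = 30, k_rec = 20,
                                      seed = 5)$synapses)
  expect_error(build_single_group(n_neurons = 10, n_inputs = 5, k_ff = 20,
                                  k_rec = 2), "infeasible")
})

test_that("two-group builder: block-diagonal feed-forward, whole-network
           recurrence with hypergeometric class counts", {
  m <- build_two_groups(n_per_group = 60, k_ff = 20, k_rec = 30, seed = 6)
  syn <- m$synapses
  ff <- syn[!syn$plastic, ]
  g <- m$group_assignment
  ig <- m$input_groups
  expect_true(all(ig[ff$pre] == g[ff$post]))
  rec <- syn[syn$plastic, ]
  within <- sum(g[rec$pre - m$n_inputs] == g[rec$post])
  # each neuron samples 30 of the other 119 neurons; 59 are in its own group
  expt <- nrow(rec) * 59 / 119
  se <- sqrt(nrow(rec) * (59 / 119) * (60 / 119))
  expect_lt(abs(within - expt), 3 * se)
})

test_that("simulation trivia: silence without input, expected spike count for
           one synapse, seed determinism, fixed weights with plasticity off", {
  m <- tiny_poisson_net()
  silent <- spike_train_set(rep(list(numeric(0)), 60), 1)
  r0 <- simulate_network(m, silent, 1, seed = 3)
  expect_equal(sum(lengths(r0$spikes$trains)), 0)
  # one input spike through weight w yields w expected output spikes
  m1 <- build_single_group(n_neurons = 2, n_inputs = 1, k_ff = 1, k_rec = 1,
                           j_ff = 0.5, j0 = 0, seed = 1)
  one <- spike_train_set(list(0.01), 0.3)
  tot <- 0
  for (s in 1:60) {
    r <- simulate_network(m1, one, 0.3, seed = s)
    tot <- tot + sum(lengths(r$spikes$trains))
  }
  # 2 neurons x 60 runs x 0.5 expected; Poisson SE ~ sqrt(60)
  expect_lt(abs(tot - 60), 4 * sqrt(60))
  # determinism
  drv <- drive_spec(f_mod = 120)
  ins <- generate_oscillatory_trains(60, drv, 1, seed = 2)
  ra <- simulate_network(m, ins, 1, seed = 9)
  rb <- simulate_network(m, ins, 1, seed = 9)
  expect_identical(ra$spikes, rb$spikes)
  expect_identical(ra$pop_rate, rb$pop_rate)
  # plasticity off: weights bit-identical
  expect_identical(ra$weights, m$synapses$weight)
})

test_that("LIF respects the absolute refractory period and calibrates to the
           input rate", {
  m <- build_single_group(n_neurons = 150, n_inputs = 150, k_ff = 50,
                          k_rec = 10, j_ff = 1 / 50, neuron_kind = "lif",
                          epsp = "fast", seed = 4)
  drv <- drive_spec(r0 = 20, r1 = 5, f_mod = 240)
  m <- calibrate_lif_gain(m, drv, duration = 4)
  # calibration: feed-forward-only rate within 10% of the input rate
  ff_only <- m
  ff_only$synapses$weight[ff_only$synapses$plastic] <- 0
  ins0 <- generate_oscillatory_trains(150, drive_spec(r0 = 20, r1 = 0), 3,
                                      seed = 5)
  r <- simulate_network(ff_only, ins0, 3, seed = 6)
  expect_lt(abs(mean(r$pop_rate[-(1:2000)]) - 20) / 20, 0.1)
  # refractory: no ISI below 1 ms, ever
  ins <- generate_oscillatory_trains(150, drv, 2, seed = 7)
  r2 <- simulate_network(m, ins, 2, seed = 8)
  isis <- unlist(lapply(r2$spikes$trains, diff))
  expect_gt(length(isis), 100)
  expect_true(all(isis >= 1e-3 - 1e-9))
})

test_that("apply_stdp matches the closed form for a single pair and the
           online simulator matches the offline rule synapse by synapse", {
  w <- stdp_window(eta = 1e-3)
  # single pre at 0, single post at +8 ms, no delays
  expect_equal(apply_stdp(0, 8e-3, 0, 0, w),
               w$eta * (w$w_in + w$w_out) + window_value(w, 8))
  # increasing the axonal delay shifts the pairing depression-ward
  expect_lt(apply_stdp(0, 8e-3, 12, 0, w), apply_stdp(0, 8e-3, 2, 0, w))
  # increasing the dendritic delay shifts it potentiation-ward
  expect_gt(apply_stdp(0, 8e-3, 12, 6, w), apply_stdp(0, 8e-3, 12, 0, w))

  # dual route: online trace-based C++ rule vs offline all-to-all pairing
  m <- build_single_group(n_neurons = 30, n_inputs = 30, k_ff = 10,
                          k_rec = 8, j_ff = 1 / 10, seed = 11)
  dur <- 3
  ins <- generate_oscillatory_trains(30, drive_spec(f_mod = 120), dur,
                                     seed = 5)
  wt <- stdp_window(eta = 1e-7)  # small: clipping never engages
  res <- simulate_network(m, ins, dur, plasticity_on = TRUE, stdp = wt,
                          seed = 9)
  syn <- m$synapses[m$synapses$plastic, ]
  fin <- res$model$synapses[res$model$synapses$plastic, ]
  tr <- res$spikes$trains
  dt <- m$dt
  # offline oracle in integer step units (branch decided exactly at ties)
  oracle <- function(pre, post, da) {
    ps <- round(tr[[pre - 30]] / dt - 0.5)
    ps <- ps[ps + round(da / 1000 / dt) < dur / dt]  # arrival inside the run
    qs <- round(tr[[post]] / dt - 0.5)
    u <- (outer(qs, ps, `-`) - round(da / 1000 / dt)) * dt * 1000
    wt$eta * (wt$w_in * length(ps) + wt$w_out * length(qs)) +
      sum(window_value(wt, u))
  }
  pred <- mapply(oracle, syn$pre, syn$post, syn$d_axonal)
  expect_equal(fin$weight, syn$weight + pred, tolerance = 1e-12)
})

test_that("with uncorrelated drive the mean weight drifts toward the
           homeostatic equilibrium from both sides", {
  drv <- drive_spec(r0 = 20, r1 = 0)
  ins <- generate_oscillatory_trains(150, drv, 6, seed = 2)
  w <- stdp_window(eta = 2e-5)
  for (j0 in c(0.004, 0.011)) {
    m <- build_single_group(n_neurons = 150, n_inputs = 150, k_ff = 100,
                            k_rec = 100, j0 = j0, seed = 3)
    res <- simulate_network(m, ins, 6, plasticity_on = TRUE, stdp = w,
                            seed = 4, record_spikes = FALSE)
    mw <- mean(res$weights[m$synapses$plastic])
    if (j0 < 0.0075) expect_gt(mw, j0) else expect_lt(mw, j0)
  }
})

test_that("population response: pure cosine rate recovers amplitude and peak", {
  dt <- 1e-4
  t <- seq(0, 5 - dt, by = dt)
  fake <- structure(list(pop_rate = 20 + 4 * cos(2 * pi * 50 * t), dt = dt,
                         duration = 5), class = "sim_result")
  pr <- population_response(fake, 50, warmup = 1)
  expect_equal(pr[["amplitude"]], 4, tolerance = 0.01)
  expect_equal(pr[["peak_rate"]], 24, tolerance = 0.1)
  # constant drive: amplitude ~ 0
  flat <- structure(list(pop_rate = rep(20, length(t)), dt = dt,
                         duration = 5), class = "sim_result")
  expect_lt(population_response(flat, 50, warmup = 1)[["amplitude"]], 1e-9)
  expect_error(population_response(flat, 0.1), "cycles")
})

test_that("weight scaling is multiplicative on recurrent synapses only and
           criticality matches the linear-gain prediction", {
  m <- tiny_poisson_net(n = 150, seed = 7)   # k_rec 10, j0 0.0075: gain 0.075
  m2 <- scale_weights(m, 0.5)
  sel <- m$synapses$plastic
  expect_equal(m2$synapses$weight[sel], m$synapses$weight[sel] * 0.5)
  expect_identical(m2$synapses$weight[!sel], m$synapses$weight[!sel])
  expect_identical(scale_weights(m, 1), m)
  expect_equal(sum(scale_weights(m, 0)$synapses$weight[sel]), 0)
  # bisection: runaway at recurrent gain 1 => critical scale ~ 1/0.075
  crit <- find_critical_scale(m, drive_spec(), probe_duration = 1.2,
                              bracket = c(2, 30), tol = 0.5, seed = 3)
  expect_gt(crit, 9)
  expect_lt(crit, 16)
})

test_that("network delay profile measures mean weight per bin", {
  m <- build_single_group(n_neurons = 60, n_inputs = 60, k_ff = 10,
                          k_rec = 20, j0 = 0.006, seed = 8)
  p <- delay_profile_from_network(m, bin_width = 0.5)
  expect_true(all(abs(p$weights - 0.006) < 1e-12))
  # single bin: the overall mean recurrent weight
  p1 <- delay_profile_from_network(m, bin_width = 9)
  expect_equal(p1$weights[1], 0.006, tolerance = 1e-12)
})

test_that("Poisson-network oscillatory response matches the analytic amplitude", {
  m <- build_single_group(n_neurons = 400, n_inputs = 400, k_ff = 100,
                          k_rec = 100, seed = 2)
  prof <- delay_profile_from_network(m)
  ff <- feedforward_spec()
  for (f in c(60, 120, 240)) {
    drv <- drive_spec(f_mod = f)
    ins <- generate_oscillatory_trains(400, drv, 6, seed = f)
    res <- simulate_network(m, ins, 6, seed = f + 1, record_spikes = FALSE)
    sim_amp <- population_response(res, f, warmup = 1)[["amplitude"]]
    g <- profile_gain_ft(prof, f)$z * epsp_ft(m$epsp, f)$z
    ana_amp <- Mod(5 * ff$j_ff * epsp_ft(m$epsp, f)$z / (1 - g))
    expect_lt(abs(sim_amp - ana_amp) / ana_amp, 0.2)
  }
})
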