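drv120 <- drive_spec(f_mod = 120)

test_that("axonal learning term is periodic, vanishes without modulation", {
  d <- seq(1, 9, by = 0.37)
  expect_equal(learning_term_axonal(d, drive_spec(r1 = 0, f_mod = 120)),
               rep(0, length(d)))
  lt <- learning_term_axonal(d, drv120)
  lt_shift <- learning_term_axonal(d + 1000 / 120, drv120)
  expect_equal(lt, lt_shift, tolerance = 1e-12)
})

test_that("learning-term amplitude scales as r1^2 and j_ff^2", {
  amp_of <- function(r1, j_ff) {
    d <- seq(0, 1000 / 120, length.out = 200)
    max(abs(learning_term_axonal(
      d, drive_spec(r0 = 2 * r1 + 1, r1 = r1, f_mod = 120),
      ff = feedforward_spec(j_ff = j_ff))))
  }
  r1s <- c(1, 2, 4, 8)
  sl_r1 <- coef(lm(log(vapply(r1s, amp_of, numeric(1), j_ff = 1)) ~
                     log(r1s)))[2]
  expect_equal(unname(sl_r1), 2, tolerance = 0.01)
  jffs <- c(0.5, 1, 2, 4)
  sl_j <- coef(lm(log(vapply(jffs, function(j) amp_of(4, j),
                             numeric(1))) ~ log(jffs)))[2]
  expect_equal(unname(sl_j), 2, tolerance = 0.01)
})

test_that("closed-form selected delay agrees with the grid argmax", {
  for (f in c(90, 120, 180, 240, 400, 600)) {
    expect_equal(selected_delay(f), selected_delay_grid(f, delay_range = c(0.2, 25)),
                 tolerance = 0.02)
  }
  # strictly decreasing in frequency
  d <- selected_delay(seq(76, 750, by = 2))
  expect_true(all(diff(d) < 0))
  # independent of the EPSP kernel by construction: argmax of the term
  # computed with different kernels coincides
  for (ep in c("slow", "fast")) {
    d_grid <- seq(1, 10, by = 0.01)
    lt <- learning_term_axonal(d_grid, drv120, epsp = epsp_params(ep))
    expect_equal(d_grid[which.max(lt)], selected_delay(120), tolerance = 0.01)
  }
})

test_that("resonant delays enumerate the k/f images inside the range", {
  dd <- resonant_delays(240, delay_range = c(1, 10))
  expect_equal(length(dd), 2)
  expect_equal(diff(dd), 1000 / 240, tolerance = 1e-9)
  expect_equal(dd[1], selected_delay(240))
})

test_that("frequency bounds invert the selected delay and behave monotonically", {
  b <- learnable_frequency_bounds(1, 10)
  expect_equal(selected_delay(b[["f_min"]]), 10, tolerance = 1e-6)
  expect_equal(selected_delay(b[["f_max"]]), 1, tolerance = 1e-6)
  # degenerate range
  b2 <- learnable_frequency_bounds(5, 5.001)
  expect_equal(b2[["f_min"]], b2[["f_max"]], tolerance = 0.5)
  # widening the delay range never shrinks the frequency band
  wide <- learnable_frequency_bounds(0.5, 12)
  expect_lte(wide[["f_min"]], b[["f_min"]])
  expect_gte(wide[["f_max"]], b[["f_max"]])
  expect_error(learnable_frequency_bounds(10, 1), "d_min < d_max")
})

test_that("2D learning term reduces to 1D at zero dendritic delay and is
           invariant along the diagonal", {
  d <- seq(0, 10, by = 0.1)
  expect_identical(learning_term_2d(d, 0, drv120),
                   learning_term_axonal(d, drv120))
  for (delta in c(0.3, 1.1, 2.7)) {
    expect_equal(learning_term_2d(d + delta, delta, drv120),
                 learning_term_2d(d, 0, drv120), tolerance = 1e-12)
  }
})

test_that("2D ridge has slope 1.0", {
  r <- ridge_slope_2d(drv120)
  expect_equal(r$slope, 1.0, tolerance = 0.05)
  expect_gt(nrow(r$ridge), 10)
})

test_that("two-group terms: lag 0 degenerates, groups relabel symmetrically,
           and 60 Hz / 6.5 ms matches the expected geometry", {
  d <- seq(1, 10, by = 0.1)
  dr0 <- two_group_drive_spec(drive_spec(f_mod = 60), t_lag = 0)
  single <- learning_term_axonal(d, dr0$base, epsp = epsp_params("slow"))
  for (k in 1:2) for (l in 1:2) {
    expect_identical(
      two_group_learning_term(k, l, d, dr0, epsp = epsp_params("slow")),
      single)
  }
  dr <- two_group_drive_spec(drive_spec(f_mod = 60), t_lag = 6.5e-3)
  drm <- two_group_drive_spec(drive_spec(f_mod = 60), t_lag = -6.5e-3)
  expect_equal(two_group_learning_term(1, 2, d, dr),
               two_group_learning_term(2, 1, d, drm), tolerance = 1e-12)
  # within-group maxima fall outside 1-10 ms; between-group peaks inside
  within <- two_group_learning_term(1, 1, d, dr, epsp = epsp_params("slow"))
  expect_lt(max(within) / max(abs(within)), 1) # never reaches its global max
  expect_gt(selected_delay(60), 10)
  b21 <- two_group_learning_term(1, 2, d, dr, epsp = epsp_params("slow"))
  b12 <- two_group_learning_term(2, 1, d, dr, epsp = epsp_params("slow"))
  expect_equal(d[which.max(b21)], selected_delay(60) - 6.5, tolerance = 0.1)
  expect_equal(d[which.max(b12)],
               (selected_delay(60) + 6.5) %% (1000 / 60), tolerance = 0.1)
})

test_that("homeostatic equilibrium sits mid-range, is stable, and degenerates
           to the lower bound without per-spike terms", {
  drv <- drive_spec()
  js <- homeostatic_equilibrium(drv, j_max = 0.015)
  expect_gt(js, 0)
  expect_lt(js, 0.015)
  expect_equal(js, 0.0075, tolerance = 1e-6)
  # drift positive below, negative above
  expect_gt(homeostatic_drift(js * 0.9, drv), 0)
  expect_lt(homeostatic_drift(js * 1.1, drv), 0)
  # w_in = w_out = 0 with a net-depressing window: monotone depression
  w0 <- stdp_window(w_in = 0, w_out = 0)
  expect_equal(homeostatic_equilibrium(drv, window = w0, j_max = 0.015), 0)
})

test_that("input correlation spectrum carries the expected line masses", {
  drv <- drive_spec(r0 = 20, r1 = 5, f_mod = 120)
  lines <- input_correlation_lines(drv)
  expect_equal(lines$mass[lines$frequency == 0], 400)
  expect_equal(lines$mass[lines$frequency == 120], 25 / 4)
  expect_equal(input_correlation_ft(drv, 120), input_correlation_ft(drv, -120))
  expect_equal(input_correlation_ft(drv, 57), 0)
  # unmodulated: DC line only
  expect_equal(nrow(input_correlation_lines(drive_spec(r1 = 0))), 1)
  # line mass equals the discrete transform of the sampled correlation
  u <- seq(0, 1 - 1 / 4096, by = 1 / 4096)   # 1 s at 4096 Hz, 120 Hz bin exact
  cu <- input_correlation_fun(drv, u)
  spec <- fft(cu) / length(cu)
  expect_equal(Mod(spec[121]), 25 / 4, tolerance = 1e-8)  # bin 121 = 120 Hz
  expect_error(drive_spec(r0 = 3, r1 = 5), "r1 <= r0")
})

test_that("recurrent correlation reduces to feed-forward filtering and flags
           strong coupling", {
  drv <- drive_spec(f_mod = 120)
  ff <- feedforward_spec()
  prof0 <- flat_delay_profile(0, 0.015)
  lines <- recurrent_correlation_lines(drv, ff, prof0)
  eamp <- epsp_ft(med_epsp, 120)$amplitude
  expect_equal(lines$mass[lines$frequency == 120], 25 / 4 * eamp^2,
               tolerance = 1e-10)
  # r1 = 0: only DC remains
  expect_equal(nrow(recurrent_correlation_lines(drive_spec(r1 = 0), ff, prof0)),
               1)
  over <- flat_delay_profile(0.011, 0.015)  # gain 1.1
  expect_error(recurrent_correlation_lines(drv, ff, over), "weak-coupling")
})

test_that("profile evolution conserves mean, respects bounds, and concentrates
           mass at the resonant delay", {
  js <- 0.0075
  prof <- flat_delay_profile(js, 0.015)
  # duration 0: unchanged
  ev0 <- evolve_profile(prof, drv120, duration = 0)
  expect_identical(ev0$snapshots[[1]]$weights, prof$weights)
  # deviation increment integrates to ~0 each step: mean conserved pre-clipping
  ev <- evolve_profile(prof, drv120, duration = 300, dt_learn = 5)
  fin <- ev$snapshots[[length(ev$snapshots)]]
  expect_equal(mean(fin$weights), js, tolerance = 1e-10)
  # mid run (before bound saturation): peak at the selected delay
  ev1 <- evolve_profile(prof, drv120, duration = 2000, dt_learn = 10)
  mid <- ev1$snapshots[[length(ev1$snapshots)]]
  expect_equal(mid$delay_grid[which.max(mid$weights)], selected_delay(120),
               tolerance = 0.1)
  # long run: bounds respected, surviving band centred on the selected delay
  ev2 <- evolve_profile(prof, drv120, duration = 20000, dt_learn = 10)
  fin2 <- ev2$snapshots[[length(ev2$snapshots)]]
  expect_true(all(fin2$weights >= 0 & fin2$weights <= 0.015))
  band <- fin2$weights > 0.9 * 0.015
  expect_true(any(band))
  centroid <- sum(fin2$delay_grid[band] * fin2$weights[band]) /
    sum(fin2$weights[band])
  expect_equal(centroid, selected_delay(120), tolerance = 0.2)
  expect_error(evolve_profile(prof, drv120, duration = 10, dt_learn = 0),
               "dt_learn")
})

test_that("delay profiles serialise to text and back", {
  prof <- flat_delay_profile(0.004, 0.015)
  prof$weights[3] <- 0.011
  path <- tempfile(fileext = ".tsv")
  write_delay_profile(prof, path)
  back <- read_delay_profile(path)
  expect_equal(back$weights, prof$weights)
  expect_equal(back$delay_grid, prof$delay_grid)
  expect_equal(back$j_max, prof$j_max)
  unlink(path)
})
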