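test_that("cosine sum amplitude equals the phasor modulus", {
  expect_equal(cosine_sum_amplitude(list()), 0)
  expect_equal(cosine_sum_amplitude(rbind(c(1, 0))), 1)
  expect_equal(cosine_sum_amplitude(rbind(c(1, 0), c(1, pi))), 0,
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    comp <- cbind(runif(5, 0, 2), runif(5, -pi, pi))
    theta <- seq(0, 2 * pi, length.out = 2e5)
    grid_max <- max(colSums(comp[, 1] *
                              cos(outer(comp[, 2], theta, `+`))))
    expect_equal(cosine_sum_amplitude(comp), grid_max, tolerance = 1e-6)
  }
  expect_error(cosine_sum_amplitude(rbind(c(-1, 0))), "non-negative")
})

test_that("response amplitude truncates correctly and respects the series
           remainder bound", {
  prof <- gaussian_profile_spec(mu = 6.3, sigma = 0.5, j_rec = 0.3)
  ep <- med_epsp
  # no input oscillation
  expect_equal(response_amplitude(100, prof, r1 = 0), 0)
  # no recurrence: pure feed-forward value
  p0 <- gaussian_profile_spec(mu = 6.3, sigma = 0.5, j_rec = 0)
  f <- c(40, 120, 260)
  expect_equal(response_amplitude(f, p0, epsp = ep),
               5 * epsp_ft(ep, f)$amplitude, tolerance = 1e-12)
  # order-2 truncation error bounded by |G|^3/(1-|G|) relative
  for (f1 in seq(20, 300, by = 40)) {
    full <- response_amplitude(f1, prof, epsp = ep, order = Inf)
    o2 <- response_amplitude(f1, prof, epsp = ep, order = 2)
    g <- prof$j_rec * epsp_ft(ep, f1)$amplitude *
      exp(-2 * pi^2 * (prof$sigma / 1000)^2 * f1^2)
    expect_lte(abs(o2 - full) / full, g^3 / (1 - g) + 1e-12)
  }
  sup <- gaussian_profile_spec(mu = 6.3, sigma = 0.5, j_rec = 1.2)
  expect_error(response_amplitude(5, sup), "super-critical")
})

test_that("peak response frequency: none for slow kernels at high training
           frequency, ordering fast >= medium", {
  w <- stdp_window()
  # slow EPSP, high training frequency: no interior peak
  mu <- selected_delay(240, w)
  expect_true(is.na(peak_response_frequency(
    gaussian_profile_spec(mu, 0.5, 0.5), epsp = epsp_params("slow"),
    f_search = c(10, 500))))
  # very wide profile: transform suppressed, no peak
  expect_true(is.na(peak_response_frequency(
    gaussian_profile_spec(mu, 20, 0.5), epsp = epsp_params("fast"),
    f_search = c(10, 500))))
  # fast kernel peaks at or above the medium kernel's peak
  mu2 <- selected_delay(120, w)
  fr_med <- peak_response_frequency(gaussian_profile_spec(mu2, 0.5, 0.5),
                                    epsp = epsp_params("medium"))
  fr_fast <- peak_response_frequency(gaussian_profile_spec(mu2, 0.5, 0.5),
                                     epsp = epsp_params("fast"))
  expect_false(is.na(fr_med))
  expect_gte(fr_fast, fr_med)
  expect_error(peak_response_frequency(gaussian_profile_spec(mu2, 0.5, 0.5),
                                       f_search = c(-5, 100)), "invalid")
})

test_that("two-group response degenerates, is lag-periodic, and peaks at the
           trained lag", {
  ep <- epsp_params("custom", tau_rise = 1, tau_decay = 3)
  f <- 60
  # zero recurrence: both groups at the feed-forward amplitude, lag-independent
  p0 <- gaussian_profile_spec(5, 0.5, 0)
  for (lag in c(0, 4, 9)) {
    r <- two_group_response(f, lag, list(p0, p0), epsp = ep)
    expect_equal(unname(r[1]), 5 * epsp_ft(ep, f)$amplitude,
                 tolerance = 1e-12)
    expect_equal(unname(r[1]), unname(r[2]), tolerance = 1e-12)
  }
  # trained configuration: mirrored profiles at the trained lag
  t_lag <- 6.5
  d_sel <- selected_delay(f)
  p12 <- gaussian_profile_spec(d_sel - t_lag, 0.5, 0.9)
  p21 <- gaussian_profile_spec((d_sel + t_lag) %% (1000 / f), 0.5, 0.9)
  # periodicity in the lag
  r1 <- two_group_response(f, 2.2, list(p12, p21), epsp = ep)
  r2 <- two_group_response(f, 2.2 + 1000 / f, list(p12, p21), epsp = ep)
  expect_equal(r1, r2, tolerance = 1e-10)
  # the mean amplitude over a lag sweep at f is maximal near the trained lag
  lags <- seq(0, 1000 / f, by = 0.25)
  amps <- vapply(lags, function(l)
    mean(two_group_response(f, l, list(p12, p21), epsp = ep)), numeric(1))
  expect_equal(lags[which.max(amps)] %% (1000 / f), t_lag, tolerance = 1)
})

test_that("two-group response surface is mirror-symmetric in the lag", {
  ep <- epsp_params("custom", tau_rise = 1, tau_decay = 3)
  p12 <- gaussian_profile_spec(4.2, 0.5, 0.6)
  p21 <- gaussian_profile_spec(7.9, 0.5, 0.6)
  s <- two_group_response_surface(c(40, 60, 80), seq(-8, 8, by = 2),
                                  list(p12, p21), epsp = ep)
  s_mirror <- two_group_response_surface(c(40, 60, 80), seq(8, -8, by = -2),
                                         list(p21, p12), epsp = ep)
  expect_equal(s$amplitude, s_mirror$amplitude, tolerance = 1e-10)
})

test_that("critical weight scale is the reciprocal peak gain and the resummed
           response diverges approaching it", {
  ep <- med_epsp
  expect_equal(critical_weight(gaussian_profile_spec(5, 0.5, 0), ep), Inf)
  # gain exactly 1 at DC -> scale 1
  expect_equal(critical_weight(gaussian_profile_spec(5, 0.5, 1), ep), 1,
               tolerance = 1e-12)
  prof <- gaussian_profile_spec(5, 0.5, 0.5)
  sc <- critical_weight(prof, ep)
  expect_equal(sc, 2, tolerance = 1e-12)
  amps <- vapply(c(0.9, 0.99, 0.999), function(s) {
    p <- gaussian_profile_spec(5, 0.5, 0.5 * s * sc)
    response_amplitude(1e-3, p, epsp = ep, order = Inf)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
  expect_gt(amps[3] / amps[1], 50)
})

test_that("gaussian fit recovers the moments of a near-gaussian profile", {
  grid <- seq(1, 10, by = 0.1)
  w0 <- 0.001 + 0.012 * exp(-(grid - 6.3)^2 / (2 * 0.6^2))
  prof <- delay_profile(grid, w0, j_max = 0.015)
  fit <- gaussian_fit_profile(prof)
  expect_equal(fit$mu, 6.3, tolerance = 0.05)
  expect_equal(fit$sigma, 0.6, tolerance = 0.05)
})
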