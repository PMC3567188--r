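# shared tiny fixtures; all randomness under fixed seeds

std_window <- stdp_window()
med_epsp <- epsp_params("medium")

# numerical quadrature of a kernel's ordinary-frequency Fourier transform
quad_ft <- function(fun, f, lower, upper, rel.tol = 1e-12) {
  re <- stats::integrate(function(t) fun(t) * cos(2 * pi * f * t),
                         lower, upper, rel.tol = rel.tol,
                         subdivisions = 2000L)$value
  im <- -stats::integrate(function(t) fun(t) * sin(2 * pi * f * t),
                          lower, upper, rel.tol = rel.tol,
                          subdivisions = 2000L)$value
  complex(real = re, imaginary = im)
}

# composite-Simpson transform oracle for oscillatory integrands: error
# O((2 pi f h)^4), machine-level at h = 1e-6 s for f <= 1 kHz
simpson_ft <- function(fun, f, lower, upper, h = 1e-6) {
  n <- ceiling((upper - lower) / (2 * h))
  x <- seq(lower, upper, length.out = 2 * n + 1)
  y <- fun(x) * exp(-2i * pi * f * x)
  hh <- (upper - lower) / (2 * n)
  w <- c(1, rep(c(4, 2), n - 1), 4, 1)
  sum(w * y) * hh / 3
}

tiny_poisson_net <- function(n = 60, seed = 11) {
  build_single_group(n_neurons = n, n_inputs = n, k_ff = 20, k_rec = 10,
                     j_ff = 1 / 20, seed = seed)
}
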