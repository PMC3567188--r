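#' EPSP kernel parameters
#'
#' Constructs the parameter set of the causal double-exponential excitatory
#' post-synaptic potential (EPSP) kernel
#' \deqn{\varepsilon(t) = \Theta(t)\,\frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\tau_d - \tau_r},}
#' where \eqn{\Theta} is the Heaviside step function, \eqn{\tau_r} the synaptic
#' rise time and \eqn{\tau_d} the decay time. The prefactor normalises the
#' kernel to unit time-integral, so that a synapse of weight \eqn{J}
#' contributes \eqn{J} expected spike-equivalents of drive in the linear
#' Poisson neuron model and \eqn{|\tilde\varepsilon(0)| = 1}.
#'
#' Three named presets are provided: `"slow"` (1/5 ms rise/decay, typical of
#' cortical pyramidal synapses), `"medium"` (0.5/1 ms) and `"fast"`
#' (0.1/0.5 ms, consistent with auditory-brainstem synapses).
#'
#' @param preset one of `"slow"`, `"medium"`, `"fast"`, or `"custom"`.
#' @param tau_rise synaptic rise time in ms; overrides the preset value.
#' @param tau_decay synaptic decay time in ms; overrides the preset value.
#' @return an object of class `epsp_params` with fields `tau_rise`,
#'   `tau_decay` (ms) and `preset_name`.
#' @examples
#' ep <- epsp_params("medium")
#' epsp_value(ep, c(-1, 0.5, 2))
#' @export
epsp_params <- function(preset = c("medium", "slow", "fast", "custom"),
                        tau_rise = NULL, tau_decay = NULL) {
  preset <- match.arg(preset)
  presets <- list(slow = c(1, 5), medium = c(0.5, 1), fast = c(0.1, 0.5))
  if (preset == "custom") {
    if (is.null(tau_rise) || is.null(tau_decay))
      stop("custom EPSP needs tau_rise and tau_decay")
    tr <- tau_rise; td <- tau_decay
  } else {
    tr <- if (is.null(tau_rise)) presets[[preset]][1] else tau_rise
    td <- if (is.null(tau_decay)) presets[[preset]][2] else tau_decay
  }
  if (!is.finite(tr) || !is.finite(td) || tr <= 0 || td <= tr)
    stop("EPSP requires 0 < tau_rise < tau_decay")
  structure(list(tau_rise = tr, tau_decay = td, preset_name = preset),
            class = "epsp_params")
}

#' @export
print.epsp_params <- function(x, ...) {
  cat(sprintf("EPSP kernel ('%s'): rise %g ms, decay %g ms, unit area\n",
              x$preset_name, x$tau_rise, x$tau_decay))
  invisible(x)
}

#' Evaluate the EPSP kernel
#'
#' @param params an [epsp_params] object.
#' @param t time in ms (vectorised); the kernel is exactly 0 for `t < 0`.
#' @return kernel values in units of 1/s (the kernel integrates to 1 over
#'   time in seconds).
#' @export
epsp_value <- function(params, t) {
  stopifnot(inherits(params, "epsp_params"))
  if (any(!is.finite(t))) stop("non-finite t")
  tr <- params$tau_rise / 1000
  td <- params$tau_decay / 1000
  ts <- t / 1000
  out <- ifelse(ts < 0, 0, (exp(-ts / td) - exp(-ts / tr)) / (td - tr))
  pmax(out, 0)
}

#' Peak time of the EPSP kernel
#'
#' Closed-form stationary point of the double exponential,
#' \eqn{t^* = \tau_r\tau_d/(\tau_d-\tau_r)\,\log(\tau_d/\tau_r)}.
#'
#' @param params an [epsp_params] object.
#' @return peak time in ms.
#' @export
epsp_peak_time <- function(params) {
  tr <- params$tau_rise; td <- params$tau_decay
  tr * td / (td - tr) * log(td / tr)
}

#' Construct a spectrum value (amplitude and phase of a Fourier transform)
#'
#' Small container for evaluations of Fourier transforms of real kernels:
#' amplitude \eqn{\ge 0} and phase wrapped to \eqn{(-\pi,\pi]}. For a real
#' function the transform satisfies amplitude(-f) = amplitude(f) and
#' phase(-f) = -phase(f). The raw complex value is retained in `z`.
#'
#' @param z complex transform values.
#' @param f the frequencies (Hz) at which `z` was evaluated.
#' @return an object of class `spectrum_value` with vector fields
#'   `frequency`, `amplitude`, `phase`, `z`.
#' @export
spectrum_value <- function(z, f = NA_real_) {
  structure(list(frequency = f, amplitude = Mod(z), phase = Arg(z), z = z),
            class = "spectrum_value")
}

#' @export
print.spectrum_value <- function(x, ...) {
  n <- length(x$z)
  cat(sprintf("spectrum_value: %d frequencies\n", n))
  print(utils::head(data.frame(frequency = x$frequency,
                               amplitude = x$amplitude, phase = x$phase), 6))
  if (n > 6) cat("...\n")
  invisible(x)
}

#' Fourier transform of the EPSP kernel (closed form)
#'
#' With the ordinary-frequency convention
#' \eqn{\tilde\varepsilon(f) = \int \varepsilon(t)e^{-2\pi i f t}\,dt}, the
#' unit-area double exponential has the exact transform
#' \deqn{\tilde\varepsilon(f) = \frac{1}{(1 + 2\pi i f\tau_d)(1 + 2\pi i f\tau_r)},}
#' so its amplitude is \eqn{[(1+\omega^2\tau_d^2)(1+\omega^2\tau_r^2)]^{-1/2}}
#' (monotonically decreasing in \eqn{|f|}; slower kernels attenuate high
#' frequencies more) and its phase is
#' \eqn{-\arctan(\omega\tau_d)-\arctan(\omega\tau_r)} with \eqn{\omega=2\pi f}.
#'
#' @param params an [epsp_params] object.
#' @param f frequency in Hz (vectorised).
#' @return a [spectrum_value].
#' @export
epsp_ft <- function(params, f) {
  stopifnot(inherits(params, "epsp_params"))
  tr <- params$tau_rise / 1000
  td <- params$tau_decay / 1000
  w <- 2i * pi * f
  spectrum_value(1 / ((1 + w * td) * (1 + w * tr)), f)
}

#' STDP learning window parameters
#'
#' Constructs the parameter set of the bimodal exponential learning window
#' of additive STDP,
#' \deqn{W(u) = \eta\,c_p\,e^{-u/\tau_p} \quad (u \ge 0), \qquad
#'       W(u) = -\eta\,c_d\,e^{u/\tau_{dep}} \quad (u < 0),}
#' where \eqn{u} is the post-minus-pre spike-time difference measured at the
#' synapse: pre-before-post pairings (\eqn{u > 0}) potentiate, post-before-pre
#' pairings depress. `c_pot`/`c_dep` are the branch peak amplitudes and
#' `eta` is a small learning rate scaling the whole rule (window and
#' per-spike rate terms alike); it sets the speed of learning, never which
#' delays are selected. `w_in`/`w_out` are the per-pre-spike and
#' per-post-spike weight increments of the rate-based part of the rule; the
#' defaults place the homeostatic mean-weight equilibrium mid-range for the
#' default network configuration (see [homeostatic_equilibrium]).
#'
#' The standard window (preset `"standard"`) has potentiation factor 15,
#' depression factor 10 and time constants 17/34 ms, giving a net-depressing
#' window: \eqn{\int W = \eta(c_p\tau_p - c_d\tau_{dep}) < 0}.
#'
#' Exactly simultaneous synaptic events (`u == 0`) take the potentiation
#' branch value (a deterministic convention for a measure-zero case).
#'
#' @param preset `"standard"` or `"custom"`.
#' @param c_pot,c_dep dimensionless branch amplitudes (>= 0).
#' @param tau_pot,tau_dep branch time constants in ms (> 0).
#' @param eta learning rate per pairing (dimensionless).
#' @param w_in,w_out per-spike rate terms (pre/post), in window units.
#' @return an object of class `stdp_window`.
#' @examples
#' w <- stdp_window()
#' window_value(w, c(-34, 0, 17))
#' @export
stdp_window <- function(preset = c("standard", "custom"),
                        c_pot = 15, c_dep = 10,
                        tau_pot = 17, tau_dep = 34,
                        eta = 5e-6, w_in = 7.8, w_out = -1) {
  preset <- match.arg(preset)
  if (tau_pot <= 0 || tau_dep <= 0) stop("time constants must be positive")
  if (c_pot < 0 || c_dep < 0) stop("window factors must be non-negative")
  structure(list(c_pot = c_pot, c_dep = c_dep,
                 tau_pot = tau_pot, tau_dep = tau_dep,
                 eta = eta, w_in = w_in, w_out = w_out,
                 preset_name = preset),
            class = "stdp_window")
}

#' @export
print.stdp_window <- function(x, ...) {
  cat(sprintf(
    "STDP window ('%s'): c_pot %g, c_dep %g, tau_pot %g ms, tau_dep %g ms\n",
    x$preset_name, x$c_pot, x$c_dep, x$tau_pot, x$tau_dep))
  cat(sprintf("  eta %g, w_in %g, w_out %g, integral %g (x eta, s)\n",
              x$eta, x$w_in, x$w_out,
              (x$c_pot * x$tau_pot - x$c_dep * x$tau_dep) / 1000))
  invisible(x)
}

#' Evaluate the STDP learning window
#'
#' @param params an [stdp_window] object.
#' @param u synaptic spike-time difference (post minus pre) in ms
#'   (vectorised).
#' @return weight change per pairing (dimensionless, includes `eta`).
#' @export
window_value <- function(params, u) {
  stopifnot(inherits(params, "stdp_window"))
  if (any(!is.finite(u))) stop("non-finite u")
  params$eta * ifelse(u >= 0,
                      params$c_pot * exp(-u / params$tau_pot),
                      -params$c_dep * exp(u / params$tau_dep))
}

#' Time integral of the STDP window
#'
#' \eqn{\int W(u)\,du = \eta(c_p\tau_p - c_d\tau_{dep})} in seconds; negative
#' for the standard (net-depressing) window.
#'
#' @param params an [stdp_window] object.
#' @return the integral, in units of weight times seconds.
#' @export
window_integral <- function(params) {
  params$eta *
    (params$c_pot * params$tau_pot - params$c_dep * params$tau_dep) / 1000
}

#' Fourier transform of the STDP window (closed form)
#'
#' \deqn{\tilde W(f) = \eta\left[\frac{c_p\tau_p}{1 + 2\pi i f\tau_p}
#'   - \frac{c_d\tau_{dep}}{1 - 2\pi i f\tau_{dep}}\right].}
#' Its phase at the input modulation frequency sets which conduction delays
#' resonate with the oscillation and are therefore potentiated (see
#' [selected_delay]).
#'
#' @param params an [stdp_window] object.
#' @param f frequency in Hz (vectorised).
#' @return a [spectrum_value].
#' @export
window_ft <- function(params, f) {
  stopifnot(inherits(params, "stdp_window"))
  tp <- params$tau_pot / 1000
  td <- params$tau_dep / 1000
  w <- 2i * pi * f
  z <- params$eta *
    (params$c_pot * tp / (1 + w * tp) - params$c_dep * td / (1 - w * td))
  spectrum_value(z, f)
}

# resolve a kernel given either a params object or a preset name (used by
# the configuration layer)
resolve_epsp <- function(x) {
  if (inherits(x, "epsp_params")) return(x)
  if (is.character(x)) return(epsp_params(x))
  if (is.list(x)) return(do.call(epsp_params, x))
  stop("cannot interpret EPSP specification")
}

resolve_window <- function(x) {
  if (inherits(x, "stdp_window")) return(x)
  if (is.null(x)) return(stdp_window())
  if (is.character(x)) {
    if (x %in% c("standard", "standard-window")) return(stdp_window())
    stop("unknown window preset: ", x)
  }
  if (is.list(x)) return(do.call(stdp_window, x))
  stop("cannot interpret STDP window specification")
}
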