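---
title: "Delay selection by STDP under oscillatory drive: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay selection by STDP under oscillatory drive: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdpdelay)
```

## The model

`stdpdelay` studies a recurrent network of excitatory neurons driven by a
population of Poisson spike trains whose common intensity is sinusoidally
modulated,

$$r(t) = r_0 + r_1 \cos\!\big(2\pi f_{mod}(t - t_0)\big),$$

with mean rate $r_0$ (spikes/s), modulation amplitude $r_1$ and modulation
frequency $f_{mod}$. Each neuron receives $k_{ff}$ feed-forward synapses
(fixed weight, common axonal delay $d_{in}$) and $k_{rec}$ recurrent
synapses from other network neurons. Recurrent synapses carry axonal
delays sampled uniformly from a range (1–10 ms by default) and are the
only plastic elements.

Two neuron models are used. The analytic half works with the **linear
Poisson neuron**: an inhomogeneous Poisson process whose intensity is the
delayed, weighted sum of unit-area EPSP kernels

$$\varepsilon(t) = \Theta(t)\,\frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\tau_d - \tau_r},$$

with rise/decay presets `slow` (1/5 ms), `medium` (0.5/1 ms) and `fast`
(0.1/0.5 ms). Simulations additionally support the **leaky
integrate-and-fire (LIF) neuron** (threshold −50 mV, rest/reset −65 mV,
excitatory reversal 0 mV, 1 ms absolute refractory period, membrane
constants 20/10/5 ms paired with the three kernels).

Plasticity is **additive STDP**: each (pre, post) spike pair, evaluated at
the synapse (pre somatic time + axonal delay $d_a$; post somatic time +
dendritic delay $d_d$), changes the weight by the bimodal exponential
window

$$W(u) = \eta\,c_p e^{-u/\tau_p}\ (u \ge 0), \qquad
  W(u) = -\eta\,c_d e^{u/\tau_{dep}}\ (u < 0),$$

with $c_p = 15$, $c_d = 10$, $\tau_p = 17$ ms, $\tau_{dep} = 34$ ms, plus
per-spike rate increments $w_{in}$ (each pre spike) and $w_{out}$ (each
post spike). Weights are clipped to $[0, J_{max}]$ after every update.

### Normalisation choices

The EPSP prefactor $1/(\tau_d - \tau_r)$ makes the kernel integrate to 1
over time, so $|\tilde\varepsilon(0)| = 1$ and a weight of $J$ contributes
$J$ expected spike-equivalents of drive. This keeps the rate equations
dimensionally transparent and reproduces the expected amplitude ordering
of the three kernels at high frequency. The window factors 15/10 are
interpreted as branch peak amplitudes; the learning rate $\eta$ scales the
window *and* both rate terms. $\eta$ sets only the speed of learning — the
selected delays depend on the window shape alone — and defaults to
$5\times10^{-6}$, which makes the analytic profile evolution form its
selected band on the $\sim$5000 s timescale of the reference training
protocol. Exactly simultaneous synaptic events take the potentiation
branch (a deterministic convention for a measure-zero case).

## Fourier-domain learning theory

Because all inputs share one modulated rate, any pair of network neurons
has (to first order in the recurrent coupling) the oscillatory pair
correlation

$$C_{osc}(u) = \tfrac{r_1^2}{2} J_{ff}^2\,
  |\tilde\varepsilon(f_{mod})|^2 \cos(2\pi f_{mod} u),$$

where $J_{ff}$ is the total feed-forward gain — the EPSP phases of the pre
and the post pathway cancel in the correlation. Convolving this with the
learning window shifted by the axonal delay gives the correlation-driven
drift of the mean weight at delay $d$:

$$\dot J_{dev}(d) \propto \tfrac{r_1^2}{2} J_{ff}^2
  |\tilde\varepsilon(f)|^2\,|\tilde W(f)|
  \cos\!\big(2\pi f d - \phi_W(f)\big),$$

an $f_{mod}$-periodic function of $d$ whose peak positions depend only on
the *phase* of the window transform,

$$\tilde W(f) = \eta\left[\frac{c_p\tau_p}{1 + 2\pi i f \tau_p}
  - \frac{c_d\tau_{dep}}{1 - 2\pi i f \tau_{dep}}\right].$$

The shortest resonant delay is therefore

$$d^*(f) = \frac{\phi_W(f) \bmod 2\pi}{2\pi f},$$

implemented in `selected_delay()` and cross-checked by the grid argmax in
`selected_delay_grid()` (0.1 ms grid, quadratic peak refinement — the
resolution at which selected delays are reported). Inverting $d^*$ at the
ends of the delay range (`learnable_frequency_bounds()`) gives the
learnable band: for 1–10 ms and the standard window, about 76–750 Hz.

```{r}
selected_delay(240)                 # ms; the 240 Hz resonant delay
learnable_frequency_bounds(1, 10)   # Hz
```

With dendritic delays the pairing argument shifts by $d_d - d_a$, so the
2D learning term is `learning_term_axonal` evaluated at $d_a - d_d$: its
potentiation ridges are lines of slope 1.0 in the (dendritic, axonal)
plane (`ridge_slope_2d()`), meaning frequency no longer maps one-to-one
onto total delay — the reason short dendritic delays are required for
frequency-selective responses.

For two groups whose drives differ by a lag $T_{lag}$, the between-group
correlations are shifted by $\pm T_{lag}$, so connections from the lagging
into the leading group select $d^* - T_{lag}$ and the reverse direction
$d^* + T_{lag}$ (modulo the period), while within-group terms keep their
single-group form — at 60 Hz with a 6.5 ms lag the within-group optimum
(12.7 ms) falls outside a 1–10 ms delay range, so within-group weights are
driven to the lower bound while both between-group classes peak inside
the range.

### Homeostasis and profile evolution

The rate-based terms drive the *mean* recurrent weight to the fixed point
of $(w_{in} + w_{out})\nu + \nu^2 \int W = 0$ with
$\nu(J_{av}) = J_{ff} r_0/(1 - k_{rec} J_{av})$. The defaults
($w_{in} = 7.8$, $w_{out} = -1$, $J_{max} = 0.015$, $k_{rec} = 100$,
$r_0 = 20$ spikes/s) place this equilibrium at $J^* = J_{max}/2$, i.e.
mid-range, with the stationary rate at 80 spikes/s; stability follows
because the net-depressing window term grows faster than the linear
per-spike terms. $r_1$ defaults to 5 spikes/s (the modulation depth of
the reference protocols); $r_0$ is chosen inside the range where both
potentiation and depression are active.

`evolve_profile()` integrates the deviation dynamics about this mean by
forward Euler: each step adds the zero-mean increment
$\Delta t\,(LT(d) - \overline{LT})$ and clips to $[0, J_{max}]$. The mean
is therefore conserved exactly until the bounds engage; afterwards mass
concentrates on the resonant delays (all $+k/f$ images equally — the
winner-take-shortest effect seen in spiking simulations is a property of
the nonlinear network, not of the linearised theory).

## Response theory

After learning, the recurrent connectivity is summarised as a Gaussian
profile over total delay (mean $\mu$, width $\sigma$, total gain
$J_{rec}$), fitted to measured profiles by moment matching of the weight
mass above baseline. The oscillatory component of the population rate
obeys $\hat\nu = F + G\hat\nu$ with feed-forward phasor
$F = r_1 J_{ff} \tilde\varepsilon(f) e^{-2\pi i f d_{in}}$ and loop gain
$G = J_{rec}\tilde\varepsilon(f)\,e^{-2\pi^2\sigma^2 f^2} e^{-2\pi i f\mu}$.
`response_amplitude()` evaluates the second-order expansion
$|F||1 + G + G^2|$ (the full geometric resummation is available as an
internal oracle; the truncation error is bounded by $|G|^3/(1-|G|)$).
`peak_response_frequency()` scans a 1 Hz grid above a 10 Hz cutoff (the
0 Hz peak is always present and excluded; the cutoff value is our choice)
and refines the dominant interior maximum by golden-section search
(the truncated series can show a shallow spurious ripple near the
anti-resonance that the full resummation lacks; the dominant peak tracks
the genuine resonance), returning `NA` when no interior peak exists —
the typical outcome for the slow kernel at high training frequencies. The two-group analogue combines
the feed-forward phasors of the two groups with the between-group loop
gains (`two_group_response()`), the sum evaluated by the phasor identity
in `cosine_sum_amplitude()`.

`critical_weight()` returns the weight scale at which the linear loop
gain reaches 1 at any frequency; for the spiking network
`find_critical_scale()` instead bisects on the operational runaway
criterion (population rate above 10× the input rate sustained for
100 ms — the multiplier and window are documented constants of this
package). LIF networks reach instability at much smaller weight scales
than the linear theory predicts because their supra-threshold gain curve
is steep; trained networks are probed at 0.99 of the measured critical
scale.

## Synthetic inputs

`generate_oscillatory_trains()` samples each source independently by
thinning against the homogeneous bound $r_0 + r_1$ — exact,
$O(\text{expected spikes})$, and seeded per source so any single train
can be regenerated in isolation. The generator reproduces exactly the
input statistics the theory assumes: a shared sinusoidal rate, rate-only
pair correlations $r_0^2 + (r_1^2/2)\cos(2\pi f u)$, and no
higher-than-second-order correlations (checked empirically via the
third-order cumulant). It does *not* emulate features of biological
inputs such as refractoriness, adaptation, non-sinusoidal waveforms or
heterogeneous rates, so passing tests validate the model's internal
consistency, not its fit to recorded data.

`estimate_correlogram()` gives the unbiased pair-averaged correlation
density in rate-product units with boundary correction
(duration − |lag|); the autocorrelation's zero-lag delta mass is reported
separately from the smooth part.

## The spiking simulator

`simulate_network()` steps both neuron models at `dt` = 0.1 ms (delays
live on a circular delay-line buffer as integer multiples of `dt`; the
reported delay resolution is also 0.1 ms). The double-exponential synaptic
drive is computed by two exponential state variables per neuron, and a
pre-synaptic spike is delivered once to the synapse (somatic time +
axonal delay, where STDP pairing happens) and once to the post soma
(+ dendritic delay, where it contributes drive).

Online STDP uses two exponential somatic-spike traces per neuron plus a
short recent-spike list that corrects the trace for pairs whose
synaptic-time order differs from their somatic-time order. For
$d_d \le d_a$ (all built networks; the default is $d_d = 0$) this
reproduces exact all-to-all pairing — the test suite verifies bit-level
agreement with an offline pairing oracle. For $d_d > d_a$ the rare pairs
that flip order inside the $|d_a - d_d|$ window are omitted; this is a
stated approximation.

The Poisson kind emits a spike with probability $\nu\,dt$ and warns if
that probability ever exceeds 0.1. The LIF kind uses an Euler update with
conductance-style drive toward the excitatory reversal and an absolute
refractory clamp. The weight-to-conductance gain is not a printed
constant of the model; it is calibrated (`calibrate_lif_gain()`) by the
stated rule that without recurrence the output rate approximately equals
the input rate.

## Problem sizes and numerical choices

The reference protocols (10,000 LIF neurons, 20,000 s of learning) are
summarised by the `"paper"` preset of `experiment_config()`. All tests
and the acceptance pipeline use the `"desk"` preset — networks of
60–1,000 neurons (250/group for two-group runs), training durations of
3–240 s with learning rates raised accordingly, and response tests of a
few seconds per frequency — sizes we chose so the full suite runs on a
single CPU while each qualitative result survives.

Two empirical regimes matter when scaling down:

* **Drift vs diffusion.** Per-event STDP increments make each weight
  diffuse; the oscillatory drift is visible in the delay profile only
  when the accumulated diffusion stays small against the bounds. The
  signal-to-noise ratio of the binned deviation profile grows as
  $\sqrt{T}$ and with the synapse count per bin but is independent of
  $\eta$, and falls with the stationary rate (trace amplitudes scale with
  $\nu$). The learning-agreement property is therefore run at reduced
  recurrent gain (stationary rate ≈ 30 spikes/s, with $w_{in}$ rebalanced
  to hold that rate), 1,000 neurons, 240 s and 1 ms profile bins.
* **LIF susceptibility.** The supra-threshold LIF gain curve is steep, so
  spiking networks turn unstable at recurrent weight scales far below the
  linear-theory critical gain. LIF protocols therefore locate the
  critical scale by simulation and operate relative to it, and the
  two-group training run uses a reduced weight ceiling so that a fully
  potentiated between-group pathway remains simulable.

Other numerical choices: delay grids at 0.1 ms with quadratic peak
interpolation; learning-term plots and tables normalised to unit peak
(the absolute scale is arbitrary — it folds $\eta$ and the drive
strength); bisection tolerances of 1e−10 Hz for the frequency-bound
inversion and 0.02–0.005 for critical-scale searches; thinning candidates
deduplicated to keep spike times strictly increasing; profile bins with
no synapses reported as missing and treated as zero mass.

## Known limitations

* The learning theory is first order in the recurrent coupling; at gains
  close to 1 the predicted correlation amplitude underestimates the
  simulated one (the full resummation is available for responses only).
* The response theory has no membrane time constant, so LIF peak response
  frequencies sit below the Poisson-model prediction; LIF response claims
  are made relative to simulation, not to the closed form.
* Only excitatory neurons and mean-driven regimes are modelled — no
  inhibition, no fluctuation-driven balanced state, no conductance
  saturation, no weight-dependent or triplet STDP.
* Within-group depression in the two-group protocol relies on the global
  weight competition; its speed at desk scale is set by the raised
  learning rate, not by the (unprinted) rates of the reference runs.
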