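# stdpdelay

Delay selection by spike-timing-dependent plasticity (STDP) in recurrent
networks driven by oscillatory inputs — analytical theory plus spiking
simulation.

## The problem

Networks in the auditory brainstem and cortex receive spike trains whose
instantaneous rate oscillates (100–300 Hz modulation frequencies for
pitch; gamma-band for cortical rhythms). `stdpdelay` implements a model
of how additive STDP, acting on the recurrent connections of such a
network, *selects conduction delays*: synapses whose axonal delay
resonates with the input modulation period are potentiated, all others
are depressed, and the trained network afterwards responds selectively
to the frequency (and, with two neuron groups, to the phase lag) it was
trained on.

The package is aimed at computational neuroscientists who want to

* predict which delays STDP selects for a given learning window and
  modulation frequency (closed-form, Fourier-domain);
* evolve weighted delay profiles (1D axonal, 2D axonal × dendritic,
  two-group) under the correlation-driven learning dynamics;
* simulate the full spiking counterpart — Poisson or leaky
  integrate-and-fire (LIF) neurons with per-synapse conduction delays and
  online additive STDP — and measure learned delay profiles, oscillatory
  response curves and criticality.

## The core result

For the bimodal exponential learning window
W(u) = η c_p e^(−u/τ_p) for u ≥ 0, −η c_d e^(u/τ_dep) for u < 0
(c_p = 15, c_d = 10, τ_p = 17 ms, τ_dep = 34 ms), the correlation-driven
weight drift of a recurrent connection with axonal delay d under input
modulation at frequency f is proportional to

    |ε̃(f)|² |W̃(f)| cos(2π f d − φ_W(f)),

where ε̃ is the EPSP kernel transform and φ_W the phase of the window
transform. The shortest resonant (selected) delay is therefore

    d*(f) = (φ_W(f) mod 2π) / (2π f),

independent of the EPSP kernel. Inverted at the ends of a 1–10 ms delay
range this gives a learnable band of roughly 76–750 Hz.

## Worked example

```r
library(stdpdelay)

selected_delay(240)            # delay selected by 240 Hz drive
#> [1] 3.135336                # ms -> reported as 3.1 ms

learnable_frequency_bounds(1, 10)
#>     f_min     f_max
#>  75.77786 750.79375          # Hz: the 1-10 ms range learns ~76-750 Hz

# evolve a flat delay profile under 120 Hz drive for 5000 s
prof <- flat_delay_profile(0.0075, j_max = 0.015)
ev   <- evolve_profile(prof, drive_spec(f_mod = 120), duration = 5000)
fin  <- ev$snapshots[[length(ev$snapshots)]]
fin$delay_grid[which.max(fin$weights)]
#> [1] 6.3                     # ms, = selected_delay(120) to the grid

# post-learning response curve of the trained profile
g <- gaussian_profile_spec(mu = selected_delay(120), sigma = 0.5,
                           j_rec = 0.5)
peak_response_frequency(g, epsp = epsp_params("medium"))
#> [1] 124.2958                # Hz: the trained network's response peak
                              # sits just above the training frequency
```

The numbers mean: a network whose recurrent delays span 1–10 ms can
encode modulation frequencies between about 76 and 750 Hz; trained at
240 Hz it concentrates weight at 3.1 ms; trained at 120 Hz at 6.3 ms;
and the trained network's oscillatory response peaks near (but not
exactly at) the training frequency, the offset depending on the EPSP
kernel.

A spiking run end-to-end:

```r
cfg <- experiment_config(list(kind = "train", kernel = "medium",
                              drive = list(f_mod = 120),
                              network = list(n_neurons = 500),
                              train = list(duration = 100)))
out <- run_training(cfg)      # Poisson network, online STDP
print(out$profile)            # learned axonal delay profile
```

A command-line entry point wrapping the same functions is installed at
`inst/cli/stdpdelay` (subcommands `train`, `respond`, `twogroup`,
`analytic`; see `--help`).

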