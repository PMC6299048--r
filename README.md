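# snnkit

Spiking neural network simulation in R: exact-integration
leaky-integrate-and-fire dynamics, sparse synaptic connectivity
structures, constant-time connectivity samplers, and trace-based
spike-timing-dependent plasticity (STDP), together with builders for two
classic benchmark networks and the spike-train statistics used to
validate them.

The package is a CPU reference implementation of the algorithm family
behind modern GPU spiking-network simulators. It is aimed at
computational neuroscientists and simulator developers who need a
transparent, testable implementation of these algorithms: every fast
path (a compiled time-stepping engine) is mirrored by a pure-R
composition of exported primitives, and every constant-time sampler is
tested against a brute-force oracle.

## The models

**Dynamics.** Current-based LIF neurons,

    tau_m dV/dt = -(V - V_rest) + R_m I,

advanced with the exact solution of each linear ODE per timestep
(membrane and synapse filters solved separately, giving a fixed
one-timestep delivery latency); exponential or alpha-kernel synaptic
current filters; Poisson background drive sampled with the
product-of-uniforms method; integer-timestep refractoriness and
dendritic delays realised with per-population ring buffers.

**Connectivity.** Padded ragged matrices with per-synapse weights and
delays; one-bit-per-pair bitmask matrices for constant-weight
projections (`bitmask_bytes(90000, 22500)` is 241 MiB — the reason this
structure exists); a post-major column view for plasticity. Fixed-total
connectivity is realised by a multinomial row partition plus streaming
sorted target sampling through uniform order statistics;
fixed-probability connectivity by geometric skip sampling. All samplers
produce each synapse in constant time.

**Plasticity.** Power-law weight-dependent STDP with all-to-all spike
pairing,

    dw+ = lambda w0^(1-mu) w^mu exp(-dt/tau)   (potentiation)
    dw- = -lambda alpha w exp(-|dt|/tau)       (depression)

computed in constant time per spike via per-neuron traces, with an
all-pairs oracle used to verify exact equivalence.

**Benchmarks.** `build_microcircuit()` builds the eight-population
layered cortical microcircuit (77,169 neurons, ~0.3e9 synapses at full
scale) with principled downscaling (`downscale()`: in-degree scaling
with 1/sqrt(K) weight compensation and DC mean restoration, or
in-degree-preserving scaling). `build_balanced_network()` builds the
plastic balanced random network (90,000 excitatory + 22,500 inhibitory
neurons, STDP on the excitatory-to-excitatory projection).
`firing_rates()`, `cv_isi_set()`, `binned_correlations()`,
`fd_bin_edges()`, `kde_distribution()`, `kl_divergence()` and
`fano_factor()` implement the validation statistics.

## Worked example

Simulate the microcircuit at a tenth of full scale for 3 s of biological
time and summarise the activity after discarding the 1 s transient:

```r
library(snnkit)

spec <- build_microcircuit(scale_config(0.1), duration = 3000)
net  <- realize_network(spec, seed = 1)
res  <- simulate_network(net)
glance(res)
#> # A tibble: 1 × 5
#>   duration_ms dt_ms n_neurons n_spikes mean_rate_hz
#>         <dbl> <dbl>     <int>    <int>        <dbl>
#> 1        3000   0.1      7717    75736         3.27

trains <- as_spike_train_set(res, t_start = 1000)
summarise_spike_trains(trains)
#> # A tibble: 8 × 4
#>   population mean_rate active mean_cv_isi
#>   <chr>          <dbl>  <int>       <dbl>
#> 1 L23e           0.686   1214       0.593
#> 2 L23i           2.84     553       0.673
#> 3 L4e            4.52    2153       0.712
#> 4 L4i            5.93     546       0.723
#> 5 L5e            7.85     481       0.709
#> 6 L5i            8.95     106       0.701
#> 7 L6e            1.16    1018       0.643
#> 8 L6i            8.51     295       0.698
```

The 7,717 neurons fire at population rates between ~0.7 Hz (L2/3e) and
~9 Hz (L5i) with interspike-interval CVs well away from zero — the
asynchronous-irregular regime the downscaling compensation is designed
to preserve (per-population rates track the published full-scale values
because the lost mean input is restored as DC current and weight
variance is kept invariant). `tidy(res)` returns the raw spike raster
as a tibble, `autoplot(res)` draws it, and `write_raster()` /
`read_raster()` round-trip it through plain text.

A command-line driver is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "snnkit-run", package = "snnkit"))')" \
  --model microcircuit --scale 0.1 --duration 1000 --seed 1 --record-spikes out/
```

## Package layout

* `R/propagators.R`, `R/stimulus.R` — exact propagators and drives
* `R/connectivity.R`, `R/samplers.R`, `R/propagation.R` — structures,
  initialisation samplers, ring-buffer delivery
* `R/plasticity.R` — trace STDP and the all-pairs oracle
* `R/builders.R`, `inst/extdata/*.yaml` — benchmark models and their
  literature-derived configuration
* `R/simulate.R`, `src/engine.cpp` — realization and the compiled
  engine
* `R/analysis.R` — validation statistics
* `vignettes/spiking-network-methods.Rmd` — model semantics, numerical
  choices and design decisions
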