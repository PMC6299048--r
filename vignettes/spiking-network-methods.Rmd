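---
title: "Methods: exact-integration spiking networks, sparse connectivity and trace STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-integration spiking networks, sparse connectivity and trace STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnkit)
```

snnkit is a CPU reference implementation of the algorithm family used by
modern GPU spiking-network simulators: exact-integration current-based
leaky integrate-and-fire (LIF) dynamics, padded row-major ("ragged") and
one-bit-per-pair ("bitmask") sparse connectivity, constant-time
connectivity-initialisation samplers, dendritic-delay ring buffers and
trace-based spike-timing-dependent plasticity (STDP). This vignette
documents the model semantics, the numerical and design choices, and
what the bundled benchmark networks do and do not emulate.

## Neuron and synapse dynamics

Each neuron is a current-based LIF unit,

$$\tau_m \frac{dV_j}{dt} = -(V_j - V_\mathrm{rest}) + R_m I_j,$$

which fires when $V_j \ge V_\mathrm{thresh}$, resets to
$V_\mathrm{reset}$ and is then refractory for
$\mathrm{round}(\tau_\mathrm{ref}/dt)$ whole timesteps, during which the
membrane holds its value and only the countdown advances. Synaptic input
is filtered either by a single exponential,
$\tau_\mathrm{syn}\, dI_j/dt = -I_j + \text{(events)}$, or by an alpha
kernel (two coupled variables with a shared time constant, so a unit
impulse produces a current that peaks at $1/e$ after
$\tau_\mathrm{syn}$).

The membrane and synapse equations are solved *separately*: within one
timestep each filter output is treated as constant while the membrane
equation is advanced by its closed-form solution
$V' = V_\infty + (V - V_\infty)e^{-dt/\tau_m}$ with
$V_\infty = V_\mathrm{rest} + R_m I$, and vice versa. Every update is
therefore the exact propagator of a linear ODE — there is no
discretisation error in the state updates themselves — at the cost of a
fixed one-timestep latency between an event's arrival and its effect on
the membrane. The per-step phase order is:

1. read (and clear) the current ring-buffer slot,
2. add background impulses and update the synapse filter,
3. update the membrane, detect and reset spikes,
4. apply plasticity and deliver this step's spikes into future
   ring-buffer slots.

Spike times are recorded at the detection step as $(t+1)\,dt$, so all
recorded times lie in $(0, \mathrm{duration}]$ on the simulation grid.
The threshold test uses $\ge$; a neuron whose exact update lands
precisely on threshold fires.

The compiled engine (`simulate_network()`) implements exactly these
semantics in double precision; a pure-R loop composed from the exported
primitives (`lif_step()`, `exp_synapse_step()`, `deliver_ragged()`, ...)
serves as the executable specification, and the test suite requires the
two paths to agree to float-roundoff tolerance on deterministic
networks, including networks with plasticity and bitmask projections.

## Background drive

Poisson background input models the summed drive of $n_\mathrm{ext}$
external fibres at rate $\nu_\mathrm{ext}$: each neuron receives a
Poisson count with mean $n_\mathrm{ext}\nu_\mathrm{ext}\,dt$ per step,
multiplied by a population-specific weight, injected *through* the
synaptic filter like any other event. Deviates are drawn with the
product-of-uniforms method (multiply uniforms until the running product
drops below $e^{-\lambda}$), which is exact and fast for the small
per-step means that arise at biological rates; means of 10 or more are
drawn exactly as sums of independent smaller-mean deviates using Poisson
additivity, so no normal approximation is ever involved. DC drive, by
contrast, models a mean current rather than events and is added directly
to the neuron input, bypassing the filter.

## Sparse connectivity structures

Three representations cover the use cases:

* **Ragged matrix** — row-major storage padded to the longest row, with
  parallel per-synapse weight and delay tables. Duplicate (pre, post)
  pairs (multapses) are permitted, which matters because fixed-total
  sampling draws targets with replacement.
* **Bitmask** — one bit per (pre, post) pair for projections whose
  weight and delay are compile-time constants. The flat bitfield is
  rounded up *once* to a whole number of 32-bit words:
  `bitmask_bytes(n_pre, n_post) = 4 ceil(n_pre n_post / 32)`. Per-row
  rounding was considered and rejected; the single flat rounding is what
  the 90,000 x 22,500 projection's 241 MiB figure corresponds to. Bit
  $k$ of word $w$ covers pair index $32w + k$ (little-endian), fixed for
  reproducibility. Converting a ragged matrix with multapses to a
  bitmask is an error, not a silent merge.
* **Column view** — a post-major CSR index into the row-major tables,
  built once per plastic projection so postsynaptic-spike-triggered
  updates can reach their column of synapses; the mapping is checked to
  be a bijection.

Delivery goes through a per-population dendritic-delay ring buffer of
$D_\mathrm{max} \times N_\mathrm{post}$ accumulator slots: a spike at
step $t$ with delay $d$ adds its weight to slot $(t + d) \bmod
D_\mathrm{max}$, and the target population reads (and zeroes) slot $t
\bmod D_\mathrm{max}$ at step $t$. Clearing on read is the single point
that prevents double counting. $D_\mathrm{max}$ is the maximum sampled
delay plus one, rounded up to a power of two for cheap modulo; this is
an implementation convenience, not a semantic requirement. Delays are
clamped to at least one step, which enforces the minimum delivery
latency, and a delay reaching $D_\mathrm{max}$ is a build-time error.

## Constant-time initialisation samplers

Connectivity is specified either by a total synapse count
(`fixed_number_total`) or by a per-pair probability
(`fixed_probability`). Both are realised with samplers whose per-sample
cost is constant, so rows can be generated independently (and, in the
original GPU setting, in parallel):

* **Row partition.** The total $N_\mathrm{syn}$ is split over rows by
  Multinomial($N_\mathrm{syn}$; equal probabilities $1/N_\mathrm{pre}$) —
  the only reading that conserves the total exactly. This step is
  inherently serial and is done once per projection (via `rmultinom`).
* **Row capacity.** Storage is allocated before sampling using the
  smallest $k$ with $P(\mathrm{Binom}(N_\mathrm{syn}, 1/N_\mathrm{pre})
  \le k) \ge 0.9999^{1/N_\mathrm{pre}}$, so the chance that *any* row of
  the matrix overflows is about $10^{-4}$ per network. The Bernoulli
  analogue uses $\mathrm{Binom}(N_\mathrm{post}, p)$.
* **Sorted targets.** Each row's targets are drawn with replacement from
  the discrete uniform, already sorted, by walking successive
  first-order statistics: with $E_i \sim \mathrm{Exp}(1)$, the $i$-th
  ascending uniform order statistic out of $k$ is
  $1 - \exp(-\sum_{j\le i} E_j/(k-j+1))$, each term obtained in constant
  time through the exponential transform of a Beta(1, remaining)
  variable. Continuous samples are discretised as
  $\lfloor u \cdot N_\mathrm{post}\rfloor$, clamped to
  $N_\mathrm{post}-1$. The test suite checks equality in distribution
  against sort-based sampling.
* **Geometric skips.** Bernoulli rows are generated without touching
  non-connected pairs by skipping ahead
  $1 + \lfloor \ln U / \ln(1-p) \rfloor$ positions per connection.
  $p = 0$ yields an empty row by convention; $p$ outside $[0,1]$ is an
  error.

Weights are normal, truncated (clamped at zero) so an excitatory weight
never becomes negative nor an inhibitory one positive; re-drawing
instead of clamping was a genuinely open choice and clamping was chosen
for its determinism and single-pass cost. Delays are normal in ms,
rounded to the nearest step, clamped to one step minimum.

## Trace-based STDP

The plasticity rule is power-law weight-dependent STDP: for a pair with
lag $\Delta t = t_\mathrm{post} - t_\mathrm{pre}$,

$$\Delta w = \begin{cases}
\lambda\, w_0^{1-\mu} w^{\mu}\, e^{-|\Delta t|/\tau} & \Delta t > 0\\
-\lambda\alpha\, w\, e^{-|\Delta t|/\tau} & \Delta t \le 0
\end{cases}$$

with all-to-all pairing. Rather than evaluating pairs, each neuron
carries a trace $s$ obeying $ds/dt = -s/\tau$ with $s \to s + 1$ at its
own spikes; the trace sampled at an opposite-side spike equals the sum
of exponential factors over all preceding spikes, collapsing the
all-pairs update into one constant-time update per spike
(`depress_on_pre()`, `potentiate_on_post()`).

Conventions, enforced identically in the trace path, the compiled
engine, and the brute-force all-pairs oracle:

* traces are sampled *before* the same-step increment, so a spike never
  pairs with itself and two spikes in the same timestep do not pair at
  all (only strictly preceding opposite-side spikes pair);
* within a timestep, depression (presynaptic-spike-triggered) is applied
  before potentiation, mirroring the synapse-then-postsynaptic-learning
  kernel order, and delivery uses the freshly depressed weight;
* pairing uses spike times on the simulation grid; the dendritic delay
  is not added to $\Delta t$ (delay handling inside the rule is not part
  of the model definition, and the grid-time choice keeps the trace and
  oracle formulations exactly equivalent);
* depression is clamped at zero weight. With $\mu > 0$ multiplicative
  depression cannot cross zero on its own; the clamp only engages for
  pathological $\lambda\alpha s > 1$.

The central correctness property — trace-based evolution equals the
all-pairs oracle for arbitrary grid-aligned spike trains — is asserted
in the tests to $10^{-5}$ relative tolerance over 100+ random train
pairs and across additive ($\mu = 0$), intermediate and multiplicative
($\mu = 1$) parameterisations.

## The benchmark networks

### Layered cortical microcircuit

`build_microcircuit()` constructs the standard eight-population model of
1 mm^3 of early sensory cortex: four layers, each with an excitatory and
an inhibitory population, 77,169 neurons in total, fully described by a
bundled YAML config whose population sizes, connection-probability
table, neuron constants, external in-degrees and delay distributions
follow the published description of the source model (Potjans &
Diesmann's tables; provenance is annotated in the file). Excitatory
weights are Normal(0.0878, 0.00878) nA — doubled on the L4e to L2/3e
projection — inhibitory weights Normal(-0.3512, 0.03512) nA, synapses
exponential, drive Poisson at 8 Hz per external fibre. Probabilities are
converted to synapse totals with the pairwise-Bernoulli convention
$N_\mathrm{syn} = \mathrm{round}(\ln(1-p)/\ln(1-1/(N_\mathrm{pre}
N_\mathrm{post})))$ (the source model's convention); a simple product
convention is selectable.

### Downscaling

`downscale()` shrinks the model to a fraction $K$ of its size while
compensating so that spiking statistics are approximately preserved.
Population sizes always scale by $K$. Two modes cover the two readings
of "scaling the connections by $K$":

* `indegree = "scale"` (default): per-neuron in-degrees shrink by $K$
  (synapse totals by $K^2$). All weights are multiplied by
  $K^{-g}$ with $g = 0.5$ by default — i.e. $1/\sqrt{K}$, which keeps
  the *variance* of the summed synaptic input invariant. The Poisson
  background rate scales by $K$ (its weight by $1/\sqrt K$), and the
  mean input lost to these changes, computed from full-scale in-degrees,
  mean weights and bundled literature reference rates, is restored as a
  DC current $(1-\sqrt K)(\mu_\mathrm{rec} + \mu_\mathrm{ext})$. A
  plain proportional weight scaling ($w \propto K$) is sometimes quoted
  for this family of models, but it breaks the variance-preservation
  argument that motivates the compensation in the first place; the
  exponent is therefore configurable, with the variance-preserving
  value as default.
* `indegree = "preserve"`: synapse totals shrink only by $K$, leaving
  per-neuron in-degrees and hence input statistics untouched; no
  compensation is needed. This mode is cheaper statistically but more
  expensive per neuron.

At $K = 1$ both modes are the identity and the DC term is absent. In
scale mode the per-neuron input mean and variance are preserved by
construction, but pairwise correlations are not (they scale like
$1/N$); distributions of correlation coefficients at reduced scale are
therefore systematically wider than at full scale, which is a known,
intended limitation of this compensation family.

### Plastic balanced random network

`build_balanced_network()` constructs a two-population balanced random
network — 90,000 excitatory and 22,500 inhibitory neurons at full scale,
connection probability 0.1, alpha synapses — with power-law STDP
($\mu = 0.4$) on the excitatory-to-excitatory projection and
constant-weight static projections elsewhere (bitmask-representable;
initial weights 0.04561 nA excitatory, -0.22805 nA inhibitory). Rule
and drive constants not fixed by the benchmark description follow the
source model (Morrison, Aertsen & Diesmann) and live in the bundled
config: $\lambda = 0.1$, $\alpha = 0.1$, $\tau = 20$ ms, and a
reference weight $w_0 = 1$ pA chosen so the rule's uncorrelated-balance
fixed point,

$$w^\* = w_0\,\alpha^{-1/(1-\mu)} \approx 46\ \mathrm{pA},$$

coincides with the initial excitatory weight — the source model starts
at its equilibrium, and this fixed point is independent of the firing
rates, which is what makes the weight distribution stationary. The
external drive rate (45,000 events/s per neuron at the excitatory
weight) was fixed once at design time by mean-field reasoning plus short
pilot runs to place the network in an asynchronous-irregular regime near
9 Hz, and is not a tuning knob of the tests.

With `preserve_indegree = TRUE` the builder raises the connection
probability to $\min(1, p/\mathrm{scale})$, preserving as much of the
full-scale in-degree (11,250) as the reduced population allows; the
residual in-degree fraction $k$ is compensated by scaling *every*
weight — static, plastic initial and the rule's $w_0$ alike — by
$1/\sqrt{k}$, the background rate by $k$, its weight by $1/\sqrt k$,
plus the mean-restoring DC term. Scaling $w_0$ along with the weights
keeps the rule's fixed point aligned with the scaled weights, so the
plastic equilibrium is preserved in scaled units; reporting in original
units just divides by $1/\sqrt k$. Note that full in-degree preservation
under a 10,000-neuron cap is arithmetically impossible (it would need
$p > 1$), so "preserve" here means "preserve up to the all-to-all
limit".

## Analysis conventions

The statistics pipeline mirrors standard practice for validating
spiking simulations:

* per-neuron firing rates over an analysis window (the first second of
  each run is conventionally discarded as transient);
* CV ISI with the *population*-SD convention (divide by the number of
  intervals), selectable; neurons with fewer than three spikes are
  undefined and excluded;
* Pearson correlations of 2 ms-binned trains between sampled pairs of
  *active* (>= 1 spike) neurons, with a dedicated sampling seed;
* histogram grids from the Freedman-Diaconis rule
  ($\mathrm{width} = 2\,\mathrm{IQR}\,n^{-1/3}$) computed on the
  *reference* sample and shared by both distributions;
* Gaussian-kernel smoothing with *fixed* bandwidths (0.3 /s for rates,
  0.04 for CV ISI, 0.002 for correlations), evaluated at the bin
  centres of the shared grid and renormalised to unit mass;
* KL divergence $\sum_k p_k \ln(p_k/q_k)$ in nats with the candidate as
  $p$ and the reference as $q$ (direction chosen and documented here;
  the floor $q_k \ge 10^{-12}$ with renormalisation keeps empty
  reference bins finite);
* Fano factor: variance over mean of pooled 3 ms-bin counts from 1,000
  sampled neurons.

## Reproducibility

One root seed expands into labelled substreams — `conn:<projection>`,
`wd:<projection>` (weights/delays), `vinit:<population>`, `poisson` — so
changing the Poisson stream reruns *identical* connectivity under fresh
background noise, which is what the seed-change control experiments
require. Identical seed and config give byte-identical rasters,
connectivity dumps and weight snapshots. The engine uses a counter-based
64-bit generator seeded from the `poisson` substream; everything else is
drawn through R's RNG.

## Problem sizes used by the test suite

The packaged validation runs at desk scale, chosen as the smallest sizes
at which the qualitative regimes of interest are stable:

* microcircuit at $K = 0.1$ (7,717 neurons, ~3M synapses), 10 s of
  biological time, first second discarded; three Poisson-seed replicates
  for the KL seed-change control;
* balanced network proxy at scale 0.0125 with in-degree preservation
  (1,125 + 281 neurons, all-to-all after the $p \le 1$ cap, ~2M
  synapses of which ~1.3M plastic), 200 s of biological time, weight
  statistics sampled every 5 s and the last 50 s of spikes analysed.

Passing these runs demonstrates that the scaled models sit in an
asynchronous-irregular regime with seed-robust statistics and that the
plastic weight distribution is stationary and unimodal. They do *not*
reproduce full-scale quantities that depend on the complete correlation
structure (e.g. the exact weight-distribution moments, CV ISI or Fano
factor of the 112,500-neuron plastic network over 2,000 s) — those
remain full-scale, long-running validations by construction.

## Known limitations

* The engine is double precision; single-precision semantics are not
  emulated, only tolerated by the test tolerances.
* Conductance-based synapses, off-grid ("precise") spike timing,
  voltage-dependent or third-factor plasticity rules, and
  deferred-update STDP schemes are out of scope.
* DC replacement current bypasses the synaptic filter by design (it
  models a mean, not events); filtering it would double-count the
  filter's DC gain.
* Downscaled models preserve single-neuron input statistics, not
  pairwise correlations; conclusions about correlation magnitudes at
  full scale cannot be drawn from scaled runs.
* `fixed_number_total` samples targets with replacement (multapses
  possible), matching the discrete-uniform sampling definition;
  without-replacement variants are not implemented.
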