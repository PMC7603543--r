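---
title: "Modelling cortical synchrony with izhnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical synchrony with izhnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`izhnet` simulates a layered cortical microcircuit of Izhikevich spiking
neurons and measures how strongly its neuronal groups synchronise as the
synaptic coupling is varied. This vignette documents the model, the
parameters that matter, the numerical choices, and the design decisions
taken where the modelling question was genuinely open — together with what
the package's tests do and do not establish.

## 1. Neuron model

Each neuron is the two-variable quadratic model

$$\frac{dv}{dt} = 0.04v^2 + 5v + 140 - u + I, \qquad
  \frac{du}{dt} = a(bv - u),$$

with the algebraic reset $v \leftarrow c$, $u \leftarrow u + d$ whenever
$v > 30$ mV. $v$ is the membrane potential (mV), $u$ a slow recovery
variable providing spike-frequency adaptation and bursting. Five parameter
quadruples give the five cortical firing phenotypes:

```{r}
library(izhnet)
do.call(rbind, lapply(spiking_types(), function(t) {
  p <- phenotype_parameters(t)
  data.frame(type = t, a = p$a, b = p$b, c = p$c, d = p$d)
}))
```

Units: $a$, $b$ are rates per ms, $c$ is in mV, $d$ is the per-spike
increment to $u$. The recovery variable is treated as dimensionless (in
mV-compatible units inside the voltage equation); sources in this model
family annotate $d$ in mixed units, and normalising everything to the
mV/ms convention above is our choice.

**Integration.** Forward Euler with $dt = 0.5$ ms, the established
convention for this model family: the quadratic spike upstroke is so fast
that sub-millisecond accuracy in the upstroke is immaterial once the reset
is algebraic; what matters is subthreshold fidelity, which the test suite
checks against an adaptive-step reference integrator (agreement within
0.5 mV over 10 ms for all five phenotypes). Spike detection uses the strict
test $v > 30$ mV *after* the update; recorded traces clamp the spike sample
to 30 mV so spikes have uniform height, while the reset value is what
enters the next step. Observables are recorded on a fixed 1 ms grid
regardless of `dt` (which must divide 1 ms).

## 2. The circuit

`default_cortex_config()` builds 17 groups — 8 excitatory (pyramidal and
spiny cells, 8000 neurons) and 9 inhibitory (GABAergic non-basket and
basket cells, 2000 neurons), the cortical 80/20 split — each with its
layer, count and phenotype. Excitatory groups signal through AMPA
(layers 2/3 and 4) or NMDA (layer 5/6); inhibitory groups through GABA.
The layer tables mix merged labels (L2/3, L5/6) with single ones (L2, L4,
L6); receptor assignment and noise targeting treat L2 and L3 as members of
L2/3 and L5/6 as reaching L6.

Connectivity is block-random: every ordered pair of groups, including a
group with itself, carries an independent Bernoulli wiring of its neuron
pairs at sparseness 0.1 (the low end of the plausible 0.1–0.2 range;
configurable per connection), with autapses excluded. Each synapse carries
one weight (mV); the sweep experiment overrides all weights with a single
value, which is how the model family treats coupling strength as a single
control parameter.

## 3. Synapses and how they drive the current

Each neuron keeps one conductance variable per receptor class. A
presynaptic spike adds the synapse weight to the target's variable;
between spikes the variable decays as $dg/dt = -g/\tau$, applied in exact
exponential form ($g \leftarrow g e^{-dt/\tau}$), which is unconditionally
stable and exactly composable across steps. Decay constants default to the
standard literature values $\tau_{AMPA} = 5$ ms, $\tau_{NMDA} = 150$ ms,
$\tau_{GABA} = 10$ ms. Initial conductances are uniform on $[0, 1)$,
seeded.

**Coupling of g to the membrane.** How $g$ enters the current term is a
genuine modelling choice — the quantity is stated as a per-spike increment
in mV with no stated conversion into drive. The package's operations expose
the elementary current-based rule
$I_{syn} = g_{AMPA} + g_{NMDA} - g_{GABA}$ (a conductance-based form
$\sum_r g_r(E_r - v)$ is available as a switch). Applied raw, however,
either rule places the default circuit in an unphysical regime: with
roughly a hundred incoming synapses per neuron, weights of 1–100 mV, and
decay times of 5–150 ms, the integrated recurrent drive reaches thousands
of mV/ms and the network locks at the numerical ceiling of one spike per
integration step (2 kHz — beyond any cortical firing rate) for essentially
the whole weight range, erasing all dynamics the sweep is meant to probe.

The engine therefore normalises each neuron's recurrent drive by its
synaptic indegree and applies a dimensionless gain:
$I_{syn,i} = \text{gain} \cdot (g^{(i)}_{AMPA} + g^{(i)}_{NMDA} -
g^{(i)}_{GABA}) / K_i$, with $K_i$ the neuron's incoming synapse count.
Indegree normalisation makes the mean drive per neuron a function of the
mean presynaptic rate and weight but not of network size, so a 1000-neuron
reduction and the full 10,000-neuron circuit operate in the same regime —
a property the reduced replications rely on. The gain (default 1.5) was
calibrated once so that the default circuit crosses its
asynchronous-to-synchronous transition *inside* the 1–100 mV weight
interval the sweep probes, which is where the reference phenomenon places
it; it is not re-tuned per experiment. `synapse_params(scale = "none",
gain = 1)` recovers the raw rule exactly.

Polarity is carried by the receptor, not the weight: weights are
non-negative, GABA subtracts. A three-neuron motif test verifies that
increasing the GABA weight monotonically suppresses a driven target. (At
very large GABA weights the Izhikevich model shows genuine
post-inhibitory rebound — deep hyperpolarisation drags $u$ down and the
quadratic term accelerates the return — so "more inhibition, fewer
spikes" is only guaranteed in the moderate-weight regime the motif test
uses.)

## 4. Thalamic drive

Thalamic populations are not simulated explicitly; their effect enters as
independent zero-mean Gaussian current noise injected each integration
step into every neuron of layers L2/3, L4 and L6, with standard deviation
5 for excitatory and 2 for inhibitory targets — the convention of the
original published recipe for this network family. Whether that drive is
current or conductance is unstated in the sources; current injection is
the simpler choice and interacts identically with both coupling modes. A
constant `bias` term (default 0) can be added for deterministic
characterisation runs. The noise stream is a named substream of the run
seed, drawn per step, and is unaffected by recording options.

## 5. The engine

One step of the engine: (1) assemble $I$ = noise + scaled synaptic
current; (2) advance all neurons one Euler step with reset; (3) decay all
conductances; (4) deliver this step's spikes. Delivery after the state
update gives an implicit one-step (0.5 ms) synaptic delay — a fixed
ordering had to be chosen, and this one keeps a spike from influencing its
own step. Initial conditions are $v = c + \mathcal{U}[0,5)$ mV (jitter
breaks the symmetry of otherwise identical neurons) and $u = bv$. Note a
consequence probed by the tests: phenotypes whose reset potential $c$
equals the *unstable* subthreshold fixed point (FS/CH/LTS at $-50$ mV) can
fire once from the jittered start even without input; quiescence tests
therefore use RS populations, whose start lies in the stable basin.

Recorders: spike raster (exact step times), per-group spike counts per
1 ms bin (conserving raster events exactly), probe traces
($v, u, g_{AMPA}, g_{NMDA}, g_{GABA}$) for the first neuron of each group,
and optionally the full membrane matrix, the substrate of the synchrony
measure. Runs abort with a diagnostic naming the first offending neuron
and time if the state ever becomes non-finite. All CSV output is written
with full 17-digit precision, so identical seeds reproduce files byte for
byte.

## 6. The synchrony measure

For a group of $N$ neurons with membrane traces $v_i(t)$ on the 1 ms grid,

$$\chi^2(N) = \frac{\sigma_V^2}{\frac{1}{N}\sum_{i=1}^N \sigma_{V_i}^2},
\qquad V(t) = \frac{1}{N}\sum_i v_i(t),$$

with $\sigma^2$ the population-style temporal variance (uncentred second
moment minus squared mean; computed internally in centred form for
numerical stability — identical value, guaranteed non-negative). The
measure is 1 for identical traces, $\to 1/N$ for independent ones, and
bounded in $[0,1]$ by the Cauchy–Schwarz inequality. Tests verify the
bound on random matrices, exact agreement with a brute-force double-loop
implementation, and the $1/N$ asymptotics at $N \in \{10, 100\}$,
$T = 10^4$.

Numerical conventions: membrane traces (not spike trains) are the
substrate; spike samples are clamped at 30 mV, which bounds the variance
contribution of spikes; the first 50 ms of each run are discarded as
transient before variances are computed (configurable, default on); and a
group whose traces are all exactly constant has an undefined ratio — it is
reported as $\chi^2 = 0$ with a `degenerate` flag rather than an error, so
sweeps over quiescent configurations complete. The square root $\chi$ is
reported alongside $\chi^2$ since either form may be the quantity of
interest.

## 7. The weight-sweep experiment

`weight_sweep()` overrides every connection weight with each value of the
grid — default $\{1, 11, \dots, 91\}$, reading "1 to 100 in steps of 10"
as starting at the stated lower endpoint; the grid is configurable for the
other reading $\{10, \dots, 100\}$ — runs the engine afresh per weight,
and computes $\chi^2$ per group. Each weight's run derives its seed from
the base seed plus the weight index: reproducible, yet independent across
weights. Full group membership is used for $N$ (at most 2500 neurons per
group).

On the tenth-scale reduction of the default circuit (1000 neurons,
composition preserved) the mean $\chi^2$ across groups rises from the
$\sim 1/N$ floor at weight 1 to $\sim 0.9$ at the top of the grid, with
positive Spearman rank correlation between weight and mean $\chi^2$ —
checked by the acceptance-level test at a fixed seed and observed across
independent seeds during development. The reduction, rather than the full
10,000-neuron circuit, keeps the sweep's ten simulations inside a
practical test-suite budget; indegree normalisation (section 3) is what
licenses reading the reduced result as representative of the full
circuit's regime.

## 8. Hebbian plasticity

The rate-based rule $\Delta w_i = \eta\, x_i\, y$ (presynaptic rate times
postsynaptic rate over the last epoch, scaled by the learning rate) is
implemented as an optional epoch-wise modifier of the synapse weights,
floored at zero, with rates measured in spikes per epoch (the sources
leave the units of $x$ and $y$ open). It is **off by default** and never
active during the sweep experiment: the reference experiments treat
weights as the swept control variable. No decay/forgetting term is
included — none is specified, and adding one would change the rule's
fixed-point structure. Spike-timing-dependent plasticity is out of scope.

## 9. What the synthetic conditions do and do not show

All inputs are generated: there is no recorded cortical data anywhere in
the pipeline. The generator reproduces the *structural* statistics of the
reference circuit (counts, layers, phenotypes, receptor classes, 80/20
balance, Bernoulli connectivity at sparseness 0.1) and a stochastic stand-
in for thalamic drive. It does not emulate conduction delays, distance- or
layer-specific connection probabilities, NMDA voltage dependence,
synaptic depression/facilitation, or structured (oscillatory) thalamic
input. Passing tests therefore establish the internal consistency of the
model and the synchrony phenomenology *of this model class* — not that
real cortex behaves quantitatively like any particular curve. The χ²
values themselves depend on the clamping and transient conventions above;
comparisons should be made within a fixed convention.

## 10. Reproducibility

Every source of randomness — connectivity, initial conditions, noise,
per-weight runs — flows from one user seed through named substreams, so
any component can be reproduced in isolation. Identical configuration and
seed give byte-identical CSV output (tested). Each CLI run writes a
manifest with a key-order-independent configuration hash, the seed, the
package version and the file list.
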