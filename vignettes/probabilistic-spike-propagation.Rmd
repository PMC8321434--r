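---
title: "Probabilistic spike propagation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic spike propagation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeprop)
```

## The model

`spikeprop` simulates feed-forward, rate-coded spiking neural networks of
integrate-and-fire (IF) neurons and studies a stochastic alternative to
conventional spike propagation. Evaluation has three phases per timestep:
spike injection (inputs arrive as Poisson spike trains or as analog currents
integrated by a front-end IF stage), spike propagation (each input spike
updates the membrane potentials of its fan-out), and spike generation (each
neuron adds its bias, fires on a strict threshold crossing `v > v_th`, and
resets). Layers are evaluated layer-major: one layer for all `T` timesteps
before its successor, which maximizes weight reuse and is exact for strictly
feed-forward networks.

Deterministic propagation performs one synaptic update per synapse per
spike: the unit of computational cost, since each update implies two memory
reads (weight, postsynaptic state) and one write. Probabilistic propagation
instead treats the weight as evidence of how *likely* a spike is to cross
the synapse. For a synapse of magnitude $w_{ij}$ inside a synaptic cluster
$b$ with maximum magnitude $w^{max}_{ib}$, one uniform threshold
$r_b \in [0, w^{max}_{ib}]$ is drawn per cluster per spike and the spike
propagates on every synapse with $w_{ij} > r_b$, i.e. with probability
$p_{ij} = w_{ij} / w^{max}_{ib}$, applying the substituted update
$\hat w_{ij} = \pm\, w^{max}_{ib}$ (the sign is the synapse's own). The
per-spike expected potentiation $p_{ij}\,\hat w_{ij} = w_{ij}$ is unbiased,
so over many spikes the rate code averages the randomness out: the
per-synapse average potentiation $\bar M_{ij}$ (total potentiation divided
by presynaptic spike count $C_i$) converges to $w_{ij}$ at the Bernoulli
rate, standard error $\hat w\sqrt{p(1-p)/C_i}$. The package's
`potentiation_ledger()` exposes exactly this diagnostic.

Because cluster magnitudes are stored sorted, the propagated synapses are
always the first $t_p$ ranks, where the *termination point* $t_p$ is the
number of magnitudes strictly above $r_b$. Two realizations are provided:

* **scan** — walk the sorted weights and stop at the first failure
  (early termination; costs one weight read per examined synapse);
* **histogram** — discretize $r_b$ to $K$ thresholds $k\,w^{max}_{ib}/K$,
  $k = 0,\dots,K-1$, and store $t_p$ for each in a per-cluster lookup (the
  complement of a cumulative histogram of the weights). Propagation then
  never fetches weights at all: one table read and one maximum read per
  cluster per spike, plus index/state traffic for the $t_p$ updates.

The discrete threshold set includes 0 so that full propagation is
reachable, and excludes $w^{max}$, whose success probability is zero for
every synapse; consequently a synapse at the cluster maximum propagates
with probability 1 in both schemes, and the discretized per-synapse
probability is $\lceil K p \rceil / K$ — never below the continuous one and
within $1/K$ of it. `K = 1` degenerates to deterministic propagation with
every weight replaced by its cluster maximum.

## Why clusters

Outgoing-weight distributions of trained networks are heavy-tailed: the
per-neuron maximum is typically around five times the median, so
normalizing by the global per-neuron maximum leaves half the synapses with
propagation probabilities below 0.2 and convergence (hence timesteps)
correspondingly slow. Grouping each neuron's outgoing synapses into `B`
contiguous clusters and normalizing within each cluster shields most
synapses from the outlier maximum and skews probabilities upward. `B` is
the cost–fidelity dial: under refining partitions the closed-form expected
updates per spike (`expected_updates()`) is non-decreasing in `B`, and at
one synapse per cluster every probability is 1 and the engine reproduces
the deterministic spike trains bit for bit. The regime this package's
defaults target is `B = 8` with `K = 50` bins.

## The accelerator cost model

Spike propagation is modeled as served by an array of `n_lanes` parallel
lanes (16 by default), each owning a contiguous share of the work: whole
clusters when `B >= n_lanes`, a share of one cluster's rank range when
`B < n_lanes`. Deterministic propagation loads lanes equally; probabilistic
termination points are random, so per-spike lane loads are unequal and
synchronous serving (all lanes finish a spike before the next is
dispatched) accumulates idle bubbles. Asynchronous serving gives each lane
its own queue; with unbounded queues the makespan is the maximum per-lane
total, never exceeding the synchronous makespan and equal to it exactly
when loads are equal. A bounded queue interpolates between the two.
The cycle model is deliberately parametric — one cycle per synaptic update
plus a fixed per-spike dispatch overhead, both configurable — as is the
energy model, a linear form over categorized counters whose defaults weight
memory traffic an order of magnitude above update arithmetic. No physical
units are claimed; the model's purpose is to *express* ratios between
baseline and probabilistic runs, not to reproduce any specific silicon.
`memory_overhead()` prices the probabilistic tables (rank-ordered indices,
termination tables, cluster maxima) against baseline weight storage under
configurable bit widths, optionally sharing tables across the neurons of a
shared-kernel locally connected layer.

Counter conventions: the histogram method charges one termination-table
read and one maximum read per cluster per spike, plus one index read, one
state read and one state write per propagated synapse. The scan method
charges the maximum read (it scales the uniform draw), one weight read per
examined synapse (the `t_p` successes plus the failing one, capped at the
cluster size), and the same per-update traffic.

## Randomness and reproducibility

A single master seed fans out into named substreams — encoding, and one
stream per (phase, layer) — so changing the lane count, cluster count or
reporting options never reshuffles unrelated draws. Within a layer, draws
occur in canonical simulation order (timestep, presynaptic neuron, cluster
index); lane mapping affects only cost accounting, never the draw order,
so simulated results are independent of the scheduling discipline. Given
the network container, the configuration and the seed, every output byte
is reproducible; the command-line `run` subcommand logs the seed and full
configuration into its report.

## Synthetic networks: what they emulate, and what they do not

`generate_network()` draws each neuron's outgoing weights independently;
the default two-point heavy-tail family jitters weights around a median
`m` and plants one outlier at `max_median_ratio * m` (default 5), matching
the per-neuron max/median statistic that motivates clustering. The
lognormal and uniform families are available, with an optional per-neuron
power transform that pins the realized max/median ratio exactly. What the
generator does *not* emulate: trained, task-structured weights. Synthetic
class scores are arbitrary, so "accuracy" is undefined; fidelity is
instead measured as *prediction agreement with the deterministic baseline
on the same stimuli and encoding seed* — the natural offline surrogate,
since the method's accuracy claims are relative to the deterministic run
anyway. Passing trend tests here demonstrates the estimator mechanics
(unbiasedness, discretization bias shrinking as $1/K$, cost monotone in
`B`), not task accuracy on real networks.

Two opposing effects govern agreement as a function of `K`: coarse bins
inflate probabilities (systematic over-propagation with substituted
weights), fine bins approach the continuous scheme whose remaining
disagreement is pure sampling variance that the rate code suppresses as
`T` grows. The shrinking-bias mechanism orders resolutions reliably once
the distortion is a perturbation, i.e. for `K >= 2`; at `K = 1` every
spike propagates on every synapse with the cluster maximum substituted,
which is not a perturbed version of the network but a different
deterministic network altogether, so its agreement with the baseline is
idiosyncratic per network rather than governed by resolution. The
packaged trend study therefore spans `K = 2, 4, 16`. The packaged trend study therefore runs long enough
(`T = 300` timesteps, ensemble-averaged over networks, stimuli and
replicate seeds) for the variance term to be negligible, which is the
regime the method is meant to operate in; at short horizons the variance
term can locally mask the bias trend. The study also uses a single-layer
network, so the input spike stream — and hence the sequence of coupled
threshold draws — is identical across the compared `K` values, removing
between-`K` sampling noise that multi-layer divergence would reintroduce.

## Numerical and design choices

* **Reset rule** — the threshold is compared strictly (`v > v_th`) and the
  default reset subtracts the threshold, preserving residual drive as
  rate-coded conversions expect; reset-to-zero is available by
  configuration. Bias is added every timestep during spike generation,
  after the propagation phase of that timestep.
* **Readout** — argmax of output spike counts, ties broken by larger final
  membrane potential, then by lower neuron index. All three rules are
  deterministic, so reported agreement is well defined.
* **Cluster partition** — contiguous blocks of the ascending postsynaptic
  index range, sizes differing by at most one; sorting within a cluster is
  by magnitude descending with a stable tie-break on ascending index, so
  tables are reproducible. Zero-magnitude synapses are pruned at build
  (they can never propagate); a neuron with fewer synapses than `B` gets
  singleton clusters.
* **Mixed-sign clusters** — the normalizer is the maximum *magnitude*; the
  applied update carries each synapse's own sign.
* **One threshold per cluster per spike** — a single shared threshold
  across clusters would correlate cluster outcomes and break the
  per-cluster variance analysis.
* **Unit normalizer** — `normalizer = "unit"` keeps the plain
  weight-as-probability scheme ($p = w$, $\hat w = 1$, requiring
  magnitudes at most 1). It is the slow-converging baseline against which
  cluster-max normalization is the fix, and is used in the convergence
  studies of the two-source toy network.
* **Container format** — networks round-trip through a single JSON file
  whose numbers are written with 17 significant digits, making the
  round trip exact and repeated saves byte-identical.
* **Degenerate inputs** — empty fan-outs yield inert cluster tables;
  `propagation_probability()` refuses a zero normalizer; spike trains
  validate strict timestep ordering.

## Problem sizes

The shipped tests and studies run at desk scale, chosen so statistical
tolerances are meaningful: convergence ledgers use $10^4$ presynaptic
spikes (4-standard-error bands), update-count estimators $10^5$ draws
(3-standard-error bands), oracle cross-checks 1,000 random clusters up to
64 synapses and 32 bins, equivalence sweeps 100 random networks, and the
bin-resolution trend study 4 networks × 30 stimuli × 2 replicate seeds at
`T = 300`. Benchmark-scale networks (millions of synapses) are out of
scope: no trained models ship with the package, and the claims that depend
on trained weight distributions (absolute update-reduction factors,
physical energy and speedup figures, printed memory-overhead percentages)
are deliberately not reproduced — the cost model can express such ratios
on synthetic networks, which is what the tests assert.

## Limitations

* Feed-forward topologies only; no recurrence, no on-line learning.
* Pure IF neurons; no leak or refractory period.
* 1-D locally connected layers model kernel sharing; 2-D convolution
  geometry is not built in.
* The cycle and energy models are parametric abstractions, not silicon.
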