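---
title: "Dendritic hierarchical scheduling: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic hierarchical scheduling: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrosched)
```

## The problem

Simulating a biophysically detailed neuron means repeatedly solving a linear
system on the neuron's dependency tree: an implicit time step of the branched
cable equation produces a quasi-tridiagonal ("Hines") matrix in which each
compartment couples only to its parent. The classic serial solve eliminates
every non-root compartment child-before-parent (triangularization), then
propagates voltages root-to-leaves (back-substitution) — n − 1 sequential
steps for n compartments. When spines are modelled explicitly a single cell
can have tens of thousands of compartments, and this serial solve dominates
the simulation.

dendrosched implements, verifies, and applies *dendritic hierarchical
scheduling* (DHS): a compartment-level parallel schedule for the Hines solve
that is provably optimal in step count and performs exactly the same
arithmetic as the serial method, so solutions agree to machine precision.

## The scheduling model

Given the tree and k threads, a feasible schedule is an ordered partition
$P(V) = \{V_1, \dots, V_n\}$ of the non-root compartments with $|V_i| \le k$
and every child scheduled before its parent. The cost is $|P(V)|$, the number
of parallel steps of the triangularization phase (back-substitution mirrors
it exactly, so ratios are unchanged).

`dhs_partition()` builds the partition greedily: maintain the candidate set Q
of nodes whose children are all processed (initially the leaves); at each
step take all of Q if $|Q| \le k$, otherwise the k *deepest* candidates,
where depth is the ancestor count. Ties between equal-depth candidates are
broken by ascending node index — the optimality argument shows any
deepest-first choice is optimal, so tie-breaking is free and we choose
determinism. Every emitted subset realises the depth sum of the
$\min(k, |Q|)$ deepest candidates (the max-depth property), which is the
lever of the optimality proof.

Rather than restating the proof, the package carries it as an executable
oracle: `min_steps_exhaustive()` finds the exact minimum over *all* feasible
partitions by breadth-first search over processed-node bitmasks (exponential,
hence capped at 14 non-root nodes). Only maximal selections of
$\min(k, |\text{candidates}|)$ nodes are enumerated, because processing more
nodes can only enlarge later candidate sets. The test suite and the
acceptance script check `dhs_partition()` against this oracle on hundreds of
random trees, alongside the combinatorial lower bound
$\max(\lceil |V|/k \rceil, \text{tree height})$.

On the bundled 15-compartment demonstration tree (`example_tree()`) serial
elimination takes 14 steps while DHS with k = 4 takes 5, with subsets of
sizes 4, 4, 4, 1, 1 — chains of deep nodes force the two singleton tail
steps, which is exactly the dependency bottleneck that limits how far
threads help. `relative_cost()` exposes the steps-to-serial ratio, and
saturation (`steps(k)` constant beyond some k*) falls out of the same
dependency structure.

## Execution, warps, and memory layout

A schedule is only useful if replaying it cannot change results.
`execute_schedule()` uses simulated-parallel semantics: steps are separated
by barriers, and within a step each node's contribution to its parent is
accumulated in ascending node order. Because children always sit in earlier
steps, within-step reads only ever see pre-step state; the only
order-sensitive operation is the accumulation onto a shared parent, which is
serialized deterministically. Executing the serial-order schedule is
therefore *bitwise* identical to `solve_hines()`, and DHS schedules agree
with the serial solve to ~1e-16 relative (the test suite asserts 1e-12
across 500 random diagonally dominant systems, and exact equality under
rational arithmetic on the demonstration tree). Real threading would be an
execution backend, never a semantics change.

`group_warps()` and `permute_layout()` express the data-layout contracts of
lockstep-thread execution as pure functions: cells sorted by (size,
canonical topology) are packed so one cell's threads never straddle a warp,
and the storage permutation places each step's nodes contiguously, ordered
by thread. Layout is provably irrelevant to the numbers — the tests permute
a system, execute, un-permute, and require identity — so these functions
only assert the contracts (contiguity, bijectivity, packing arithmetic), not
performance.

## Cable model and units

`assemble_hines()` discretises the passive cable with backward Euler
(unconditionally stable; a fixed step of 0.025 ms is the default
throughout). Units are mV / ms / nA / µS / MΩ / µm, with areas in cm² for
specific parameters; axial coupling is computed midpoint-to-midpoint from
half-compartment resistances, NEURON-style. Compartments are cylinders with
sealed-end caps excluded from membrane area.

Numerical conventions worth stating:

* Synaptic conductances enter the diagonal (implicitly in the new voltage)
  with g·E_syn on the right-hand side. Spine heads have ~0.01 pF
  capacitance, so C/g for a single activated synapse is ~17 µs — shorter
  than the 25 µs step — and a fully explicit synaptic current would be
  unstable. Only the NMDA magnesium-block factor is evaluated at the
  previous-step voltage (staggered), which linearises each step.
* No pivoting: cable discretisations are diagonally dominant; a pivot below
  1e-300 raises an error rather than being repaired.
* Spike detection is an upward crossing of a somatic threshold (−10 mV
  default; the firing criterion is a modelling choice, exposed as a
  parameter) with a 2 ms refractory gap for counting.

The physics is validated against closed forms: steady-state attenuation
along a uniform sealed cable matches cosh((L−x)/λ)/cosh(L/λ) to < 0.1% at
1 µm compartments; the single-compartment decay constant matches
τ = r_m·c_m to < 0.1% at dt = 0.025 ms; transfer resistances are reciprocal
and match hand-derived resistor networks.

## Spines: explicit vs membrane-scaled

A spine is two compartments: a neck (1.35 × 0.25 µm) and a head modelled as
a cylinder with length = diameter = 0.944 µm, i.e. 2.8 µm² of lateral area;
spine membrane is passive with a −86 mV leak reversal and the host
dendrite's specific parameters. `attach_spines()` plants
`round(density × length)` spines (ties-to-even) on every dendritic
compartment whose midpoint lies beyond the 60 µm path-distance threshold,
at a default density of 1.3 µm⁻¹. The alternative, `apply_fspine()`,
multiplies c_m and the leak conductance of the same compartments by
F_spine = 1.9 and adds no nodes. Both raise total membrane conductance; the
explicit version is the leakier one whenever the dendrites are thin, since
1.3 µm⁻¹ of spine membrane exceeds the 0.9 × dendrite-area increment that
F = 1.9 encodes for sub-3-µm diameters.

## The excitability protocol

`run_excitability()` measures somatic spike probability against synaptic
drive in two placement modes: distributed (synapse counts 0, 10, 20, 40, …,
240: 14 cases; the endpoints are stated by the protocol, the interior grid
is our choice) and clustered (0, 1, 2, 3, 4, 6, 8, 10, 12 clusters of 20
synapses on one compartment each: 9 cases). Each case uses 50 samples by
default, so the paired design totals (14 + 9) × 50 = 1150 simulated
instances. Every activated site carries an AMPA (τ 0.3/1.8 ms, peak
0.73 nS) plus NMDA (τ 8.019/34.9884 ms, peak 1.31 nS, Jahr–Stevens Mg block
with [Mg] = 1 mM, γ = 0.062 mV⁻¹ — the block's functional form is an
assumption, as only "voltage-dependent" is specified) pair on the spine-head
terminal, all activated simultaneously. Background noise, on by default, is
400 Poisson trains at 1 Hz from t = 10 ms onto randomly chosen spine heads,
with the NMDA peak drawn uniformly from 1.57–3.275 nS.

The shipped experiments run on `synthetic_pyramidal()`, a deterministic
branched stand-in morphology (soma + 3 bifurcating dendrites, 720 µm of
neurite), *not* a reconstructed human pyramidal cell: reconstructed
morphologies are optional external inputs. Two consequences are worth
knowing. First, the synthetic cell is small (resting input conductance
< 1 nS), so its spike-probability transition sits at low synapse counts and
the upper grid saturates at probability 1 in both variants; the asserted
properties — monotone non-decreasing curves, and the membrane-scaled
("few-spine") model being at least as excitable as the full-spine model at
matched high counts — are exactly the qualitative structure expected of the
leak argument, but quantitative probability curves on this stand-in do not
transfer to a real morphology. Second, timing: a full-spine sample
(~1500 compartments, 4000 steps) runs in tens of milliseconds, so the
reduced acceptance grid (3 cases × 20 samples per variant) costs seconds;
the full 1150-sample design remains a supported but optional run.

## The dendritic network and its learning rule

`hpcnet()` builds a three-layer network: input neurons (one per pixel) are
passive single compartments (c_m 1.0 µF/cm², r_m 10⁴ Ω cm², E_l 0 mV)
driven by spike trains through a single-exponential synapse (g_max 0.05 µS,
τ 0.5 ms, E_syn 1 mV); hidden neurons are copies of one passive dendritic
tree (c_m 1.5, r_m 48300, r_a 261.97, E_l 0; by default the 15-compartment
demonstration tree — a synthetic stand-in at desk scale); output neurons are
passive single compartments. Pixels are encoded as constant-interval trains
with τ_ISI = 5/(p + 0.01) ms starting at 9 + τ_ISI ms over a 50 ms stimulus.
Inter-layer coupling is graded, not spiking: contact k of input i onto
hidden j injects g·W_ijk·f(v_i) with f the ReLU of the presynaptic somatic
voltage at the previous step (instantaneous, per-step). Class probabilities
are the softmax of output somatic voltages averaged over 20–50 ms.

The learning rule replaces backpropagation's weight transpose with
electrotonic structure: the credit a synapse receives is proportional to the
*transfer resistance* r from its dendritic location to the soma (computed
once at build time by a steady-state solve), its conductance scale g, and
the presynaptic activation averaged over the 30–50 ms learning window. With
output error e_c = y_c − p_c and hidden error
e_j = Σ_c e_c·r_c·g·W_jc·f′(v̄_j), the update is
ΔW = e·r·g·(dt/(t_e−t_s))·Σ_t f(v^t), applied as W ← W + η·ΔW. Note the
sign pairing: written with e = y − p the update must be *added* to descend
the cross-entropy loss (the equivalent convention e = p − y with
subtraction is identical); the package verifies descent directly by
finite-difference comparison, with cosine similarity > 0.9999 on the output
layer of a steady-state toy network. Mini-batches are logical copies of the
network: per-sample updates are averaged and applied once, so weights never
diverge across copies.

Two parameter choices were genuinely open and are ours:

* The hidden→output conductance scale is not part of the stated parameter
  set. Reusing the input-layer 0.05 µS would put single-compartment outputs
  (~3.8 GΩ input resistance) at hundreds of mV and saturate the softmax, so
  the default is `g_out = 1e-4` µS, holding readout voltages at a few mV
  where the softmax is well conditioned. Input→hidden contacts keep 0.05 µS.
* Weight initialisation uniform(0, 0.1), η = 0.01, one contact per
  input–hidden pair. All are configurable.

At desk scale the task is `toy_images()`: size² grayscale images whose class
is a bright column block plus uniform noise in [0, 0.2] — linearly separable
by construction, standing in for full image datasets. A 16-8-2 network on
4×4 images reaches 100% training accuracy within a handful of epochs
(batch 4, η = 0.01); the acceptance criterion (≥ 90% within 50 epochs on at
least 2 of 3 seeds) passes on all three. This demonstrates that the rule
descends the intended loss on an easy task; it says nothing about
competitive accuracy on real datasets, which are out of scope here.

## Synthetic data and problem sizes

All fixtures are generated in code: canonical shapes (`tree_chain()`,
`tree_star()`, `tree_binary()`), uniform-random-parent trees
(`random_tree()`, every labelled shape reachable), strictly diagonally
dominant random Hines systems (`random_hines()`, dominance margin > 0
enforced), the demonstration tree (also shipped as an SWC fixture so
morphology I/O is exercised), and the toy images. Every generator is a pure
function of its seed.

Problem sizes used by the default test and acceptance runs, chosen as
representative rather than exhaustive: optimality is checked on 200 random
trees with ≤ 12 non-root nodes and k ∈ {2, 3, 4} (the exhaustive oracle is
exponential); numerical equivalence on 500 random systems with n ≤ 50 and
k ∈ {2, 4, 8}; the cable-physics checks on a 500-compartment cable and a
single soma at dt = 0.025 ms (40,000 iterations per simulated second); the
excitability ordering on a reduced 3-case × 20-sample grid with noise off;
training on 16 images for 50 epochs, three seeds.

## Known limitations

* Passive membrane only: active soma/axon channels are out of scope; the
  mechanism surface is the synapse set plus constant current injection.
* The exhaustive scheduling oracle stops at 14 non-root nodes; beyond that,
  optimality rests on the max-depth argument checked per partition.
* Warp grouping and layout permutation assert deterministic contracts; the
  package measures no memory traffic and makes no performance claims.
* Spike-probability magnitudes and the trained network's behaviour are
  demonstrated on synthetic stand-ins (morphology, images); reconstructed
  morphologies and real datasets are optional external inputs the package
  can consume via SWC but does not ship.
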