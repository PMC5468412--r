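---
title: "Connectome-constrained dynamics: model, equilibria, and attractor mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained dynamics: model, equilibria, and attractor mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemodyn)
```

## The model

`nemodyn` simulates a network of non-spiking, single-compartment neurons
whose only heterogeneity is their wiring. Many *C. elegans* neurons are
nearly isopotential and respond with graded rather than spiking dynamics,
so a membrane voltage $V_i$ and a synaptic activity $s_i \in [0,1]$ per
neuron suffice:

$$C \dot V_i = -G^c (V_i - E^{cell})
  - \sum_j G^g_{ij} (V_i - V_j)
  - \sum_j G^s_{ij}\, s_j (V_i - E_j)
  + I^{Ext}_i,$$

$$\dot s_i = a_r\, \phi\!\left(\beta (V_i - V^{th}_i)\right)(1 - s_i)
  - a_d\, s_i,
  \qquad \phi(x) = \frac{1}{1 + e^{-x}}.$$

Gap junctions are ohmic couplings through the symmetric conductance matrix
$G^g$; chemical synapses drive the postsynaptic membrane toward the
presynaptic neuron's reversal potential $E_j$ (0 mV for excitatory, -45 mV
for inhibitory neurons), gated by the presynaptic activity $s_j$. $\phi$
is evaluated exactly as the logistic function, with no clipping.

The unit system is {mV, s, pS, pF, fA}, which is closed: pS·mV = fA and
pF·mV/s = fA, so the equations carry no hidden conversion factors.

### Parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| `C` | membrane capacitance | 1 | pF |
| `Gc` | membrane leak conductance | 10 | pS |
| `Ecell` | leak reversal | -35 | mV |
| `g_unit` | conductance per anatomical contact | 100 | pS |
| `beta` | synaptic sigmoid width | 0.125 | 1/mV |
| `ar` | synaptic rise rate | 1 | 1/s |
| `ad` | synaptic decay rate | 5 | 1/s |
| `E_exc`, `E_inh` | presynaptic reversal potentials | 0, -45 | mV |

Published parameter sets for this model family disagree about the
sigmoid width (0.25/mV appears alongside a tabulated 0.125/mV); we
default to the tabulated value and leave `beta` freely configurable,
since every derived quantity (thresholds, Jacobians, sweeps) responds to
it.

These defaults give three intrinsic timescales, computed by
`intrinsic_timescales()`: free membrane decay $C/G^c$ = 100 ms, the
single-contact gap timescale $C/g$ = 10 ms, and — because with frozen
voltages $\dot s_i = a_r \phi_i - (a_r\phi_i + a_d) s_i$ relaxes
exponentially — synaptic time constants in
$(1/(a_r + a_d),\, 1/a_d)$ = (166.7, 200) ms. Transients measured by the
sweep machinery (seconds to tens of seconds) should always be compared
against these.

## The standard equilibrium

The sigmoid centers $V^{th}_i$ are not free data: they are constructed by
requiring $\phi(\beta(V^{eq}_i - V^{th}_i)) = 1/2$ at the zero-input
equilibrium. With $\phi \equiv 1/2$, every activity equals
$s^* = \tfrac{a_r/2}{a_r/2 + a_d} = 1/11$ and the voltage balance becomes
a linear system whose matrix is strictly diagonally dominant (the gap
off-diagonals are dominated through $G^c > 0$), hence uniquely solvable.
Setting $V^{th} := V^{eq}$ closes the construction. This "standard
equilibrium" always exists, but it is neither necessarily unique nor
necessarily stable.

We define it at zero external input. The alternative — re-deriving
thresholds per stimulus — would make "distance from standard equilibrium",
the quantity every bifurcation diagram plots, incomparable across
stimuli.

```{r}
fx <- build_fixture("excitatory_synapse_pair")
eq <- standard_equilibrium(fx$connectome, fx$params)
eq$Veq   # postsynaptic neuron pulled from -35 mV toward 0 mV
```

The postsynaptic value solves $G^c(V - E^{cell}) + G s^* V = 0$ by hand:
$V = \frac{G^c E^{cell}}{G^c + G/11} \approx -18.33$ mV.

## Stability, continuation, and the first bifurcation

`jacobian()` assembles the analytic $2n \times 2n$ Jacobian (leak + gap
Laplacian + synaptic-conductance diagonal; driving-force block; two
diagonal activity blocks). `continue_branch()` tracks the fixed point
seeded at the standard equilibrium over a strictly increasing amplitude
grid of a fixed input direction, warm-starting a damped Newton iteration
(max 100 iterations, step halving on residual increase, convergence at
an $\infty$-norm residual below $10^{-9}$ in native units) and recording
the leading eigenvalue real part. `first_bifurcation_amplitude()` refines
the first stability flip by bisection to a relative width of $10^{-3}$
(configurable); the coarse grid value is returned when no model context
is supplied. We do not distinguish Hopf from saddle-node events — only
the flip amplitude is reported, which is what the per-neuron summaries
consume. Folds are handled by truncating the branch where Newton fails;
there is no pseudo-arclength continuation around them.

## Time integration and attractor classification

`integrate_model()` wraps deSolve's `lsoda` with the analytic Jacobian
supplied, at relative/absolute tolerances $10^{-8}/10^{-10}$, sampling on
a uniform grid (default 10 ms, far below the shortest oscillation periods
of interest and above the solver's internal steps).

`classify_attractor()` inspects the final window of a trajectory
(defaults: 50 s of discarded transient, then a 20 s window — transients
in multistable regimes reach ~10 s, so the window must comfortably exceed
them; the desk-scale fixtures in the tests use shorter, explicitly passed
windows because their transients die within a second or two). The
decision rule is deliberately full-state: a tail is a fixed point only if
*every* state variable — all voltages and all activities, not just the
motorneurons — has peak-to-peak variation below `tol_fp` (default
$10^{-3}$). Otherwise a period is estimated from the plane coordinates by
autocorrelation (local maxima above a significance floor; the smallest
lag whose multiples explain all peaks, so a two-harmonic waveform yields
its fundamental; parabolic refinement of the peak) and the tail is a
limit cycle if it recurs one period apart within a relative `tol_cycle`
(default 5%). Anything else is returned as `"unclassified"`, never
silently labeled: exploratory sweeps report these counts.

`convergence_time()` implements the $\epsilon$-criterion for transient
length: the earliest sampled time after which the trajectory stays within
$\epsilon$ of its final value, with $\epsilon = 0.004$ by default, in
projection-plane units. Whether that distance is best measured in the
plane or in the full state space is a genuine modeling choice; plane
coordinates are the default here, since the plane is where transient
lengths are compared, and any coordinate matrix can be passed instead.

## The motorneuron projection plane

`fit_projection_plane()` collects forward-motion motorneuron voltages
(classes DB, DD, VB, VD) into a snapshot matrix, centers each snapshot at
the standard-equilibrium motorneuron voltages, and takes its SVD; the
plane is the span of the two leading left singular vectors. Centering is
a choice: the decomposition could equally be taken on raw snapshots, but
all reported distances are "from standard equilibrium", which forces this
reference for the coordinates to be interpretable. Each mode's
largest-magnitude entry is made positive so coordinates are reproducible
across runs. Only motorneuron voltages project onto the plane; sensory
and interneuron perturbations lie exactly in its null space, which the
tests assert. Degenerate data (fewer than two nonzero singular values)
raise an error rather than returning a meaningless second mode.

## Ensemble sweeps, merging, and basins

`bifurcation_diagram()` is the exploratory engine: per amplitude it draws
an ensemble of initial conditions around the standard equilibrium
(default: uniform in a plane-coordinate disc of radius $4 \times 10^{-6}$,
displacing motorneuron voltages only, with activities set to their
voltage-consistent equilibria; a full-space Gaussian voltage jitter is
available, since nothing in the model fixes the ensemble's
distribution), integrates past the transient, classifies each tail, merges
duplicates by single linkage (`fp_tol` on plane distance for fixed
points; relative period *and* distance agreement for cycles; kinds never
merge), and attaches the continued standard branch. Identical seeds give
bit-identical diagrams. Ensemble searching carries no completeness
guarantee — attractors can be missed — which is why the tests include a
saturation check (doubling the ensemble discovers nothing new on the
fixtures) and an oracle comparison against a 5x ensemble with 3x
integration time.

`basin_map()` lays a square lattice over the plane (default half-width
$4 \times 10^{-6}$, a small neighbourhood of the standard equilibrium),
starts each cell at the displaced equilibrium with activities set
consistently (off-plane activity initialization is unconstrained;
voltage-consistent equilibria are the least arbitrary choice), and labels
each cell with the nearest reference attractor of the same kind.
`basin_map_grid()` exposes the same grid machinery for any runner, which
is how the test suite plumbs the bistable normal form
$\dot x = x - x^3$ through it and checks the recovered boundary against
the analytic separatrix.

```{r}
os <- build_fixture("mutual_excitation_oscillator")
eq_o <- standard_equilibrium(os$connectome, os$params)
stability(eq_o$Veq, eq_o$seq, os$connectome, os$params,
          eq_o$Vth)$leading_real_part
```

## Synthetic connectomes and fixtures

`generate_synthetic_connectome()` emulates the structural assumptions the
model makes about real connectivity data — a symmetric nonnegative gap
matrix on unordered pairs, a directed nonnegative synapse matrix, three
neuron classes, a configurable inhibitory fraction — with one 100 pS
contact per realized edge. It does *not* attempt realistic degree
distributions, reciprocity, or spatial structure; passing tests on these
networks demonstrates the correctness of the machinery, not biological
conclusions about any real connectome. Analyses of the real somatic
network require its published connectivity tables, consumed through
`read_connectome()`; the `inst/scripts/reproduce_*.R` scripts run each
full-network study once those tables are supplied.

The fixture registry (`build_fixture()`) pins down known answers:
isolated neuron (equilibrium at $E^{cell}$, leading eigenvalue
$-(a_r/2 + a_d) = -5.5\,s^{-1}$), a gap pair, the hand-solvable
excitatory pair, a 30-neuron seeded three-class network, and the
oscillator pair. On the last: a two-neuron circuit with *pure* mutual
excitation cannot oscillate in this model — its feedback loop is
sign-positive, so eigenvalues cross on the real axis — and, because the
threshold construction puts every neuron at the top of its sigmoid gain
at zero input, no two-neuron circuit destabilizes with *increasing*
drive. The fixture is therefore a mutually coupled
excitatory/inhibitory pair with `beta` scaled 40-fold: an unstable focus
at zero input surrounded by a 0.36 s limit cycle, quenched as drive
grows. Its frozen expectations (leading eigenvalue, flip bracket,
period) come from an independent brute-force script
(`tools/search_oscillator.R`) with its own hand-written vector field,
root finder, finite-difference Jacobian and zero-crossing period
estimator.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
systems: 8-30 neuron networks, 20-point amplitude grids, ensembles of
5 (25 for the brute-force oracle), transients of 7-27 s per simulation,
and a 12x12 basin grid for the normal-form harness. These sizes were
chosen so each property is exercised well past its convergence scales
(fixture transients die within ~1-2 s; oscillation periods are ~0.36 s
against 5-10 s analysis windows). The full 279-neuron single-neuron
survey is exposed through the `survey` subcommand and the
reproduction scripts, and is expected to take hours, as exploratory
ensemble sweeps do.

Degenerate inputs are rejected loudly: non-finite states, mismatched
dimensions, non-increasing amplitude grids, self-edges, unknown neuron
names, rank-deficient snapshot matrices. Ties in period estimation break
toward the smallest period whose multiples explain all autocorrelation
peaks. Newton failures are values, not exceptions, except at the first
branch point where nothing has been computed yet.

## Known limitations

* No chaos detection: tails that are neither fixed points nor cycles are
  reported indeterminate by design.
* No limit-cycle continuation (Floquet analysis); cycle existence is
  established by simulation only.
* No proprioceptive or neuromodulatory feedback; all neurons share one
  parameter set, so conclusions are about what *connectivity alone* can
  encode.
* The mapping from motorneuron modes to muscle activation or body shape
  is outside the package's scope.
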