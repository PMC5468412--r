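# nemodyn

Connectome-constrained neural network dynamics and numerical bifurcation
analysis in R.

`nemodyn` is for researchers studying how a fixed wiring diagram — gap
junctions plus signed chemical synapses, as mapped for the *C. elegans*
somatic nervous system — shapes collective neural dynamics when every
neuron is modeled identically. It implements the graded-synapse
single-compartment membrane model, and around it the exploratory
machinery needed to map a network's attractor landscape as a function of
input: standard-equilibrium construction, fixed-point continuation with
analytic Jacobians, stiff time integration, fixed-point/limit-cycle
classification of trajectory tails, a two-mode motorneuron projection
plane, ensemble bifurcation diagrams, basin-of-attraction maps, and
transient convergence-time measurement.

## The model

Each neuron carries a membrane voltage `V_i` (mV) and a synaptic activity
`s_i` in [0, 1]:

    C dV_i/dt = -Gc (V_i - Ecell)
                - sum_j Gg_ij (V_i - V_j)            (gap junctions)
                - sum_j Gs_ij s_j (V_i - E_j)        (graded synapses)
                + I_i                                 (external input)

    ds_i/dt   = ar * phi(beta (V_i - Vth_i)) * (1 - s_i) - ad * s_i

with `phi` the logistic function and `E_j` = 0 mV (excitatory) or -45 mV
(inhibitory) a property of the presynaptic neuron. The sigmoid centers
`Vth` are constructed, not supplied: each neuron's activation is required
to be exactly 1/2 at the zero-input equilibrium ("standard equilibrium"),
which reduces to one linear solve. Inputs are a fixed direction vector
scaled by an amplitude (fA) — the bifurcation parameter of all sweeps.

## Worked example

A two-neuron excitatory/inhibitory oscillator fixture, analysed end to
end:

```r
library(nemodyn)

fx <- build_fixture("mutual_excitation_oscillator")
eq <- standard_equilibrium(fx$connectome, fx$params)
print(eq)
#> standard equilibrium: 2 neurons, Veq in [-43.197, -6.311] mV, s = 0.09091

stability(eq$Veq, eq$seq, fx$connectome, fx$params, eq$Vth)$leading_real_part
#> [1] 5.852228
```

The leading eigenvalue real part is +5.85 1/s: the standard equilibrium
is an unstable focus, so the system must settle elsewhere. Integrating
and classifying the tail finds the surrounding limit cycle:

```r
V0 <- eq$Veq + c(0.5, -0.5)
traj <- integrate_model(V0, synaptic_equilibrium(V0, fx$params, eq$Vth),
                        fx$connectome, fx$params, eq$Vth,
                        duration = 40, sample_dt = 0.005)
plane <- structure(list(motor_indices = 1:2, modes = diag(2),
                        singular_values = c(1, 1), reference = eq$Veq,
                        variance_fraction = 1, n_neurons = 2L),
                   class = "projection_plane")
classify_attractor(traj, plane, window = 10)
#> attractor: limit_cycle, plane distance 1.276, period 0.358 s
```

An amplitude sweep of drive into the excitatory neuron shows the cycle
being quenched — a one-row-per-attractor table straight from the
ensemble engine:

```r
dg <- bifurcation_diagram(fx$connectome, fx$params, eq, c(1, 0),
                          amplitudes = c(0, 100),
                          ensemble = ensemble_spec(4, 0.5, seed = 5),
                          plane = plane, transient = 25, window = 10,
                          sample_dt = 0.005)
diagram_table(dg)
#>   amplitude        kind max_plane_distance    period count
#> 1         0 limit_cycle           1.275818 0.3581916     4
#> 2       100 fixed_point           2.086851        NA     4
```

At zero input all four ensemble members converge to the same limit cycle
(period 0.36 s, farthest plane distance 1.28 from the standard
equilibrium); at amplitude 100 fA the only attractor is a fixed point.

Real connectivity data enter through two CSV tables
(`read_connectome()`): an edge list `pre,post,kind,count` with
`kind` in {gap, chem}, and per-neuron metadata
`name,class,inhibitory,subclass`. Conductances are
`count x 100 pS`. A command-line front end is installed at
`inst/scripts/nemodyn` with subcommands `timescales`, `equilibrium`,
`simulate`, `bifurcate`, `basin`, `survey`, and the
`inst/scripts/reproduce_*.R` scripts run each full-connectome study
(PLM-drive bifurcation, limit-cycle period, two-mode variance, PLM+ASK
bistability, per-class survey) against user-supplied connectome tables.

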