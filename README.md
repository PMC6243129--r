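# wormlab

A headless R toolkit for defining *Caenorhabditis elegans* behavioral
experiments and executing them on point-neuron models of the worm's
nervous system. It re-implements, as a library plus command-line tool,
the experiment-definition stack that web-based *C. elegans* simulation
platforms expose through GUIs: behavioral experiment encoding, declarative
neuron-model assembly, fixed-topology connectome configuration, simulation,
and results handling — every stage importable and exportable as
machine-readable XML/CSV/JSON so experiments stay reproducible across
simulation environments.

## What it does

**Behavioral experiment encoding.** Assays are encoded as a duration-based
timeline: events happen *at a specific time*, *from t0 to t1*, or
*experiment-wide*, over the five taxis modalities (mechanotaxis,
chemotaxis, thermotaxis, galvanotaxis, phototaxis), plus an environment
block (worm strain/stage, cylindrical plate, obstacles, crowding). The
dialect is an XML format frozen in a shipped XSD; `read_experiment()` /
`write_experiment()` are loss-free inverses, `validate_experiment()`
returns violations as data, and `active_stimuli()` answers which stimuli
act at any instant (intervals are half-open `[t0, t1)`).

**Declarative neuron models.** Model dynamics live in `ComponentType`
templates (parameters, state variables, derived variables, time
derivatives, event-driven rules) that are parameterized into `Component`
instances — dynamics and parameter values stay strictly separated, so one
template covers many behaviors. Parameter bindings carry units and are
dimension-checked against the seven SI base quantities. The core library
(`load_core_library()`) provides leaky integrate-and-fire and Izhikevich
cells, a Hodgkin–Huxley-style two-rate gate, an ohmic ion channel, a pulse
current generator, a single-exponential chemical synapse and a linear gap
junction. Composed models export to a LEMS XML subset (`export_lems()` /
`import_lems()`).

For the integrate-and-fire cell the membrane follows
`C dv/dt = gL (EL − v) + I`, so with constant suprathreshold drive the
interspike interval has the closed form

```
T = tau * ln( RI / (RI − V_theta) ),   tau = C/gL,  R = 1/gL
```

which the test suite uses as an oracle for the interpreter.

**Connectome configuration.** A fixed 302-neuron network (packaged
fixture with canonical neuron names; synthetic positions and wiring —
see `inst/extdata/connectome/README.md`) is annotated, never edited:
assign a default cell model, override models or parameters for selected
neurons (ordered, last wins), map chemical synapses and gap junctions by
kind/neurotransmitter/endpoint selectors, auto-select recorded variables,
and export the whole network (`export_network()`); export refuses until
every connection is matched.

**Reference interpreter.** `flatten()` turns a model or network into an
ordered state-update system; `run_simulation()` integrates it (forward
Euler by default, RK4 as a cross-check) with edge-triggered threshold
rules, event delivery to synapses, gap-junction coupling, and external
current injections. `transduce()` converts behavioral events into
injections through a pluggable transduction map (default: direct touch
drives the six touch receptor neurons).

**Results.** Traces go to CSV with a JSON metadata header, locomotion
recordings (midline + 95 body-wall muscle activations per frame) to JSON
lines, tied together by a manifest with a common clock;
`generate_synthetic_results()` stands in for an external body-physics
engine so the full pipeline runs offline. `slice_results()` extracts
timeline windows; `highlight_sets()` returns the selected/postsynaptic
neuron sets a results viewer colors.

## Worked example

```r
library(wormlab)

# a cell driven by a constant 0.5 nA pulse
cell <- default_component("iaf", "cell")
stim <- instantiate(load_core_library()$pulseGenerator, "stim",
                    c(delay = "0 ms", duration = "1000 ms",
                      amplitude = "0.5 nA"))
model <- compose_model(list(cell, stim),
                       links = list(list(from = "stim/i", to = "cell/iSyn")),
                       root = "cell")

res <- run_simulation(simulation_spec(model, duration = 100, dt = 0.01))
mean(diff(res$spikes$cell))        # 7.14
20 * log(50 / (50 - 15))           # 7.133499  (closed form, ms)
```

The simulated interspike interval (7.14 ms) matches the closed form
within 0.1% at dt = 0.01 ms. On the network side:

```r
cn <- celegans_connectome()
nrow(cn$neurons)                   # 302
postsynaptic_partners(cn, "AVAL")$postsynaptic
# "AWBR" "DB2" "DVC" "M3R"          (synthetic fixture wiring)
```

The same workflow is scriptable from a shell via the thin wrapper in
`inst/cli/wormlab` (or `cli_main()` from R): `new-experiment`,
`validate-experiment`, `build-model`, `validate-model`,
`configure-network`, `export-network`, `neuron-info`, `simulate`,
`gen-demo-results`, `export-results`.

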