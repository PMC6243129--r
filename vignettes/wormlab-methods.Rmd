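---
title: "wormlab: models, encodings and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wormlab: models, encodings and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormlab)
```

This vignette is the package's own account of its science: what each
layer models, which parameters matter and why their defaults were
chosen, where the design was genuinely open and what was decided, and
what the tests do and do not demonstrate.

## The behavioral experiment encoding

Stimulus protocols for *C. elegans* assays operate at the level of the
organism — a touch, a chemical drop, a temperature ramp — not at the
level of injected currents, so the encoding is organised by *duration*
first and *modality* second. Every timeline event belongs to exactly one
of three categories:

* an interaction at a specific time `t` (`eventTime`),
* an interaction from `t0` to `t1` (`eventStartTime`, `eventStopTime`),
* an experiment-wide configuration with no time references.

Within a category the event carries one of five taxis modalities
(mechanotaxis, chemotaxis, thermotaxis, galvanotaxis, phototaxis) and a
concrete stimulus: direct touch, plate tap, chemical drop, osmotic ring,
temperature change, electric shock, or light. Behaviors not driven by
sensory input (feeding, egg laying, mating, defecation) are deliberately
out of scope. The environment block captures worm strain, age, sex,
stage and starvation time, the worm's initial pose, a cylindrical plate,
cylindrical obstacles, and a crowding block.

Units are fixed once for the whole dialect: times in ms, geometry in mm,
angles in degrees, concentrations in mM, shock amplitudes in nA, touch
force in uN (no published unit exists for the touch force; uN matches
the scale of eyelash-widget assays). The dialect itself — lowerCamelCase
element names, a frozen element order — is pinned by the shipped XSD
(`inst/xsd/behavioral-experiment.xsd`); the reader is strict, so unknown
elements fail loudly instead of being silently dropped.

Three semantic decisions were open and are fixed as follows:

* **Interval activity is half-open** `[t0, t1)`, so abutting intervals
  never double-fire at the joint.
* **Instant-event tolerance defaults to 0 ms** (strict equality) and is
  a parameter of `active_stimuli()`; no published value exists.
* **Crowding's distribution index is carried opaquely** — it keys into
  placement formulae that are not published, so the package validates
  only non-negativity and round-trips the value.

Instant mechanosensation events carry their own `contact_duration`,
because a touch plainly extends over a period even when the protocol
anchors it to one time point; transduction uses that duration as the
injection support.

## The model-building layer

Model dynamics and parameter values are kept strictly separate: a
`ComponentType` holds the equations (state variables, derived variables,
time derivatives, event-driven rules), a `Component` binds every
parameter exactly once. Two components of one type are guaranteed to
share dynamics and differ only in bindings — the property that makes one
Izhikevich template cover regular spiking, bursting and chattering cells
purely by parameterization.

Expressions use a small language (`+ − × ÷ ^`, unary minus, `exp`,
`log`, `sqrt`, `abs`, comparisons, conjunction) parsed by a
recursive-descent parser; predicates accept both symbolic (`>=`) and
dotted (`.geq.`, `.and.`) operators. Conditional predicates support only
comparisons joined by AND — sufficient for the threshold/reset rules of
every model in the library. Name resolution is lexical within a type and
shadowing is an error. Every expression is dimension-checked over the
seven SI base quantities: derived variables infer their dimension,
`dv/dt` must have dimension(v)/time, and unit-carrying bindings
(`"0.2 nF"`) are checked against the parameter's declared dimension
through a fixed unit table (ms, mV, nA, pA, nS, uS, nF, uF, per_ms,
per_s, and the SI units themselves) with power-of-ten scaling.

The implemented LEMS subset is flat: no Structure, ForEach or
KineticScheme constructs, which the described GUI workflow never
produces; imports reject anything outside the subset with an
unsupported-construct error rather than guessing. Because no exhaustive
list of the original core-type palette is published, the library here is
the minimal closed set the workflow needs: the two named point-neuron
models (integrate-and-fire, Izhikevich), an HH-style two-rate gate and
ohmic channel to represent conductance-based building blocks, a pulse
generator, and the two synapse types required by whole-network export.

Core library defaults (all overridable at instantiation):

| Component | Parameters | Why these values |
|---|---|---|
| `iafCell` | C = 0.2 nF, gL = 10 nS, EL = −65 mV, Vth = −50 mV, Vreset = −65 mV | membrane time constant τ = C/gL = 20 ms and a 15 mV threshold — textbook cortical-scale values that give the closed-form interspike interval used as the test oracle |
| `izhikevichCell` | a = 0.02, b = 0.2, c = −65, d = 8, vpeak = 30 | the classic regular-spiking parameterization |
| `expOneSynapse` | τ = 5 ms, gbase = 1 nS, erev = 0 mV | fast excitatory synapse |
| `gapJunction` | 0.5 nS | weak electrical coupling |

The Izhikevich dynamics are implemented in their dimensionless 2004 form
(`dv/dt = 0.04 v² + 5 v + 140 − u + I`), with explicit `tscale` (1 ms)
and `iscale` (1 nA) normalisation parameters so the expression is
dimensionally closed — the same device the NeuroML2 `izhikevichCell`
uses. The state `v` is mV-coded but dimensionless; consequences for
network coupling are handled in the runtime (below).

## Connectome configuration

The network topology is immutable: 302 named neurons, directed chemical
synapses, symmetric gap junctions stored once per unordered pair.
Configuration only annotates it, mirroring the default-then-customize
workflow of the three interaction modes: `assign_models()` (neuron
selection), `assign_parameters()` (neuron parameter),
`assign_synapses()` (synapse selection) — each rejects selectors of the
other mode, and later assignments win (ordered precedence). Synapse
rules select on kind, putative neurotransmitter, endpoints, or explicit
pairs; a chemical-synapse component can never be placed on a gap
junction or vice versa, and export refuses while any connection is
unmatched, naming the offending pair.

Recorded variables are auto-selected after configuration: the membrane
exposure `v` plus every state variable of each neuron's resolved model.
The exact auto-selection rule is not published; exposure-plus-states is
this package's documented choice (it is what a results viewer needs and
is editable afterwards via `set_recorded_variables()`).

Soma positions serve selection and reporting only — the network is made
of point neurons and positions never enter the simulation.

**Fixture provenance.** The packaged tables use the canonical 302
adult-hermaphrodite neuron names, but the soma positions, the
category assignment and the entire connection list are *synthetic*
(deterministic generator, documented in
`inst/extdata/connectome/README.md` and flagged by the `_synthetic`
filenames). The fixture exists for structural invariants and offline
export tests; real connectivity analyses must load a published wiring
dataset through `load_connectome()`.

## The reference interpreter

`flatten()` compiles every expression once into R closures and produces
an ordered evaluation plan: derived variables in dependency order within
each unit, units ordered so that any unit consuming another's *derived*
variable (synaptic currents feeding a cell's summed input) is refreshed
after its source; cyclic derived-variable dependencies are an error.

Numerical choices:

* **Internal units are SI** (volts, seconds, amps); bindings are scaled
  from their declared units at instantiation, and traces are reported in
  SI. Cells with dimensionless mV-coded membrane state (Izhikevich) are
  scaled by 10⁻³ when supplying a voltage requirement of a synapse or
  gap junction — the documented mV convention.
* **Integrator: forward Euler, dt default 0.05 ms.** Hardware-style
  update rules are first order, and the closed-form oracle plus the
  convergence test pin the behavior: the subthreshold charging error
  halves with dt, and at dt = 0.01 ms the interspike interval of the
  default integrate-and-fire cell is within 0.1% of
  `T = τ ln(RI/(RI − V_θ))`. Classic RK4 is available
  (`method = "rk4"`) as a cross-check oracle, not as the default.
* **Event semantics.** Conditions are tested after each state update and
  are edge-triggered (they fire on the false-to-true transition; the
  trigger memory starts false, so a rule already true at t = 0, like a
  zero-delay pulse onset, fires at start). Reset assignments apply
  before synaptic event propagation within the same step; simultaneous
  events are delivered in unit-name order — a deterministic tie-break.
  Determinism is absolute: identical specs give bit-identical results,
  and export→import round-trips reproduce spike times exactly.
* **Gap junctions** are single symmetric records expanded at flatten
  time into two directed conductance terms `g (v_peer − v)` with
  opposite signs; two identical cells driven identically therefore stay
  bit-identical, which the suite asserts.
* Numerical overflow aborts with the time and the unit/state that
  diverged.

**Transduction** is a pluggable seam, not a sensory model: the default
map drives the six classical touch receptor neurons (ALML/R, AVM,
PLML/R, PVM) with a constant pulse over the event's active span,
amplitude linear in the applied force at 0.01 nA/uN. That gain is a
placeholder — no published transduction gains exist for this pathway in
the sources this package works from — and all other modalities are
no-ops until the user supplies rules. Anything beyond current injection
(body mechanics, real sensory dynamics) belongs to an external
body/environment simulator.

## Results layer and the synthetic generator

Traces are CSV with a one-line JSON-in-comment header (a "spreadsheet"
format with no published dialect; CSV is the least surprising choice),
printed to 12 significant digits so that write→read round-trips are
exact at the printed precision and write→read→write is byte-stable.
Locomotion is JSON lines, one frame per line — the upstream
physics-engine payload is not published, so this is a clean-room
stand-in. A manifest ties both to one clock and loading verifies the
clocks reconcile (every frame within dt/2 of a trace grid point after
offset correction).

The synthetic generator emulates just enough structure to exercise the
pipeline: membrane-potential-like traces (leaky baseline, seeded noise,
stereotyped spike transients at 1–8 Hz), and a traveling-wave midline
undulation (default 33 points, amplitude 0.1 mm, wavelength 0.6 mm,
0.5 Hz — worm-scale crawling values) with antiphase dorsal/ventral
muscle activations over the fixed 95-channel anatomical order (DL 24,
DR 24, VL 24, VR 23, each anterior→posterior). It is deterministic per
seed and restores the caller's RNG state. What it does **not** emulate:
real neural dynamics, proprioceptive coupling between the two outputs,
or any body mechanics — passing pipeline tests says the formats, clocks
and slicing are correct, not that any biology is.

Slicing is half-open `[t0, t1)` with the clock rebased to the slice
start, making it a monoid action; a window ending exactly at the
recording end keeps the terminal grid point (the grid spans the closed
interval `[0, duration]`, which pure half-open slicing could never
recover), so abutting slices concatenate back to the original.

## Problem sizes in the test suite

The suite runs entirely on fixtures built in code: 50-document
round-trip loops per format, 1000 randomized timeline experiments
against a brute-force oracle, 100 random graphs for adjacency queries,
single-cell simulations of 20–300 ms at dt between 0.2 and 0.01 ms, and
toy networks of 2–5 neurons; the packaged 302-neuron fixture is used for
structural counts, whole-network export and the synthetic demo. These
sizes give sub-second individual tests while still probing every
contract; nothing about the methods limits them to these scales.

## Known limitations

* The connectome fixture's wiring is synthetic; counts and categories
  are realistic, the edges are not data.
* The LEMS subset is flat — no multi-compartment morphology, kinetic
  schemes or component hierarchies.
* Forward Euler is first-order; stiff conductance models would need the
  RK4 path or smaller dt.
* Transduction gains are placeholders; only direct touch has a default
  rule.
* Crowding semantics beyond carrying the block (multi-worm simulation)
  are out of scope, as are all GUI/3D-rendering concerns and any
  hardware or physics-engine coupling.
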