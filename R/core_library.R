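# Core library of dynamics templates: the point-neuron cells, channel
# building blocks and synapse types needed for whole-connectome export.
# Modeled on the standard NeuroML2 core types, restricted to the flat
# subset this package implements.

#' Load the core library of dynamics templates
#'
#' Returns the built-in ComponentTypes:
#'
#' * `iafCell` — leaky integrate-and-fire cell:
#'   `C dv/dt = gL (EL - v) + iSyn`, threshold `Vth`, reset `Vreset`,
#'   output event port `spike`.
#' * `izhikevichCell` — two-variable quadratic adaptive cell in its
#'   classic dimensionless form
#'   (`dv/dt = 0.04 v^2 + 5 v + 140 - u + I`), with explicit `tscale`
#'   (time) and `iscale` (current) normalisation parameters so the
#'   dynamics are dimensionally closed.
#' * `hhRateGate` — Hodgkin-Huxley-style two-rate activation gate with
#'   voltage-dependent exponential rates
#'   (`dx/dt = alpha (1 - x) - beta x`), exposing `x` and the
#'   steady-state activation `xinf = alpha / (alpha + beta)`.
#' * `ionChannelHH` — ohmic channel `i = gmax fopen (erev - v)` taking
#'   its open fraction from a linked gate.
#' * `pulseGenerator` — square current pulse (`delay`, `duration`,
#'   `amplitude`).
#' * `expOneSynapse` — single-exponential conductance-based chemical
#'   synapse; incoming spikes add `gbase` to `g`.
#' * `gapJunction` — linear electrical coupling
#'   `i = conductance (vpeer - v)`.
#'
#' @return Named list of `wl_component_type` objects.
#' @export
#' @examples
#' names(load_core_library())
load_core_library <- function() {
  list(
    iafCell = component_type(
      "iafCell",
      parameters = c(C = "capacitance", gL = "conductance", EL = "voltage",
                     Vth = "voltage", Vreset = "voltage"),
      state_variables = c(v = "voltage"),
      time_derivatives = c(v = "(gL * (EL - v) + iSyn) / C"),
      on_start = c(v = "EL"),
      on_conditions = list(list(
        test = "v .geq. Vth",
        assignments = c(v = "Vreset"),
        event_out = "spike")),
      event_ports = c(spike = "out"),
      exposures = "v",
      requirements = c(iSyn = "current")),

    izhikevichCell = component_type(
      "izhikevichCell",
      parameters = c(a = "dimensionless", b = "dimensionless",
                     c = "dimensionless", d = "dimensionless",
                     vpeak = "dimensionless",
                     tscale = "time", iscale = "current"),
      state_variables = c(v = "dimensionless", u = "dimensionless"),
      derived_variables = c(inorm = "iSyn / iscale"),
      time_derivatives = c(
        v = "(0.04 * v^2 + 5 * v + 140 - u + inorm) / tscale",
        u = "a * (b * v - u) / tscale"),
      on_start = c(v = "c", u = "b * c"),
      on_conditions = list(list(
        test = "v .geq. vpeak",
        assignments = c(v = "c", u = "u + d"),
        event_out = "spike")),
      event_ports = c(spike = "out"),
      exposures = c("v", "u"),
      requirements = c(iSyn = "current")),

    hhRateGate = component_type(
      "hhRateGate",
      parameters = c(ra = "per_time", va = "voltage", ka = "voltage",
                     rb = "per_time", vb = "voltage", kb = "voltage"),
      state_variables = c(x = "dimensionless"),
      derived_variables = c(
        alpha = "ra * exp((v - va) / ka)",
        beta = "rb * exp((vb - v) / kb)",
        xinf = "alpha / (alpha + beta)"),
      time_derivatives = c(x = "alpha * (1 - x) - beta * x"),
      on_start = c(x = "xinf"),
      exposures = c("x", "xinf"),
      requirements = c(v = "voltage")),

    ionChannelHH = component_type(
      "ionChannelHH",
      parameters = c(gmax = "conductance", erev = "voltage"),
      derived_variables = c(i = "gmax * fopen * (erev - v)"),
      exposures = "i",
      requirements = c(v = "voltage", fopen = "dimensionless")),

    pulseGenerator = component_type(
      "pulseGenerator",
      parameters = c(delay = "time", duration = "time",
                     amplitude = "current"),
      state_variables = c(i = "current"),
      on_start = c(i = "amplitude * 0"),
      on_conditions = list(
        list(test = "t .geq. delay", assignments = c(i = "amplitude")),
        list(test = "t .geq. delay + duration",
             assignments = c(i = "amplitude * 0"))),
      exposures = "i"),

    expOneSynapse = component_type(
      "expOneSynapse",
      parameters = c(tauDecay = "time", gbase = "conductance",
                     erev = "voltage"),
      state_variables = c(g = "conductance"),
      derived_variables = c(i = "g * (erev - v)"),
      time_derivatives = c(g = "-g / tauDecay"),
      on_start = c(g = "gbase * 0"),
      on_events = list(spikeIn = list(assignments = c(g = "g + gbase"))),
      event_ports = c(spikeIn = "in"),
      exposures = c("i", "g"),
      requirements = c(v = "voltage")),

    gapJunction = component_type(
      "gapJunction",
      parameters = c(conductance = "conductance"),
      derived_variables = c(i = "conductance * (vpeer - v)"),
      exposures = "i",
      requirements = c(v = "voltage", vpeer = "voltage"))
  )
}

#' Reference parameterizations of the core cell and synapse types
#'
#' Convenience Components with conventional textbook parameter values,
#' used as network-wide defaults and in examples: a leaky
#' integrate-and-fire cell (`tau_m = C/gL = 20 ms`, 15 mV spike
#' threshold above rest), a regular-spiking Izhikevich cell
#' (`a=0.02, b=0.2, c=-65, d=8`), a fast excitatory single-exponential
#' synapse, and a weak gap junction.
#'
#' @param which one of `"iaf"`, `"izhikevich"`, `"exc_synapse"`,
#'   `"gap_junction"`, `"pulse"`.
#' @param id component id.
#' @return A `wl_component`.
#' @export
default_component <- function(which = c("iaf", "izhikevich", "exc_synapse",
                                        "gap_junction", "pulse"),
                              id = which) {
  which <- match.arg(which)
  lib <- load_core_library()
  switch(which,
    iaf = instantiate(lib$iafCell, id, c(
      C = "0.2 nF", gL = "10 nS", EL = "-65 mV",
      Vth = "-50 mV", Vreset = "-65 mV")),
    izhikevich = instantiate(lib$izhikevichCell, id, c(
      a = "0.02", b = "0.2", c = "-65", d = "8", vpeak = "30",
      tscale = "1 ms", iscale = "1 nA")),
    exc_synapse = instantiate(lib$expOneSynapse, id, c(
      tauDecay = "5 ms", gbase = "1 nS", erev = "0 mV")),
    gap_junction = instantiate(lib$gapJunction, id,
                               c(conductance = "0.5 nS")),
    pulse = instantiate(lib$pulseGenerator, id, c(
      delay = "10 ms", duration = "100 ms", amplitude = "0.5 nA")))
}
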