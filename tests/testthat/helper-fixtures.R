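# Shared fixture builders for the test suite. Everything is generated in
# code; no binary data.

toy_connectome <- function() {
  neurons <- data.frame(
    name = c("S1", "S2", "I1", "M1", "M2"),
    class = c("S", "S", "I", "M", "M"),
    category = c("sensory", "sensory", "inter", "motor", "motor"),
    x = c(100, 110, 300, 500, 520), y = 0, z = 0,
    stringsAsFactors = FALSE)
  connections <- data.frame(
    pre = c("S1", "S2", "I1", "I1", "S1"),
    post = c("I1", "I1", "M1", "M2", "S2"),
    kind = c("chemical", "chemical", "chemical", "chemical",
             "gap_junction"),
    multiplicity = c(2, 1, 3, 1, 1),
    neurotransmitter = c("glutamate", "glutamate", "acetylcholine",
                         "GABA", "none"),
    stringsAsFactors = FALSE)
  load_connectome(neurons, connections)
}

two_cell_connectome <- function(kind = "chemical") {
  neurons <- data.frame(name = c("A", "B"), class = c("A", "B"),
                        category = "inter", x = c(0, 10), y = 0, z = 0,
                        stringsAsFactors = FALSE)
  connections <- data.frame(
    pre = "A", post = "B", kind = kind, multiplicity = 1,
    neurotransmitter = if (kind == "chemical") "acetylcholine" else "none",
    stringsAsFactors = FALSE)
  load_connectome(neurons, connections)
}

iaf_pulse_model <- function(amplitude = "0.5 nA", delay = "0 ms",
                            duration = "1000 ms") {
  cell <- default_component("iaf", "cell")
  stim <- instantiate(load_core_library()$pulseGenerator, "stim",
                      c(delay = delay, duration = duration,
                        amplitude = amplitude))
  compose_model(list(cell, stim),
                links = list(list(from = "stim/i", to = "cell/iSyn")),
                root = "cell")
}

configured_toy_network <- function(connectome = toy_connectome(),
                                   preset = "iaf") {
  cfg <- network_configuration(connectome,
                               default_component(preset, "cellDefault"))
  if (any(connectome$connections$kind == "chemical"))
    cfg <- assign_synapses(cfg, synapse_selector(kind = "chemical"),
                           default_component("exc_synapse", "synDefault"))
  if (any(connectome$connections$kind == "gap_junction"))
    cfg <- assign_synapses(cfg, synapse_selector(kind = "gap_junction"),
                           default_component("gap_junction", "gapDefault"))
  auto_select_recorded_variables(cfg)
}

# random expression source over given symbols; returns a string the
# package parser accepts and base R can evaluate after conversion
random_expr_source <- function(symbols, depth = 3) {
  rand_atom <- function() {
    if (runif(1) < 0.5) format(round(runif(1, 0.1, 5), 3))
    else sample(symbols, 1)
  }
  rec <- function(d) {
    if (d <= 0 || runif(1) < 0.25) return(rand_atom())
    op <- sample(c("+", "-", "*", "/", "^", "fun", "neg"), 1,
                 prob = c(0.22, 0.22, 0.22, 0.12, 0.06, 0.08, 0.08))
    if (op == "fun") {
      f <- sample(c("exp", "log", "sqrt", "abs"), 1)
      inner <- if (f %in% c("log", "sqrt"))
        paste0("abs(", rec(d - 1), ") + 0.1") else rec(d - 1)
      paste0(f, "(", inner, ")")
    } else if (op == "neg") {
      paste0("-(", rec(d - 1), ")")
    } else if (op == "^") {
      paste0("(", rec(d - 1), ") ^ ", sample(0:3, 1))
    } else {
      paste0("(", rec(d - 1), ") ", op, " (", rec(d - 1), ")")
    }
  }
  rec(depth)
}

random_environment <- function(symbols) {
  as.list(setNames(round(runif(length(symbols), 0.2, 3), 4), symbols))
}
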