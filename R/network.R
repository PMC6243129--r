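# Network configuration over a fixed connectome: a default cell model,
# per-neuron model and parameter overrides (ordered, last wins), ordered
# synapse assignment rules, and the recorded-variable set. The three
# interaction modes of the original workflow map to the three assignment
# operations: assign_models (neuron selection), assign_parameters (neuron
# parameter) and assign_synapses (synapse selection); each rejects
# selectors of the other mode.

#' Selectors for network configuration
#'
#' A neuron selector matches neurons by explicit `names`, anatomical
#' `class` and/or functional `category`; a synapse selector matches
#' connections by `kind`, `neurotransmitter`, `pre`/`post` endpoint, or an
#' explicit `pairs` data.frame (`pre`, `post`, `kind`). `NULL` fields
#' match everything.
#'
#' @param names,class,category neuron matching criteria.
#' @param kind,neurotransmitter,pre,post,pairs connection matching
#'   criteria.
#' @return A selector object.
#' @export
neuron_selector <- function(names = NULL, class = NULL, category = NULL) {
  structure(list(names = names, class = class, category = category),
            class = "wl_neuron_selector")
}

#' @rdname neuron_selector
#' @export
synapse_selector <- function(kind = NULL, neurotransmitter = NULL,
                             pre = NULL, post = NULL, pairs = NULL) {
  structure(list(kind = kind, neurotransmitter = neurotransmitter,
                 pre = pre, post = post, pairs = pairs),
            class = "wl_synapse_selector")
}

match_neurons <- function(connectome, selector) {
  stopifnot(inherits(selector, "wl_neuron_selector"))
  nn <- connectome$neurons
  keep <- rep(TRUE, nrow(nn))
  if (!is.null(selector$names)) keep <- keep & nn$name %in% selector$names
  if (!is.null(selector$class)) keep <- keep & nn$class %in% selector$class
  if (!is.null(selector$category))
    keep <- keep & nn$category %in% selector$category
  nn$name[keep]
}

match_connections <- function(connectome, selector) {
  stopifnot(inherits(selector, "wl_synapse_selector"))
  cc <- connectome$connections
  keep <- rep(TRUE, nrow(cc))
  if (!is.null(selector$kind)) keep <- keep & cc$kind %in% selector$kind
  if (!is.null(selector$neurotransmitter))
    keep <- keep & cc$neurotransmitter %in% selector$neurotransmitter
  if (!is.null(selector$pre)) keep <- keep & cc$pre %in% selector$pre
  if (!is.null(selector$post)) keep <- keep & cc$post %in% selector$post
  if (!is.null(selector$pairs)) {
    key <- paste(cc$pre, cc$post, cc$kind)
    pk <- paste(selector$pairs$pre, selector$pairs$post, selector$pairs$kind)
    keep <- keep & key %in% pk
  }
  which(keep)
}

#' Create a network configuration over a connectome
#'
#' @param connectome a `wl_connectome`; the topology is never modified.
#' @param default_model a cell `wl_component` applied to every neuron
#'   without an override (may be `NULL` if every neuron gets one).
#' @return A `wl_network_config`.
#' @export
#' @examples
#' cfg <- network_configuration(celegans_connectome(),
#'                              default_component("izhikevich", "cellDefault"))
network_configuration <- function(connectome, default_model = NULL) {
  stopifnot(inherits(connectome, "wl_connectome"))
  if (!is.null(default_model)) check_cell_component(default_model)
  structure(list(
    connectome = connectome,
    default_model = default_model,
    neuron_overrides = list(),
    param_overrides = list(),
    synapse_rules = list(),
    recorded = data.frame(neuron = character(), variable = character(),
                          stringsAsFactors = FALSE)
  ), class = "wl_network_config")
}

#' @export
print.wl_network_config <- function(x, ...) {
  cat("<network config: ", nrow(x$connectome$neurons), " neurons, ",
      length(x$neuron_overrides), " model override(s), ",
      length(x$synapse_rules), " synapse rule(s), ",
      nrow(x$recorded), " recorded variable(s)>\n", sep = "")
  invisible(x)
}

is_gap_component <- function(component) {
  "vpeer" %in% names(component$type$requirements)
}

is_chemical_synapse_component <- function(component) {
  any(component$type$event_ports == "in") && !is_gap_component(component)
}

is_cell_component <- function(component) {
  # a cell integrates synaptic current and exposes a membrane variable
  length(component$type$state_variables) > 0L &&
    !is_gap_component(component) && !is_chemical_synapse_component(component)
}

check_cell_component <- function(component) {
  stopifnot(inherits(component, "wl_component"))
  if (!is_cell_component(component))
    stop("component '", component$id, "' (type '", component$type$name,
         "') is not a cell model", call. = FALSE)
  invisible(component)
}

#' Assign a cell model to a group of neurons
#'
#' Matched neurons get `component` as a model override; later assignments
#' win. An empty selector match is a warning, not an error.
#'
#' @param config a `wl_network_config`.
#' @param selector a [neuron_selector()].
#' @param component a cell `wl_component`.
#' @return The updated configuration.
#' @export
assign_models <- function(config, selector, component) {
  stopifnot(inherits(config, "wl_network_config"))
  if (!inherits(selector, "wl_neuron_selector"))
    stop("assign_models operates in neuron-selection mode and requires a ",
         "neuron selector", call. = FALSE)
  check_cell_component(component)
  matched <- match_neurons(config$connectome, selector)
  if (length(matched) == 0L)
    warning("selector matched no neurons", call. = FALSE)
  for (n in matched) config$neuron_overrides[[n]] <- component
  config
}

#' Override model parameters for a group of neurons
#'
#' Stores per-neuron parameter overrides applied on top of each neuron's
#' resolved model at export/flatten time; later assignments win per
#' parameter.
#'
#' @param config a `wl_network_config`.
#' @param selector a [neuron_selector()].
#' @param bindings named character vector of quantity strings, e.g.
#'   `c(EL = "-60 mV")`.
#' @return The updated configuration.
#' @export
assign_parameters <- function(config, selector, bindings) {
  stopifnot(inherits(config, "wl_network_config"))
  if (!inherits(selector, "wl_neuron_selector"))
    stop("assign_parameters operates in neuron-parameter mode and requires ",
         "a neuron selector", call. = FALSE)
  matched <- match_neurons(config$connectome, selector)
  if (length(matched) == 0L)
    warning("selector matched no neurons", call. = FALSE)
  bindings <- vapply(bindings, as.character, "")
  for (n in matched) {
    cur <- config$param_overrides[[n]] %||% c()
    cur[names(bindings)] <- bindings
    config$param_overrides[[n]] <- cur
  }
  config
}

#' Assign a synapse model to a group of connections
#'
#' Appends an ordered assignment rule (later rules win). Chemical
#' connections need a chemical synapse component (incoming event port);
#' gap junctions need a gap-junction component (`vpeer` requirement);
#' assigning across kinds is an error.
#'
#' @param config a `wl_network_config`.
#' @param selector a [synapse_selector()].
#' @param component a synapse or gap-junction `wl_component`.
#' @return The updated configuration.
#' @export
assign_synapses <- function(config, selector, component) {
  stopifnot(inherits(config, "wl_network_config"),
            inherits(component, "wl_component"))
  if (!inherits(selector, "wl_synapse_selector"))
    stop("assign_synapses operates in synapse-selection mode and requires ",
         "a synapse selector", call. = FALSE)
  idx <- match_connections(config$connectome, selector)
  kinds <- unique(config$connectome$connections$kind[idx])
  if (is_gap_component(component)) {
    if ("chemical" %in% kinds)
      stop("gap-junction component '", component$id,
           "' assigned to chemical connection(s)", call. = FALSE)
  } else if (is_chemical_synapse_component(component)) {
    if ("gap_junction" %in% kinds)
      stop("chemical synapse component '", component$id,
           "' assigned to gap junction(s)", call. = FALSE)
  } else {
    stop("component '", component$id, "' is neither a chemical synapse ",
         "nor a gap junction", call. = FALSE)
  }
  if (length(idx) == 0L)
    warning("selector matched no connections", call. = FALSE)
  config$synapse_rules[[length(config$synapse_rules) + 1L]] <-
    list(selector = selector, component = component)
  config
}

#' Resolve the cell model of one neuron
#'
#' Override if present, else the default model, with any per-neuron
#' parameter overrides applied (the component is re-instantiated under a
#' neuron-specific id when overrides exist).
#'
#' @param config a `wl_network_config`.
#' @param neuron neuron name.
#' @return A cell `wl_component`.
#' @export
resolved_model <- function(config, neuron) {
  check_neuron(config$connectome, neuron)
  base <- config$neuron_overrides[[neuron]] %||% config$default_model
  if (is.null(base))
    stop("neuron '", neuron, "' has no resolved model (no override and no ",
         "default)", call. = FALSE)
  ov <- config$param_overrides[[neuron]]
  if (is.null(ov)) return(base)
  bindings <- vapply(base$bindings, binding_string, "")
  bindings[names(ov)] <- ov
  instantiate(base$type, paste0(base$id, "__", neuron), bindings)
}

# last matching rule per connection; NA for unmatched
connection_synapse_ids <- function(config) {
  cc <- config$connectome$connections
  assigned <- rep(NA_integer_, nrow(cc))
  for (r in seq_along(config$synapse_rules)) {
    idx <- match_connections(config$connectome,
                             config$synapse_rules[[r]]$selector)
    assigned[idx] <- r
  }
  assigned
}

#' Automatically select recorded variables
#'
#' After configuration is complete, the membrane-potential exposure plus
#' every state variable of each neuron's resolved model is recorded. The
#' rule is idempotent; the selection can be edited afterwards with
#' [set_recorded_variables()].
#'
#' @param config a `wl_network_config` with all neuron models resolvable.
#' @return The updated configuration.
#' @export
auto_select_recorded_variables <- function(config) {
  stopifnot(inherits(config, "wl_network_config"))
  nn <- config$connectome$neurons$name
  rows <- lapply(nn, function(n) {
    model <- resolved_model(config, n)
    vars <- unique(c(intersect("v", model$type$exposures),
                     names(model$type$state_variables)))
    data.frame(neuron = n, variable = vars, stringsAsFactors = FALSE)
  })
  config$recorded <- if (length(rows) > 0L) do.call(rbind, rows)
                     else data.frame(neuron = character(),
                                     variable = character())
  rownames(config$recorded) <- NULL
  config
}

#' @rdname auto_select_recorded_variables
#' @param recorded data.frame with columns `neuron`, `variable`; every
#'   variable must exist on the neuron's resolved model.
#' @export
set_recorded_variables <- function(config, recorded) {
  stopifnot(inherits(config, "wl_network_config"),
            all(c("neuron", "variable") %in% names(recorded)))
  for (i in seq_len(nrow(recorded))) {
    model <- resolved_model(config, recorded$neuron[i])
    ok <- c(model$type$exposures, names(model$type$state_variables))
    if (!recorded$variable[i] %in% ok)
      stop("variable '", recorded$variable[i], "' does not exist on the ",
           "model of neuron '", recorded$neuron[i], "'", call. = FALSE)
  }
  config$recorded <- recorded[c("neuron", "variable")]
  config
}

# fully resolved view: per-neuron components, per-connection synapse
# components; errors if anything is unresolved
resolve_network <- function(config) {
  nn <- config$connectome$neurons$name
  models <- lapply(nn, function(n) resolved_model(config, n))
  names(models) <- nn
  rule_idx <- connection_synapse_ids(config)
  cc <- config$connectome$connections
  if (anyNA(rule_idx)) {
    bad <- which(is.na(rule_idx))[1]
    stop("connection ", cc$pre[bad], " -> ", cc$post[bad], " (", cc$kind[bad],
         ") matches no synapse assignment rule; export refused",
         call. = FALSE)
  }
  synapses <- lapply(rule_idx, function(r)
    config$synapse_rules[[r]]$component)
  list(models = models, synapses = synapses)
}
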