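# NeuroML-style network export: a <Lems> block embedding every dynamics
# template and component instance in use, followed by a <network> block
# with per-model populations, explicit connection lists and
# recorded-variable directives. Gap junctions are single symmetric
# records here; the runtime expands them to two directed conductance
# terms.

#' Export a configured network as XML
#'
#' Requires a fully resolved configuration: every neuron must resolve to
#' a model, every connection must match a synapse rule, and recorded
#' variables must exist on the resolved models (the export refuses
#' otherwise, naming the offending connection). Output is deterministic.
#'
#' @param config a `wl_network_config`.
#' @param path optional output file.
#' @param id network id attribute.
#' @return XML text (invisibly when `path` is given).
#' @export
export_network <- function(config, path = NULL, id = "celegans") {
  stopifnot(inherits(config, "wl_network_config"))
  res <- resolve_network(config)

  # validate recorded variables against resolved models
  for (i in seq_len(nrow(config$recorded))) {
    n <- config$recorded$neuron[i]; v <- config$recorded$variable[i]
    model <- res$models[[n]]
    if (is.null(model))
      stop("recorded variable on unknown neuron '", n, "'", call. = FALSE)
    ok <- c(model$type$exposures, names(model$type$state_variables))
    if (!v %in% ok)
      stop("recorded variable '", v, "' does not exist on the model of ",
           "neuron '", n, "'", call. = FALSE)
  }

  components <- list()
  for (comp in c(res$models, res$synapses)) {
    prev <- components[[comp$id]]
    if (!is.null(prev) && !identical(
      vapply(prev$bindings, binding_string, ""),
      vapply(comp$bindings, binding_string, "")))
      stop("component id '", comp$id, "' used with conflicting bindings",
           call. = FALSE)
    components[[comp$id]] <- comp
  }
  components <- components[order(names(components))]
  types <- list()
  for (comp in components) types[[comp$type$name]] <- comp$type
  types <- types[order(names(types))]

  doc <- xml2::xml_new_root("NetworkExport")
  lems <- xml2::xml_add_child(doc, "Lems")
  write_dimensions_xml(lems, types_dimension_names(types))
  for (ct in types) write_component_type_xml(lems, ct)
  for (comp in components) write_component_xml(lems, comp)

  net <- xml2::xml_add_child(doc, "network", id = id)
  nn <- config$connectome$neurons
  for (i in seq_len(nrow(nn))) {
    xml2::xml_add_child(net, "neuron",
                        name = nn$name[i], class = nn$class[i],
                        category = nn$category[i],
                        x = fmt_num(nn$x[i]), y = fmt_num(nn$y[i]),
                        z = fmt_num(nn$z[i]),
                        model = res$models[[nn$name[i]]]$id)
  }
  cc <- config$connectome$connections
  for (i in seq_len(nrow(cc))) {
    syn <- res$synapses[[i]]
    if (cc$kind[i] == "chemical") {
      xml2::xml_add_child(net, "chemicalConnection",
                          pre = cc$pre[i], post = cc$post[i],
                          synapse = syn$id,
                          multiplicity = fmt_num(cc$multiplicity[i]),
                          neurotransmitter = cc$neurotransmitter[i])
    } else {
      xml2::xml_add_child(net, "gapJunction",
                          a = cc$pre[i], b = cc$post[i],
                          component = syn$id,
                          multiplicity = fmt_num(cc$multiplicity[i]))
    }
  }
  for (i in seq_len(nrow(config$recorded))) {
    xml2::xml_add_child(net, "record",
                        neuron = config$recorded$neuron[i],
                        variable = config$recorded$variable[i])
  }
  text <- as.character(doc)
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Import a network XML document
#'
#' Inverse of [export_network()] on its image: rebuilds the connectome
#' (neurons and connection multiset), the per-neuron model components and
#' the per-connection synapse mapping, and the recorded-variable set.
#'
#' @param document XML text or a file path.
#' @return A `wl_network_config` with explicit per-neuron overrides and
#'   per-connection synapse rules.
#' @export
import_network <- function(document) {
  doc <- xml2::read_xml(document)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "NetworkExport")
    stop("root element must be <NetworkExport>", call. = FALSE)

  lems <- xml2::xml_find_first(root, "Lems")
  types <- list(); components <- list()
  if (!inherits(lems, "xml_missing")) {
    for (node in as.list(xml2::xml_children(lems))) {
      tag <- xml2::xml_name(node)
      if (tag %in% c("Dimension", "Unit")) next
      if (tag == "ComponentType") {
        ct <- read_component_type_xml(node)
        types[[ct$name]] <- ct
      } else if (tag == "Component") {
        id <- xml2::xml_attr(node, "id")
        ct <- types[[xml2::xml_attr(node, "type")]] %||%
          load_core_library()[[xml2::xml_attr(node, "type")]]
        if (is.null(ct))
          stop("component '", id, "' references undeclared type", call. = FALSE)
        attrs <- xml2::xml_attrs(node)
        components[[id]] <-
          instantiate(ct, id, attrs[setdiff(names(attrs), c("id", "type"))])
      } else unsupported(paste0("element <", tag, "> inside <Lems>"))
    }
  }

  net <- xml2::xml_find_first(root, "network")
  if (inherits(net, "xml_missing"))
    stop("missing <network> element", call. = FALSE)
  neuron_rows <- list(); conn_rows <- list(); rec_rows <- list()
  neuron_models <- character(); syn_ids <- character()
  for (node in as.list(xml2::xml_children(net))) {
    tag <- xml2::xml_name(node)
    a <- function(x) xml2::xml_attr(node, x)
    if (tag == "neuron") {
      neuron_rows[[length(neuron_rows) + 1L]] <- data.frame(
        name = a("name"), class = a("class"), category = a("category"),
        x = as.numeric(a("x")), y = as.numeric(a("y")),
        z = as.numeric(a("z")), stringsAsFactors = FALSE)
      neuron_models[a("name")] <- a("model")
    } else if (tag == "chemicalConnection") {
      conn_rows[[length(conn_rows) + 1L]] <- data.frame(
        pre = a("pre"), post = a("post"), kind = "chemical",
        multiplicity = as.numeric(a("multiplicity")),
        neurotransmitter = a("neurotransmitter"), stringsAsFactors = FALSE)
      syn_ids <- c(syn_ids, a("synapse"))
    } else if (tag == "gapJunction") {
      conn_rows[[length(conn_rows) + 1L]] <- data.frame(
        pre = a("a"), post = a("b"), kind = "gap_junction",
        multiplicity = as.numeric(a("multiplicity")),
        neurotransmitter = "none", stringsAsFactors = FALSE)
      syn_ids <- c(syn_ids, a("component"))
    } else if (tag == "record") {
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        neuron = a("neuron"), variable = a("variable"),
        stringsAsFactors = FALSE)
    } else unsupported(paste0("element <", tag, "> inside <network>"))
  }
  neurons <- do.call(rbind, neuron_rows)
  connections <- if (length(conn_rows) > 0L) do.call(rbind, conn_rows)
    else data.frame(pre = character(), post = character(),
                    kind = character(), multiplicity = numeric(),
                    neurotransmitter = character())
  connectome <- load_connectome(neurons, connections)

  config <- network_configuration(connectome, default_model = NULL)
  for (n in names(neuron_models)) {
    comp <- components[[neuron_models[[n]]]]
    if (is.null(comp))
      stop("neuron '", n, "' references undeclared component '",
           neuron_models[[n]], "'", call. = FALSE)
    config$neuron_overrides[[n]] <- comp
  }
  # one explicit-pairs rule per distinct synapse component, in first-use order
  for (sid in unique(syn_ids)) {
    comp <- components[[sid]]
    if (is.null(comp))
      stop("connection references undeclared synapse component '", sid, "'",
           call. = FALSE)
    rows <- which(syn_ids == sid)
    config <- assign_synapses(config,
      synapse_selector(pairs = connections[rows, c("pre", "post", "kind")]),
      comp)
  }
  if (length(rec_rows) > 0L)
    config$recorded <- do.call(rbind, rec_rows)
  config
}
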