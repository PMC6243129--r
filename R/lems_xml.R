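# LEMS XML subset: flat ComponentTypes with time/event-driven dynamics,
# Components with quantity-string bindings, and a ModelAssembly element
# carrying variable/event links. The dialect is frozen in
# inst/xsd/lems-subset.xsd. Structure/ForEach/KineticScheme and other
# constructs outside this subset are rejected on import.

.dim_attrs <- c(mass = "m", length = "l", time = "t", current = "i",
                temperature = "k", amount = "n", luminosity = "j")

# canonical, fully parenthesised serialisation; comparisons in dotted form
serialize_expr <- function(src) {
  d <- expr_deparse(parse_expression(src))
  d <- gsub(" <= ", " .leq. ", d, fixed = TRUE)
  d <- gsub(" >= ", " .geq. ", d, fixed = TRUE)
  d <- gsub(" < ", " .lt. ", d, fixed = TRUE)
  d <- gsub(" > ", " .gt. ", d, fixed = TRUE)
  d <- gsub(" == ", " .eq. ", d, fixed = TRUE)
  d <- gsub(" != ", " .neq. ", d, fixed = TRUE)
  d <- gsub(" and ", " .and. ", d, fixed = TRUE)
  d
}

write_component_type_xml <- function(parent, ct) {
  node <- xml2::xml_add_child(parent, "ComponentType", name = ct$name)
  for (p in names(ct$parameters))
    xml2::xml_add_child(node, "Parameter", name = p,
                        dimension = ct$parameters[[p]])
  for (r in names(ct$requirements))
    xml2::xml_add_child(node, "Requirement", name = r,
                        dimension = ct$requirements[[r]])
  for (e in ct$exposures)
    xml2::xml_add_child(node, "Exposure", name = e)
  for (p in names(ct$event_ports))
    xml2::xml_add_child(node, "EventPort", name = p,
                        direction = ct$event_ports[[p]])
  dyn <- xml2::xml_add_child(node, "Dynamics")
  for (s in names(ct$state_variables))
    xml2::xml_add_child(dyn, "StateVariable", name = s,
                        dimension = ct$state_variables[[s]])
  for (d in names(ct$derived_variables))
    xml2::xml_add_child(dyn, "DerivedVariable", name = d,
                        value = serialize_expr(ct$derived_variables[[d]]))
  for (s in names(ct$time_derivatives))
    xml2::xml_add_child(dyn, "TimeDerivative", variable = s,
                        value = serialize_expr(ct$time_derivatives[[s]]))
  if (length(ct$on_start) > 0L) {
    os <- xml2::xml_add_child(dyn, "OnStart")
    for (s in names(ct$on_start))
      xml2::xml_add_child(os, "StateAssignment", variable = s,
                          value = serialize_expr(ct$on_start[[s]]))
  }
  for (rule in ct$on_conditions) {
    oc <- xml2::xml_add_child(dyn, "OnCondition",
                              test = serialize_expr(rule$test))
    for (s in names(rule$assignments))
      xml2::xml_add_child(oc, "StateAssignment", variable = s,
                          value = serialize_expr(rule$assignments[[s]]))
    if (!is.null(rule$event_out))
      xml2::xml_add_child(oc, "EventOut", port = rule$event_out)
  }
  for (port in names(ct$on_events)) {
    oe <- xml2::xml_add_child(dyn, "OnEvent", port = port)
    for (s in names(ct$on_events[[port]]$assignments))
      xml2::xml_add_child(oe, "StateAssignment", variable = s,
                          value = serialize_expr(
                            ct$on_events[[port]]$assignments[[s]]))
  }
  invisible(node)
}

binding_string <- function(b) {
  if (identical(b$unit, "none")) fmt_num(b$value)
  else paste(fmt_num(b$value), b$unit)
}

write_component_xml <- function(parent, comp) {
  node <- xml2::xml_add_child(parent, "Component", id = comp$id,
                              type = comp$type$name)
  for (p in names(comp$bindings))
    xml2::xml_set_attr(node, p, binding_string(comp$bindings[[p]]))
  invisible(node)
}

write_dimensions_xml <- function(parent, dim_names) {
  std <- standard_dimensions()
  for (dn in dim_names) {
    node <- xml2::xml_add_child(parent, "Dimension", name = dn)
    exps <- unclass(std[[dn]])
    for (q in names(.dim_attrs)) {
      if (exps[[q]] != 0L)
        xml2::xml_set_attr(node, .dim_attrs[[q]], as.character(exps[[q]]))
    }
  }
  ut <- unit_table()
  for (k in seq_len(nrow(ut))) {
    if (!ut$dimension[k] %in% dim_names) next
    xml2::xml_add_child(parent, "Unit", symbol = ut$symbol[k],
                        dimension = ut$dimension[k],
                        power = as.character(ut$power[k]))
  }
}

# dimension names used by a set of types (declared + none for safety)
types_dimension_names <- function(types) {
  used <- unique(unlist(lapply(types, function(ct)
    c(unname(ct$parameters), unname(ct$state_variables),
      unname(ct$requirements), "time", "dimensionless"))))
  intersect(names(standard_dimensions()), used)  # canonical order
}

#' Export a neuron model as LEMS XML
#'
#' Embeds the dimension/unit tables, the ComponentType definition of
#' every type used (sorted by name), the Component instances (model
#' order) and the link assembly. The output is deterministic and
#' re-importable by [import_lems()] with semantic equality.
#'
#' @param model a `wl_neuron_model`.
#' @param path optional output file.
#' @return XML text (invisibly when `path` is given).
#' @export
export_lems <- function(model, path = NULL) {
  stopifnot(inherits(model, "wl_neuron_model"))
  doc <- xml2::xml_new_root("Lems")
  types <- list()
  for (comp in model$components) types[[comp$type$name]] <- comp$type
  if (length(types) > 0L) types <- types[order(names(types))]
  write_dimensions_xml(doc, types_dimension_names(types))
  for (ct in types) write_component_type_xml(doc, ct)
  for (comp in model$components) write_component_xml(doc, comp)
  asm <- xml2::xml_add_child(doc, "ModelAssembly")
  if (!is.null(model$root)) xml2::xml_set_attr(asm, "root", model$root)
  for (lk in model$links)
    xml2::xml_add_child(asm, "VariableLink", from = lk$from, to = lk$to)
  for (lk in model$event_links)
    xml2::xml_add_child(asm, "EventLink", from = lk$from, to = lk$to)
  text <- as.character(doc)
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

unsupported <- function(what) {
  stop("unsupported LEMS construct: ", what, call. = FALSE)
}

read_component_type_xml <- function(node) {
  name <- xml2::xml_attr(node, "name")
  parameters <- c(); requirements <- c(); exposures <- character()
  event_ports <- c()
  state_variables <- c(); derived_variables <- c(); time_derivatives <- c()
  on_start <- c(); on_conditions <- list(); on_events <- list()
  for (ch in as.list(xml2::xml_children(node))) {
    tag <- xml2::xml_name(ch)
    if (tag == "Parameter") {
      parameters[xml2::xml_attr(ch, "name")] <- xml2::xml_attr(ch, "dimension")
    } else if (tag == "Requirement") {
      requirements[xml2::xml_attr(ch, "name")] <-
        xml2::xml_attr(ch, "dimension")
    } else if (tag == "Exposure") {
      exposures <- c(exposures, xml2::xml_attr(ch, "name"))
    } else if (tag == "EventPort") {
      event_ports[xml2::xml_attr(ch, "name")] <-
        xml2::xml_attr(ch, "direction")
    } else if (tag == "Dynamics") {
      for (d in as.list(xml2::xml_children(ch))) {
        dtag <- xml2::xml_name(d)
        if (dtag == "StateVariable") {
          state_variables[xml2::xml_attr(d, "name")] <-
            xml2::xml_attr(d, "dimension")
        } else if (dtag == "DerivedVariable") {
          derived_variables[xml2::xml_attr(d, "name")] <-
            xml2::xml_attr(d, "value")
        } else if (dtag == "TimeDerivative") {
          time_derivatives[xml2::xml_attr(d, "variable")] <-
            xml2::xml_attr(d, "value")
        } else if (dtag == "OnStart") {
          for (a in as.list(xml2::xml_children(d))) {
            if (xml2::xml_name(a) != "StateAssignment")
              unsupported(paste0("element <", xml2::xml_name(a),
                                 "> inside <OnStart>"))
            on_start[xml2::xml_attr(a, "variable")] <-
              xml2::xml_attr(a, "value")
          }
        } else if (dtag == "OnCondition") {
          rule <- list(test = xml2::xml_attr(d, "test"),
                       assignments = c(), event_out = NULL)
          for (a in as.list(xml2::xml_children(d))) {
            atag <- xml2::xml_name(a)
            if (atag == "StateAssignment") {
              rule$assignments[xml2::xml_attr(a, "variable")] <-
                xml2::xml_attr(a, "value")
            } else if (atag == "EventOut") {
              rule$event_out <- xml2::xml_attr(a, "port")
            } else unsupported(paste0("element <", atag,
                                      "> inside <OnCondition>"))
          }
          on_conditions[[length(on_conditions) + 1L]] <- rule
        } else if (dtag == "OnEvent") {
          assignments <- c()
          for (a in as.list(xml2::xml_children(d))) {
            if (xml2::xml_name(a) != "StateAssignment")
              unsupported(paste0("element <", xml2::xml_name(a),
                                 "> inside <OnEvent>"))
            assignments[xml2::xml_attr(a, "variable")] <-
              xml2::xml_attr(a, "value")
          }
          on_events[[xml2::xml_attr(d, "port")]] <-
            list(assignments = assignments)
        } else {
          unsupported(paste0("dynamics element <", dtag, ">"))
        }
      }
    } else {
      unsupported(paste0("element <", tag, "> inside <ComponentType>"))
    }
  }
  component_type(name, parameters = parameters,
                 state_variables = state_variables,
                 derived_variables = derived_variables,
                 time_derivatives = time_derivatives,
                 on_start = on_start, on_conditions = on_conditions,
                 on_events = on_events, event_ports = event_ports,
                 exposures = exposures, requirements = requirements)
}

#' Import a LEMS XML document
#'
#' Inverse of [export_lems()] on its image. ComponentTypes declared in
#' the document are used first; Components referencing core-library type
#' names resolve against [load_core_library()]. Constructs outside the
#' implemented subset raise an unsupported-construct error.
#'
#' @param document XML text or a file path.
#' @return A `wl_neuron_model`.
#' @export
import_lems <- function(document) {
  doc <- xml2::read_xml(document)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Lems")
    stop("root element must be <Lems>", call. = FALSE)
  types <- list()
  components <- list()
  links <- list(); event_links <- list(); model_root <- NULL
  for (node in as.list(xml2::xml_children(root))) {
    tag <- xml2::xml_name(node)
    if (tag %in% c("Dimension", "Unit")) {
      next  # fixed built-in tables; declarations are informative
    } else if (tag == "ComponentType") {
      ct <- read_component_type_xml(node)
      types[[ct$name]] <- ct
    } else if (tag == "Component") {
      id <- xml2::xml_attr(node, "id")
      type_name <- xml2::xml_attr(node, "type")
      ct <- types[[type_name]] %||% load_core_library()[[type_name]]
      if (is.null(ct))
        stop("component '", id, "' references undeclared type '",
             type_name, "'", call. = FALSE)
      attrs <- xml2::xml_attrs(node)
      bindings <- attrs[setdiff(names(attrs), c("id", "type"))]
      components[[length(components) + 1L]] <-
        instantiate(ct, id, bindings)
    } else if (tag == "ModelAssembly") {
      model_root <- xml2::xml_attr(node, "root")
      if (is.na(model_root)) model_root <- NULL
      for (lk in as.list(xml2::xml_children(node))) {
        ltag <- xml2::xml_name(lk)
        entry <- list(from = xml2::xml_attr(lk, "from"),
                      to = xml2::xml_attr(lk, "to"))
        if (ltag == "VariableLink") {
          links[[length(links) + 1L]] <- entry
        } else if (ltag == "EventLink") {
          event_links[[length(event_links) + 1L]] <- entry
        } else unsupported(paste0("element <", ltag,
                                  "> inside <ModelAssembly>"))
      }
    } else {
      unsupported(paste0("top-level element <", tag, ">"))
    }
  }
  compose_model(components, links = links, event_links = event_links,
                root = model_root)
}
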