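# Building-block system for declarative neuron models: a ComponentType is
# a dynamics template (parameters, state variables, derived variables,
# time derivatives, event rules); a Component binds every parameter of a
# type to a value with a unit. Two Components of one type share identical
# dynamics structure and differ only in their bindings.

#' Create a dynamics template (ComponentType)
#'
#' A ComponentType describes model dynamics separately from parameter
#' values: time-driven changes (time derivatives, derived variables) and
#' event-driven changes (condition rules with state assignments and event
#' emission, handlers for incoming events). Expressions use the language
#' of [parse_expression()]; the time symbol `t` is always in scope.
#'
#' @param name type name.
#' @param parameters named character vector: parameter name -> dimension
#'   name (see [standard_dimensions()]).
#' @param state_variables named character vector: state name -> dimension
#'   name.
#' @param derived_variables named character vector: name -> expression;
#'   dimensions are inferred.
#' @param time_derivatives named character vector: state name ->
#'   expression for its time derivative (dimension of state / time).
#' @param on_start named character vector: state name -> initialisation
#'   expression.
#' @param on_conditions list of condition rules, each a list with `test`
#'   (predicate expression), `assignments` (named character vector) and
#'   optional `event_out` (output port name). Rules fire on the
#'   false-to-true transition of the test.
#' @param on_events named list: input port name -> list with
#'   `assignments` (named character vector).
#' @param event_ports named character vector: port name -> `"in"` or
#'   `"out"`.
#' @param exposures character vector of variable names exported to other
#'   components.
#' @param requirements named character vector: variable name expected
#'   from a linked component -> dimension name.
#' @return A validated `wl_component_type`.
#' @export
component_type <- function(name,
                           parameters = c(),
                           state_variables = c(),
                           derived_variables = c(),
                           time_derivatives = c(),
                           on_start = c(),
                           on_conditions = list(),
                           on_events = list(),
                           event_ports = c(),
                           exposures = character(),
                           requirements = c()) {
  ct <- structure(list(
    name = name,
    parameters = as_named_chr(parameters),
    state_variables = as_named_chr(state_variables),
    derived_variables = as_named_chr(derived_variables),
    time_derivatives = as_named_chr(time_derivatives),
    on_start = as_named_chr(on_start),
    on_conditions = on_conditions,
    on_events = on_events,
    event_ports = as_named_chr(event_ports),
    exposures = exposures,
    requirements = as_named_chr(requirements)
  ), class = "wl_component_type")
  validate_component_type(ct)
  ct
}

as_named_chr <- function(x) {
  if (length(x) == 0L) return(setNames(character(), character()))
  stopifnot(!is.null(names(x)))
  vapply(x, as.character, "")
}

#' @export
print.wl_component_type <- function(x, ...) {
  cat("<component type '", x$name, "': ",
      length(x$parameters), " parameter(s), ",
      length(x$state_variables), " state variable(s), ",
      length(x$derived_variables), " derived variable(s)>\n", sep = "")
  invisible(x)
}

# Topologically order derived variables by their mutual dependencies;
# error on cycles.
derived_order <- function(ct) {
  dnames <- names(ct$derived_variables)
  if (length(dnames) == 0L) return(character())
  deps <- lapply(ct$derived_variables, function(src)
    intersect(expr_variables(parse_expression(src)), dnames))
  names(deps) <- dnames
  ordered <- character()
  remaining <- dnames
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(n)
      all(deps[[n]] %in% ordered), TRUE)]
    if (length(ready) == 0L)
      stop("cyclic derived-variable dependency among: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

# dimensions (as wl_dimension) of every symbol a type's expressions may use
type_symbol_dims <- function(ct) {
  std <- standard_dimensions()
  look <- function(x) {
    out <- lapply(unname(x), function(d) {
      dd <- std[[d]]
      if (is.null(dd)) stop("unknown dimension name '", d, "' in type '",
                            ct$name, "'", call. = FALSE)
      dd
    })
    names(out) <- names(x)
    out
  }
  dims <- c(look(ct$parameters), look(ct$state_variables),
            look(ct$requirements), list(t = std$time))
  for (dv in derived_order(ct)) {
    dims[[dv]] <- expr_dimension(parse_expression(ct$derived_variables[[dv]]),
                                 dims)
  }
  dims
}

validate_component_type <- function(ct) {
  all_names <- c(names(ct$parameters), names(ct$state_variables),
                 names(ct$derived_variables), names(ct$requirements), "t")
  dup <- all_names[duplicated(all_names)]
  if (length(dup) > 0L)
    stop("type '", ct$name, "': shadowed symbol(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  dims <- type_symbol_dims(ct)  # also checks derived cycles + dimensions
  known <- names(dims)
  check_expr_symbols <- function(src, what) {
    missing <- setdiff(expr_variables(parse_expression(src)), known)
    if (length(missing) > 0L)
      stop("type '", ct$name, "', ", what, ": unresolved symbol(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  std <- standard_dimensions()
  for (sv in names(ct$time_derivatives)) {
    if (!sv %in% names(ct$state_variables))
      stop("type '", ct$name, "': time derivative for unknown state '",
           sv, "'", call. = FALSE)
    src <- ct$time_derivatives[[sv]]
    check_expr_symbols(src, paste0("d", sv, "/dt"))
    want <- dim_divide(dims[[sv]], std$time)
    got <- expr_dimension(parse_expression(src), dims)
    if (!dim_equal(want, got))
      stop("type '", ct$name, "': d", sv, "/dt has wrong dimension",
           call. = FALSE)
  }
  for (sv in names(ct$on_start)) {
    if (!sv %in% names(ct$state_variables))
      stop("type '", ct$name, "': on-start assignment to unknown state '",
           sv, "'", call. = FALSE)
    check_expr_symbols(ct$on_start[[sv]], "on-start")
    if (!dim_equal(dims[[sv]],
                   expr_dimension(parse_expression(ct$on_start[[sv]]), dims)))
      stop("type '", ct$name, "': on-start assignment to '", sv,
           "' has wrong dimension", call. = FALSE)
  }
  for (rule in ct$on_conditions) {
    check_expr_symbols(rule$test, "condition test")
    expr_dimension(parse_expression(rule$test), dims)  # comparability check
    for (sv in names(rule$assignments)) {
      if (!sv %in% names(ct$state_variables))
        stop("type '", ct$name, "': condition assigns unknown state '",
             sv, "'", call. = FALSE)
      check_expr_symbols(rule$assignments[[sv]], "condition assignment")
    }
    if (!is.null(rule$event_out)) {
      if (!identical(unname(ct$event_ports[rule$event_out]), "out"))
        stop("type '", ct$name, "': event emitted on unknown or non-output ",
             "port '", rule$event_out, "'", call. = FALSE)
    }
  }
  for (port in names(ct$on_events)) {
    if (!identical(unname(ct$event_ports[port]), "in"))
      stop("type '", ct$name, "': handler for unknown or non-input port '",
           port, "'", call. = FALSE)
    for (sv in names(ct$on_events[[port]]$assignments)) {
      if (!sv %in% names(ct$state_variables))
        stop("type '", ct$name, "': event handler assigns unknown state '",
             sv, "'", call. = FALSE)
      check_expr_symbols(ct$on_events[[port]]$assignments[[sv]],
                         "event assignment")
    }
  }
  defined <- c(names(ct$state_variables), names(ct$derived_variables))
  bad <- setdiff(ct$exposures, defined)
  if (length(bad) > 0L)
    stop("type '", ct$name, "': exposure(s) reference undefined variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(ct)
}

#' Dimension (as `wl_dimension`) of a variable or exposure of a type
#'
#' @param ct a `wl_component_type`.
#' @param var variable name (parameter, state, derived or requirement).
#' @return A `wl_dimension`.
#' @export
type_variable_dimension <- function(ct, var) {
  dims <- type_symbol_dims(ct)
  d <- dims[[var]]
  if (is.null(d))
    stop("type '", ct$name, "' has no variable '", var, "'", call. = FALSE)
  d
}

#' Parameterize a dynamics template into a Component
#'
#' Every parameter of the type must be bound exactly once with a value
#' whose unit is dimensionally consistent with the parameter's declared
#' dimension. All binding problems (unbound, unknown, dimension mismatch)
#' are reported together.
#'
#' @param type a `wl_component_type`.
#' @param id component instance id.
#' @param bindings named character vector or list; each entry a quantity
#'   string such as `"0.2 nF"`, `"-65 mV"` or `"0.02"` (dimensionless).
#' @return A `wl_component`; the SI value of each binding is precomputed.
#' @export
#' @examples
#' lib <- load_core_library()
#' instantiate(lib$pulseGenerator, "stim",
#'             c(delay = "10 ms", duration = "50 ms", amplitude = "0.5 nA"))
instantiate <- function(type, id, bindings = c()) {
  stopifnot(inherits(type, "wl_component_type"))
  bindings <- vapply(bindings, as.character, "")
  problems <- character()
  unknown <- setdiff(names(bindings), names(type$parameters))
  for (p in unknown)
    problems <- c(problems, paste0("unknown parameter '", p, "'"))
  unbound <- setdiff(names(type$parameters), names(bindings))
  for (p in unbound)
    problems <- c(problems, paste0("parameter '", p, "' is unbound"))
  std <- standard_dimensions()
  parsed <- list()
  for (p in intersect(names(bindings), names(type$parameters))) {
    q <- tryCatch(parse_quantity(bindings[[p]]), error = function(e) e)
    if (inherits(q, "error")) {
      problems <- c(problems, paste0("parameter '", p, "': ",
                                     conditionMessage(q)))
      next
    }
    want <- std[[type$parameters[[p]]]]
    got <- unit_dimension(q$unit)
    if (!dim_equal(want, got)) {
      problems <- c(problems, paste0(
        "parameter '", p, "': unit '", q$unit,
        "' is dimensionally inconsistent with '", type$parameters[[p]], "'"))
      next
    }
    parsed[[p]] <- c(q, list(si = quantity_to_si(q$value, q$unit)))
  }
  if (length(problems) > 0L)
    stop("cannot instantiate type '", type$name, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  structure(list(id = id, type = type, bindings = parsed),
            class = "wl_component")
}

#' @export
print.wl_component <- function(x, ...) {
  cat("<component '", x$id, "' of type '", x$type$name, "' (",
      length(x$bindings), " binding(s))>\n", sep = "")
  invisible(x)
}

# SI-scaled parameter values of a component
component_si_parameters <- function(comp) {
  vapply(comp$bindings, function(b) b$si, 0)
}

parse_link_ref <- function(ref) {
  parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("link endpoint '", ref, "' must have the form component/variable",
         call. = FALSE)
  list(component = parts[1], variable = parts[2])
}

#' Compose components into a neuron model
#'
#' Wires a set of parameterized components into one model: variable links
#' connect a component's exposure to another component's requirement;
#' event links connect an output event port to an input event port. Every
#' requirement must be satisfied by exactly one link, link endpoints must
#' exist and be dimension-compatible, and duplicate links are refused.
#'
#' @param components list of `wl_component`s (ids must be unique).
#' @param links list of variable links, each `list(from = "comp/exposure",
#'   to = "comp/requirement")`.
#' @param event_links list of event links, each
#'   `list(from = "comp/outPort", to = "comp/inPort")`.
#' @param root id of the root (cell) component; defaults to the first.
#' @return A `wl_neuron_model`.
#' @export
compose_model <- function(components, links = list(), event_links = list(),
                          root = NULL) {
  ids <- vapply(components, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate component id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(components) <- ids
  if (is.null(root) && length(ids) > 0L) root <- ids[[1]]
  if (!is.null(root) && !root %in% ids)
    stop("unknown root component '", root, "'", call. = FALSE)

  seen <- character()
  satisfied <- character()  # "comp/requirement"
  for (lk in links) {
    key <- paste(lk$from, lk$to, sep = " -> ")
    if (key %in% seen) stop("duplicate link ", key, call. = FALSE)
    seen <- c(seen, key)
    from <- parse_link_ref(lk$from); to <- parse_link_ref(lk$to)
    for (e in list(from, to)) {
      if (!e$component %in% ids)
        stop("link references unknown component '", e$component, "'",
             call. = FALSE)
    }
    ft <- components[[from$component]]$type
    tt <- components[[to$component]]$type
    if (!from$variable %in% ft$exposures)
      stop("'", from$variable, "' is not an exposure of component '",
           from$component, "'", call. = FALSE)
    if (!to$variable %in% names(tt$requirements))
      stop("'", to$variable, "' is not a requirement of component '",
           to$component, "'", call. = FALSE)
    dfrom <- type_variable_dimension(ft, from$variable)
    dto <- standard_dimensions()[[tt$requirements[[to$variable]]]]
    if (!dim_equal(dfrom, dto))
      stop("dimension-incompatible link ", key, call. = FALSE)
    satisfied <- c(satisfied, lk$to)
  }
  for (lk in event_links) {
    from <- parse_link_ref(lk$from); to <- parse_link_ref(lk$to)
    for (e in list(from, to)) {
      if (!e$component %in% ids)
        stop("event link references unknown component '", e$component, "'",
             call. = FALSE)
    }
    if (!identical(unname(components[[from$component]]$type$event_ports[
      from$variable]), "out"))
      stop("'", from$variable, "' is not an output event port of '",
           from$component, "'", call. = FALSE)
    if (!identical(unname(components[[to$component]]$type$event_ports[
      to$variable]), "in"))
      stop("'", to$variable, "' is not an input event port of '",
           to$component, "'", call. = FALSE)
  }

  required <- unlist(lapply(components, function(cp) {
    reqs <- names(cp$type$requirements)
    if (length(reqs) == 0L) character() else paste(cp$id, reqs, sep = "/")
  }))
  unresolved <- setdiff(required, satisfied)
  if (length(unresolved) > 0L)
    stop("unresolved requirement(s): ", paste(unresolved, collapse = ", "),
         call. = FALSE)
  over <- satisfied[duplicated(satisfied)]
  if (length(over) > 0L)
    stop("requirement(s) satisfied more than once: ",
         paste(unique(over), collapse = ", "), call. = FALSE)

  structure(list(components = components, links = links,
                 event_links = event_links, root = root),
            class = "wl_neuron_model")
}

#' @export
print.wl_neuron_model <- function(x, ...) {
  cat("<neuron model: root '", x$root, "', ",
      length(x$components), " component(s), ",
      length(x$links), " link(s), ",
      length(x$event_links), " event link(s)>\n", sep = "")
  invisible(x)
}

# structural equality of two models (semantic round-trip check)
model_equal <- function(a, b, tol = 1e-12) {
  if (!setequal(names(a$components), names(b$components))) return(FALSE)
  for (id in names(a$components)) {
    ca <- a$components[[id]]; cb <- b$components[[id]]
    if (!identical(ca$type$name, cb$type$name)) return(FALSE)
    if (!setequal(names(ca$bindings), names(cb$bindings))) return(FALSE)
    for (p in names(ca$bindings)) {
      if (abs(ca$bindings[[p]]$si - cb$bindings[[p]]$si) >
          tol * max(1, abs(ca$bindings[[p]]$si))) return(FALSE)
    }
  }
  key <- function(l) sort(vapply(l, function(x) paste(x$from, x$to), ""))
  identical(key(a$links), key(b$links)) &&
    identical(key(a$event_links), key(b$event_links)) &&
    identical(a$root, b$root)
}
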