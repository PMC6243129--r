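# Reference interpreter: flattens a composed model or a configured
# network into a state-update system (compiled expression closures, an
# ordered evaluation plan, explicit requirement wiring and event routes)
# and integrates it. Internally everything is SI (volts, seconds, amps);
# user-facing times are ms and injected currents nA. Default integrator
# is forward Euler (dt 0.05 ms); classic RK4 is available as a
# cross-check. Conditions are edge-triggered and tested after each state
# update; reset assignments are applied before synaptic event
# propagation within the same step; simultaneous events are delivered in
# unit-name order.

compile_type_dynamics <- function(ct) {
  list(
    derived = lapply(ct$derived_variables[derived_order(ct)],
                     function(src) expr_compile(parse_expression(src))),
    derivs = lapply(ct$time_derivatives,
                    function(src) expr_compile(parse_expression(src))),
    on_start = lapply(ct$on_start,
                      function(src) expr_compile(parse_expression(src))),
    conditions = lapply(ct$on_conditions, function(rule) list(
      test = expr_compile(parse_expression(rule$test)),
      assigns = lapply(rule$assignments,
                       function(src) expr_compile(parse_expression(src))),
      event_out = rule$event_out)),
    on_events = lapply(ct$on_events, function(h) list(
      assigns = lapply(h$assignments,
                       function(src) expr_compile(parse_expression(src)))))
  )
}

new_unit <- function(id, component) {
  list(id = id, type = component$type,
       params = component_si_parameters(component),
       states = names(component$type$state_variables),
       compiled = NULL)  # filled by flatten via type cache
}

# requirement wiring entry: req name -> list(unit, var, scale)
# current sources for cells: list of list(unit, var, sign, weight)

#' Flatten a model or network into a state-update system
#'
#' Produces the ordered evaluation plan the interpreter executes: per
#' unit (cell, synapse instance or sub-component), compiled derived
#' variables in dependency order, time derivatives, edge-triggered
#' condition rules and event handlers; plus explicit requirement wiring
#' between units and event routes from output to input ports. Cyclic
#' derived-variable dependencies are an error.
#'
#' @param x a `wl_neuron_model` or `wl_network_config`.
#' @param ... unused.
#' @return A `wl_update_system`.
#' @export
flatten <- function(x, ...) UseMethod("flatten")

#' @export
flatten.wl_neuron_model <- function(x, ...) {
  type_cache <- list()
  units <- list()
  for (comp in x$components) {
    u <- new_unit(comp$id, comp)
    tc <- type_cache[[comp$type$name]]
    if (is.null(tc)) {
      tc <- compile_type_dynamics(comp$type)
      type_cache[[comp$type$name]] <- tc
    }
    u$compiled <- tc
    units[[u$id]] <- u
  }
  wiring <- lapply(units, function(u) list())
  for (lk in x$links) {
    from <- parse_link_ref(lk$from); to <- parse_link_ref(lk$to)
    wiring[[to$component]][[to$variable]] <-
      list(unit = from$component, var = from$variable, scale = 1)
  }
  routes <- list()
  for (lk in x$event_links) {
    from <- parse_link_ref(lk$from); to <- parse_link_ref(lk$to)
    routes[[from$component]] <- c(routes[[from$component]],
                                  list(list(unit = to$component,
                                            port = to$variable)))
  }
  structure(list(
    units = units, wiring = wiring, event_routes = routes,
    current_sources = setNames(vector("list", length(units)), names(units)),
    cells = if (is.null(x$root)) character() else x$root,
    kind = "model"
  ), class = "wl_update_system")
}

#' @export
flatten.wl_network_config <- function(x, ...) {
  res <- resolve_network(x)
  type_cache <- list()
  get_compiled <- function(ct) {
    tc <- type_cache[[ct$name]]
    if (is.null(tc)) {
      tc <- compile_type_dynamics(ct)
      type_cache[[ct$name]] <<- tc
    }
    tc
  }
  units <- list(); wiring <- list(); routes <- list()
  current_sources <- list()
  neuron_names <- x$connectome$neurons$name
  for (n in neuron_names) {
    comp <- res$models[[n]]
    u <- new_unit(n, comp)
    u$compiled <- get_compiled(comp$type)
    units[[n]] <- u
    wiring[[n]] <- list()
    current_sources[[n]] <- list()
  }
  # membrane variable supplied to synapses; dimensionless cells follow the
  # mV-coded convention and are scaled to volts
  v_scale <- function(cell_type) {
    d <- cell_type$state_variables[["v"]]
    if (identical(d, "dimensionless")) 1e-3 else 1
  }
  cc <- x$connectome$connections
  for (i in seq_len(nrow(cc))) {
    comp <- res$synapses[[i]]
    uid <- sprintf("syn%04d:%s->%s", i, cc$pre[i], cc$post[i])
    u <- new_unit(uid, comp)
    u$compiled <- get_compiled(comp$type)
    units[[uid]] <- u
    mult <- cc$multiplicity[i]
    if (cc$kind[i] == "chemical") {
      post <- cc$post[i]; pre <- cc$pre[i]
      wiring[[uid]] <- list(v = list(unit = post, var = "v",
                                     scale = v_scale(units[[post]]$type)))
      in_ports <- names(comp$type$event_ports[comp$type$event_ports == "in"])
      routes[[pre]] <- c(routes[[pre]],
                         list(list(unit = uid, port = in_ports[1])))
      current_sources[[post]] <- c(current_sources[[post]],
                                   list(list(unit = uid, var = "i",
                                             weight = mult)))
    } else {  # gap junction: two directed conductance terms
      a <- cc$pre[i]; b <- cc$post[i]
      wiring[[uid]] <- list(
        v = list(unit = a, var = "v", scale = v_scale(units[[a]]$type)),
        vpeer = list(unit = b, var = "v",
                     scale = v_scale(units[[b]]$type)))
      current_sources[[a]] <- c(current_sources[[a]],
                                list(list(unit = uid, var = "i",
                                          weight = mult)))
      current_sources[[b]] <- c(current_sources[[b]],
                                list(list(unit = uid, var = "i",
                                          weight = -mult)))
    }
  }
  structure(list(
    units = units, wiring = wiring, event_routes = routes,
    current_sources = current_sources,
    cells = neuron_names, kind = "network"
  ), class = "wl_update_system")
}

#' @export
print.wl_update_system <- function(x, ...) {
  cat("<update system: ", length(x$units), " unit(s), ",
      length(x$cells), " cell(s)>\n", sep = "")
  invisible(x)
}

#' Piecewise-constant current waveform
#'
#' Value is `values[i]` on `[breaks[i], breaks[i+1])` (last value holds
#' until the experiment end) and 0 before `breaks[1]`.
#'
#' @param breaks increasing times, ms.
#' @param values currents, nA (same length as `breaks`).
#' @return A `wl_waveform`.
#' @export
piecewise_waveform <- function(breaks, values) {
  stopifnot(length(breaks) == length(values), !is.unsorted(breaks),
            all(is.finite(values)))
  structure(list(breaks = breaks, values = values), class = "wl_waveform")
}

#' @rdname piecewise_waveform
#' @param t0,t1 pulse start/stop, ms.
#' @param amplitude pulse current, nA.
#' @export
pulse_waveform <- function(t0, t1, amplitude) {
  stopifnot(t0 < t1)
  piecewise_waveform(c(t0, t1), c(amplitude, 0))
}

#' @rdname piecewise_waveform
#' @param w a `wl_waveform`.
#' @param t time, ms.
#' @return Current at `t`, nA.
#' @export
waveform_value <- function(w, t) {
  i <- findInterval(t, w$breaks)
  ifelse(i == 0, 0, w$values[pmax(i, 1)])
}

#' Specify a simulation
#'
#' @param target a `wl_neuron_model`, `wl_network_config` or
#'   pre-flattened `wl_update_system`.
#' @param duration total simulated time, ms.
#' @param dt integration step, ms (`0 < dt <= duration`).
#' @param injections list of `list(target = <unit/neuron id>,
#'   waveform = <wl_waveform>)`; currents in nA added to the target
#'   cell's synaptic-current slot.
#' @param record data.frame with columns `unit` (or `neuron`) and
#'   `variable`; `NULL` records every state variable and exposure of
#'   every unit (for networks, of every neuron).
#' @param method `"euler"` (default) or `"rk4"` (cross-check).
#' @return A `wl_simulation_spec`.
#' @export
simulation_spec <- function(target, duration, dt = 0.05, injections = list(),
                            record = NULL, method = c("euler", "rk4")) {
  method <- match.arg(method)
  if (!(is.numeric(dt) && dt > 0 && dt <= duration))
    stop("dt must satisfy 0 < dt <= duration", call. = FALSE)
  system <- if (inherits(target, "wl_update_system")) target
            else flatten(target)
  for (inj in injections) {
    if (!inj$target %in% names(system$units))
      stop("injection targets unknown unit '", inj$target, "'",
           call. = FALSE)
    stopifnot(inherits(inj$waveform, "wl_waveform"))
  }
  structure(list(system = system, duration = duration, dt = dt,
                 injections = injections, record = record, method = method),
            class = "wl_simulation_spec")
}

default_record_table <- function(system) {
  targets <- if (system$kind == "network") system$cells
             else names(system$units)
  rows <- lapply(targets, function(uid) {
    u <- system$units[[uid]]
    vars <- unique(c(u$states, u$type$exposures))
    if (length(vars) == 0L) return(NULL)
    data.frame(unit = uid, variable = vars, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a simulation
#'
#' Deterministic given the spec: no hidden randomness. Events are applied
#' at the step where their condition first becomes true (edge-triggered);
#' spike times are reported at the time of the post-update state in which
#' the threshold test fired. Numerical overflow aborts with the time and
#' unit name.
#'
#' @param spec a [simulation_spec()].
#' @return A `wl_result_set`: uniform time grid `time_ms` of length
#'   `floor(duration/dt) + 1`, a trace matrix with one column per
#'   recorded `(unit, variable)` (SI units), and per-cell spike times in
#'   ms.
#' @export
run_simulation <- function(spec) {
  stopifnot(inherits(spec, "wl_simulation_spec"))
  system <- spec$system
  units <- system$units
  unit_ids <- names(units)
  dt_s <- spec$dt * 1e-3
  n_steps <- floor(spec$duration / spec$dt)

  # per-unit persistent environments
  envs <- list()
  for (uid in unit_ids) {
    e <- new.env(parent = baseenv())
    p <- units[[uid]]$params
    for (nm in names(p)) assign(nm, p[[nm]], envir = e)
    for (s in units[[uid]]$states) assign(s, 0, envir = e)
    assign("t", 0, envir = e)
    envs[[uid]] <- e
  }

  injections_by_target <- split(
    spec$injections,
    vapply(spec$injections, `[[`, "", "target"))

  # topological order for the per-step refresh: a unit must come after
  # any unit whose *derived* variables it consumes, either through
  # requirement wiring or through summed current sources (state
  # variables are always available from the previous update, so they
  # impose no ordering)
  derived_names_of <- function(uid)
    names(units[[uid]]$type$derived_variables)
  dep_order <- {
    deps <- lapply(unit_ids, function(uid) {
      d <- character()
      for (w in system$wiring[[uid]] %||% list()) {
        if (w$var %in% derived_names_of(w$unit)) d <- c(d, w$unit)
      }
      for (src in system$current_sources[[uid]] %||% list()) {
        if (src$var %in% derived_names_of(src$unit)) d <- c(d, src$unit)
      }
      unique(d)
    })
    names(deps) <- unit_ids
    remaining <- unit_ids
    ordered <- character()
    while (length(remaining) > 0L) {
      ready <- remaining[vapply(remaining, function(uid)
        all(!(deps[[uid]] %in% remaining)), TRUE)]
      if (length(ready) == 0L) { ordered <- c(ordered, remaining); break }
      ordered <- c(ordered, ready)
      remaining <- setdiff(remaining, ready)
    }
    ordered
  }

  sum_currents <- function(uid, t_ms) {
    total <- 0
    for (src in system$current_sources[[uid]] %||% list()) {
      total <- total + src$weight * get(src$var, envir = envs[[src$unit]])
    }
    for (inj in injections_by_target[[uid]] %||% list()) {
      total <- total + waveform_value(inj$waveform, t_ms) * 1e-9
    }
    total
  }

  refresh_unit <- function(uid, t_ms) {
    e <- envs[[uid]]
    for (rq in names(system$wiring[[uid]] %||% list())) {
      w <- system$wiring[[uid]][[rq]]
      assign(rq, w$scale * get(w$var, envir = envs[[w$unit]]), envir = e)
    }
    if ("iSyn" %in% names(units[[uid]]$type$requirements) &&
        is.null(system$wiring[[uid]][["iSyn"]]))
      assign("iSyn", sum_currents(uid, t_ms), envir = e)
    cd <- units[[uid]]$compiled$derived
    for (nm in names(cd)) assign(nm, cd[[nm]](e), envir = e)
  }
  refresh_all <- function(t_ms) {
    for (uid in dep_order) refresh_unit(uid, t_ms)
  }

  # initialisation: states zeroed, then two settling passes of
  # refresh + on-start so that on-start expressions that read linked
  # variables (e.g. a gate initialised to its steady state at the
  # cell's resting potential) see the other units' initialised values
  for (pass in 1:2) {
    for (uid in dep_order) {
      refresh_unit(uid, 0)
      os <- units[[uid]]$compiled$on_start
      e <- envs[[uid]]
      for (s in names(os)) assign(s, os[[s]](e), envir = e)
      cd <- units[[uid]]$compiled$derived
      for (nm in names(cd)) assign(nm, cd[[nm]](e), envir = e)
    }
  }
  refresh_all(0)

  # condition edge-trigger memory; initialised false so rules whose test
  # already holds at t=0 (e.g. a zero-delay pulse) fire at start
  cond_prev <- lapply(unit_ids, function(uid)
    rep(FALSE, length(units[[uid]]$compiled$conditions)))
  names(cond_prev) <- unit_ids

  record <- spec$record %||% default_record_table(system)
  if (!is.null(record$neuron) && is.null(record$unit))
    record$unit <- record$neuron
  trace_cols <- paste(record$unit, record$variable, sep = "/")
  traces <- matrix(NA_real_, nrow = n_steps + 1L,
                   ncol = length(trace_cols),
                   dimnames = list(NULL, trace_cols))
  take_row <- function(k) {
    for (j in seq_along(trace_cols)) {
      traces[k, j] <<- get(record$variable[j], envir = envs[[record$unit[j]]])
    }
  }
  spikes <- setNames(vector("list", length(system$cells)), system$cells)
  for (cn in system$cells) spikes[[cn]] <- numeric()

  # full-state access for RK4
  state_index <- list()
  for (uid in unit_ids) {
    for (s in units[[uid]]$states)
      state_index[[length(state_index) + 1L]] <- c(uid, s)
  }
  get_state_vec <- function() {
    vapply(state_index, function(ix) get(ix[2], envir = envs[[ix[1]]]), 0)
  }
  set_state_vec <- function(y) {
    for (k in seq_along(state_index))
      assign(state_index[[k]][2], y[[k]], envir = envs[[state_index[[k]][1]]])
  }
  deriv_vec <- function(t_ms) {
    refresh_all(t_ms)
    out <- numeric(length(state_index))
    for (k in seq_along(state_index)) {
      uid <- state_index[[k]][1]; s <- state_index[[k]][2]
      f <- units[[uid]]$compiled$derivs[[s]]
      out[k] <- if (is.null(f)) 0 else f(envs[[uid]])
    }
    out
  }
  set_time <- function(t_ms) {
    t_s <- t_ms * 1e-3
    for (uid in unit_ids) assign("t", t_s, envir = envs[[uid]])
  }

  # condition tests (edge-triggered); reset assignments are applied
  # before synaptic event propagation within the same step; simultaneous
  # events delivered in unit-name order
  do_events <- function(t_now) {
    fired_events <- character()
    any_assign <- FALSE
    for (uid in unit_ids) {
      rules <- units[[uid]]$compiled$conditions
      if (length(rules) == 0L) next
      e <- envs[[uid]]
      for (r in seq_along(rules)) {
        now <- rules[[r]]$test(e) != 0
        if (now && !cond_prev[[uid]][r]) {
          for (s in names(rules[[r]]$assigns)) {
            assign(s, rules[[r]]$assigns[[s]](e), envir = e)
            any_assign <- TRUE
          }
          if (!is.null(rules[[r]]$event_out)) {
            fired_events <- c(fired_events, uid)
            if (uid %in% system$cells)
              spikes[[uid]] <<- c(spikes[[uid]], t_now)
          }
        }
        cond_prev[[uid]][r] <<- now
      }
    }
    if (length(fired_events) > 0L || any_assign) {
      for (uid in sort(unique(fired_events))) {
        for (route in system$event_routes[[uid]] %||% list()) {
          handler <- units[[route$unit]]$compiled$on_events[[route$port]]
          if (is.null(handler))
            stop("unit '", route$unit, "' has no handler for port '",
                 route$port, "'", call. = FALSE)
          e <- envs[[route$unit]]
          for (s in names(handler$assigns))
            assign(s, handler$assigns[[s]](e), envir = e)
        }
      }
      refresh_all(t_now)
    }
  }

  do_events(0)
  take_row(1L)
  for (step in seq_len(n_steps)) {
    t_ms <- (step - 1L) * spec$dt
    t_next <- step * spec$dt

    if (spec$method == "euler") {
      y0 <- get_state_vec()
      k1 <- deriv_vec(t_ms)
      set_state_vec(y0 + dt_s * k1)
    } else {  # rk4
      y0 <- get_state_vec()
      k1 <- deriv_vec(t_ms)
      set_time(t_ms + spec$dt / 2); set_state_vec(y0 + dt_s / 2 * k1)
      k2 <- deriv_vec(t_ms + spec$dt / 2)
      set_state_vec(y0 + dt_s / 2 * k2)
      k3 <- deriv_vec(t_ms + spec$dt / 2)
      set_time(t_next); set_state_vec(y0 + dt_s * k3)
      k4 <- deriv_vec(t_next)
      set_state_vec(y0 + dt_s / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    }
    set_time(t_next)
    refresh_all(t_next)
    do_events(t_next)

    bad <- which(!is.finite(get_state_vec()))
    if (length(bad) > 0L) {
      ix <- state_index[[bad[1]]]
      stop("numerical overflow at t = ", t_next, " ms in unit '", ix[1],
           "' (state '", ix[2], "')", call. = FALSE)
    }
    take_row(step + 1L)
  }

  structure(list(
    time_ms = seq(0, by = spec$dt, length.out = n_steps + 1L),
    traces = traces,
    spikes = spikes,
    dt = spec$dt, duration = spec$duration
  ), class = "wl_result_set")
}

#' @export
print.wl_result_set <- function(x, ...) {
  cat("<simulation result: ", length(x$time_ms), " samples x ",
      ncol(x$traces), " trace(s), ",
      sum(lengths(x$spikes)), " spike(s)>\n", sep = "")
  invisible(x)
}
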