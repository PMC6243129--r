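# Pluggable transduction seam: converts behavioral-experiment events into
# per-neuron current injections. Real sensory transduction lives in an
# external body/environment simulator; the default map here is a
# documented placeholder that drives the six classical touch receptor
# neurons with a pulse proportional to the applied force, and labels all
# other modalities as no-ops until the user configures them.

#' The six classical touch receptor neurons
#' @return Character vector of neuron names.
#' @export
touch_receptor_neurons <- function() {
  c("ALML", "ALMR", "AVM", "PLML", "PLMR", "PVM")
}

#' Build a transduction map
#'
#' A transduction map is an ordered list of rules; each rule names a
#' stimulus `variant`, the `targets` (neuron names) it drives, and a
#' `gain` converting the stimulus magnitude into a current amplitude
#' (nA per magnitude unit). Events whose variant has no rule are ignored.
#'
#' @param rules list of `list(variant =, targets =, gain =)`.
#' @return A `wl_transduction_map`.
#' @export
transduction_map <- function(rules = list()) {
  for (r in rules)
    stopifnot(is.character(r$targets), is.numeric(r$gain),
              r$variant %in% names(.stim_modality))
  structure(list(rules = rules), class = "wl_transduction_map")
}

#' @rdname transduction_map
#' @param touch_gain current per unit force for direct touch, nA/uN
#'   (placeholder value; real gains require a sensory-transduction model).
#' @export
default_transduction_map <- function(touch_gain = 0.01) {
  transduction_map(list(
    list(variant = "direct_touch", targets = touch_receptor_neurons(),
         gain = touch_gain)))
}

stimulus_magnitude <- function(stim) {
  switch(stim$variant,
    direct_touch = stim$force,
    plate_tap = stim$intensity,
    chemical_drop = stim$concentration,
    osmotic_ring = stim$concentration,
    temperature_change = abs(stim$end_temp - stim$start_temp),
    electric_shock = stim$amplitude,
    light = stim$intensity)
}

event_active_span <- function(ev, duration) {
  switch(ev$category,
    instant = c(ev$event_time,
                min(duration,
                    ev$event_time + (ev$stimulus$contact_duration %||% 0))),
    interval = c(ev$t0, ev$t1),
    experiment_wide = c(0, duration))
}

#' Transduce a behavioral experiment into current injections
#'
#' For every (event, rule, target-neuron) match, produces one
#' piecewise-constant injection whose support equals the event's active
#' time span (instant touch events extend over their contact duration)
#' and whose amplitude is `gain * stimulus magnitude` — linear in the
#' stimulus magnitude.
#'
#' @param experiment a valid `wl_experiment`.
#' @param map a [transduction_map()].
#' @param connectome optional `wl_connectome`; when given, rule targets
#'   are checked against it.
#' @param missing_targets `"error"` (default) to reject rules targeting
#'   neurons absent from the connectome, or `"skip"` to drop such
#'   targets (useful on reduced networks that only carry a subset of the
#'   mapped neurons).
#' @return List of injections `list(target =, waveform =)` compatible
#'   with [simulation_spec()].
#' @export
transduce <- function(experiment, map = default_transduction_map(),
                      connectome = NULL,
                      missing_targets = c("error", "skip")) {
  missing_targets <- match.arg(missing_targets)
  stopifnot(inherits(experiment, "wl_experiment"),
            inherits(map, "wl_transduction_map"))
  viol <- validate_experiment(experiment)
  if (nrow(viol) > 0L)
    stop("refusing to transduce an invalid experiment", call. = FALSE)
  injections <- list()
  for (ev in experiment$events) {
    for (rule in map$rules) {
      if (!identical(rule$variant, ev$stimulus$variant)) next
      span <- event_active_span(ev, experiment$experiment_duration)
      if (span[2] <= span[1]) next
      amp <- rule$gain * stimulus_magnitude(ev$stimulus)
      for (target in rule$targets) {
        if (!is.null(connectome)) {
          if (missing_targets == "skip" &&
              !target %in% connectome$neurons$name) next
          check_neuron(connectome, target)
        }
        injections[[length(injections) + 1L]] <-
          list(target = target,
               waveform = pulse_waveform(span[1], span[2], amp))
      }
    }
  }
  injections
}
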