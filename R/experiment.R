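# Behavioral-experiment data model: a duration-based timeline of stimulus
# events over five taxis modalities, plus the environment block (worm,
# plate, obstacles, crowding). Times are ms, geometry mm, angles degrees,
# touch force uN.

#' Duration-based event categories
#'
#' Every timeline event belongs to exactly one of three categories:
#' an interaction at a specific time `t`, an interaction from `t0` to `t1`,
#' or an experiment-wide configuration active for the whole run.
#'
#' @return Character vector of the three category names.
#' @export
event_categories <- function() c("instant", "interval", "experiment_wide")

#' Taxis modalities
#'
#' The five sensory stimulus classes supported by the experiment format.
#'
#' @return Character vector of the five modality names.
#' @export
taxis_modalities <- function() {
  c("mechanotaxis", "chemotaxis", "thermotaxis", "galvanotaxis", "phototaxis")
}

.stim_modality <- c(
  direct_touch = "mechanotaxis", plate_tap = "mechanotaxis",
  chemical_drop = "chemotaxis", osmotic_ring = "chemotaxis",
  temperature_change = "thermotaxis", electric_shock = "galvanotaxis",
  light = "phototaxis"
)

new_stimulus <- function(variant, fields) {
  structure(c(list(variant = variant), fields),
            class = c(paste0("wl_stim_", variant), "wl_stimulus"))
}

#' Stimulus specifications
#'
#' Constructors for the closed set of stimulus variants. Magnitudes are
#' non-negative; the osmotic ring requires `inner_radius < outer_radius`.
#' Units: force in uN, concentration in mM, radii and coordinates in mm,
#' temperatures in degrees C, shock amplitude in nA, durations in ms,
#' frequency in Hz, wavelength in nm; tap and light intensity are in
#' arbitrary units.
#'
#' @param body_position fraction along the body, 0 (head) to 1 (tail).
#' @param circumferential_angle angle around the body, degrees.
#' @param force applied force, uN.
#' @param contact_duration touch duration, ms.
#' @param intensity stimulus intensity, arbitrary units.
#' @param substance_id identifier of the applied chemical.
#' @param concentration concentration, mM.
#' @param x,y plate-centered coordinates, mm.
#' @param center_x,center_y ring center, mm.
#' @param inner_radius,outer_radius ring radii, mm.
#' @param start_temp,end_temp temperatures, degrees C.
#' @param profile `"linear"` ramp or `"step"`.
#' @param amplitude shock amplitude, nA.
#' @param duration shock duration, ms.
#' @param frequency shock frequency, Hz.
#' @param wavelength light wavelength, nm.
#' @return A `wl_stimulus` object.
#' @export
stim_direct_touch <- function(body_position, circumferential_angle = 0,
                              force = 1, contact_duration = 100) {
  new_stimulus("direct_touch", list(
    body_position = body_position,
    circumferential_angle = circumferential_angle,
    force = force, contact_duration = contact_duration))
}

#' @rdname stim_direct_touch
#' @export
stim_plate_tap <- function(intensity = 1) {
  new_stimulus("plate_tap", list(intensity = intensity))
}

#' @rdname stim_direct_touch
#' @export
stim_chemical_drop <- function(substance_id, concentration, x = 0, y = 0) {
  new_stimulus("chemical_drop", list(
    substance_id = substance_id, concentration = concentration, x = x, y = y))
}

#' @rdname stim_direct_touch
#' @export
stim_osmotic_ring <- function(substance_id, concentration,
                              center_x = 0, center_y = 0,
                              inner_radius = 5, outer_radius = 10) {
  new_stimulus("osmotic_ring", list(
    substance_id = substance_id, concentration = concentration,
    center_x = center_x, center_y = center_y,
    inner_radius = inner_radius, outer_radius = outer_radius))
}

#' @rdname stim_direct_touch
#' @export
stim_temperature_change <- function(start_temp, end_temp,
                                    profile = c("linear", "step")) {
  new_stimulus("temperature_change", list(
    start_temp = start_temp, end_temp = end_temp,
    profile = match.arg(profile)))
}

#' @rdname stim_direct_touch
#' @export
stim_electric_shock <- function(amplitude, duration, frequency) {
  new_stimulus("electric_shock", list(
    amplitude = amplitude, duration = duration, frequency = frequency))
}

#' @rdname stim_direct_touch
#' @export
stim_light <- function(intensity = 1, wavelength = 500, x = 0, y = 0) {
  new_stimulus("light", list(
    intensity = intensity, wavelength = wavelength, x = x, y = y))
}

#' Modality of a stimulus variant
#'
#' @param stimulus a `wl_stimulus`.
#' @return One of the five taxis modality names.
#' @export
stimulus_modality <- function(stimulus) {
  stopifnot(inherits(stimulus, "wl_stimulus"))
  unname(.stim_modality[[stimulus$variant]])
}

#' Create a timeline event
#'
#' An event pairs a stimulus with one of the three duration-based
#' categories. Instant events carry `event_time`; interval events carry
#' `t0` and `t1` (active on the half-open span `[t0, t1)`);
#' experiment-wide events carry no times and are active for the whole
#' experiment. The modality is derived from the stimulus variant.
#'
#' @param stimulus a `wl_stimulus`.
#' @param category one of `event_categories()`.
#' @param event_time time of an instant event, ms.
#' @param t0,t1 start/stop of an interval event, ms.
#' @return A `wl_timeline_event`.
#' @export
timeline_event <- function(stimulus,
                           category = c("instant", "interval",
                                        "experiment_wide"),
                           event_time = NULL, t0 = NULL, t1 = NULL) {
  category <- match.arg(category)
  stopifnot(inherits(stimulus, "wl_stimulus"))
  structure(list(
    category = category,
    modality = stimulus_modality(stimulus),
    stimulus = stimulus,
    event_time = event_time, t0 = t0, t1 = t1
  ), class = "wl_timeline_event")
}

event_sort_time <- function(ev) {
  switch(ev$category,
         instant = ev$event_time %||% NA_real_,
         interval = ev$t0 %||% NA_real_,
         experiment_wide = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Worm, plate, obstacle and crowding configuration
#'
#' Constructors for the environment block of an experiment definition.
#' Defaults describe a wild-type adult on a standard cylindrical assay
#' plate (border height 15 mm, radius 50 mm); worm body defaults are the
#' textbook 1 mm length and 80 um diameter.
#'
#' @param mutation_id strain/mutation identifier.
#' @param age age in days.
#' @param sex `"hermaphrodite"` or `"male"`.
#' @param stage larval stage `L1`-`L4` or `"adult"`.
#' @param hours_without_food starvation time, h.
#' @param body_length body length, mm.
#' @param body_diameter body diameter, um.
#' @return Environment component objects (`wl_*` lists).
#' @export
worm_data <- function(mutation_id = "N2", age = 1,
                      sex = c("hermaphrodite", "male"),
                      stage = c("adult", "L1", "L2", "L3", "L4"),
                      hours_without_food = 0,
                      body_length = 1, body_diameter = 80) {
  structure(list(
    mutation_id = mutation_id, age = age, sex = match.arg(sex),
    stage = match.arg(stage), hours_without_food = hours_without_food,
    body_length = body_length, body_diameter = body_diameter
  ), class = "wl_worm_data")
}

#' @rdname worm_data
#' @param shape plate (or obstacle) shape; only `"cylindrical"` /
#'   `"cylinder"` are defined.
#' @param border_height plate border height, mm.
#' @param radius plate (or obstacle) radius, mm.
#' @param substrate_code substrate identifier (e.g. `"A"` for agar).
#' @param dryness mg over the plate's dry weight.
#' @param lid logical, lid present.
#' @export
plate_config <- function(shape = "cylindrical", border_height = 15,
                         radius = 50, substrate_code = "A", dryness = 1,
                         lid = FALSE) {
  structure(list(
    shape = shape, border_height = border_height, radius = radius,
    substrate_code = substrate_code, dryness = dryness, lid = lid
  ), class = "wl_plate_config")
}

#' @rdname worm_data
#' @param height obstacle height, mm.
#' @param stiffness obstacle stiffness, N/m.
#' @param distance_x,distance_y signed placement offsets from the plate
#'   center along the central X and Y axes, mm.
#' @param angle obstacle orientation relative to the central axes, degrees.
#' @export
obstacle <- function(shape = "cylinder", height, radius, stiffness,
                     distance_x = 0, distance_y = 0, angle = 0) {
  structure(list(
    shape = shape, height = height, radius = radius, stiffness = stiffness,
    distance_x = distance_x, distance_y = distance_y, angle = angle
  ), class = "wl_obstacle")
}

#' @rdname worm_data
#' @param worm_count number of worms on the plate (>= 1).
#' @param distribution_index integer key into predefined placement
#'   formulae (carried opaquely).
#' @export
crowding <- function(worm_count = 1, distribution_index = 0) {
  structure(list(worm_count = worm_count,
                 distribution_index = distribution_index),
            class = "wl_crowding")
}

#' @rdname worm_data
#' @param worm a [worm_data()] object.
#' @param worm_location list with `x`, `y` (mm, plate-centered) and
#'   `orientation` (degrees).
#' @param plate a [plate_config()].
#' @param obstacles list of [obstacle()]s.
#' @param crowding a [crowding()].
#' @export
environment_config <- function(worm = worm_data(),
                               worm_location = list(x = 0, y = 0,
                                                    orientation = 0),
                               plate = plate_config(),
                               obstacles = list(),
                               crowding = wormlab::crowding()) {
  structure(list(
    worm = worm, worm_location = worm_location, plate = plate,
    obstacles = obstacles, crowding = crowding
  ), class = "wl_environment_config")
}

#' Create a behavioral experiment definition
#'
#' The top-level object: an experiment duration in ms, an ordered timeline
#' of stimulus events, and the environment configuration. Events are kept
#' in canonical order: stably sorted by start time (instant events by
#' `event_time`, interval events by `t0`, experiment-wide events at 0),
#' ties resolved by insertion order.
#'
#' @param experiment_duration total duration, ms (> 0).
#' @param events list of [timeline_event()]s.
#' @param environment an [environment_config()].
#' @return A `wl_experiment` object.
#' @export
#' @examples
#' def <- experiment_definition(60000, list(
#'   timeline_event(stim_plate_tap(2), "instant", event_time = 5000)))
#' validate_experiment(def)
experiment_definition <- function(experiment_duration, events = list(),
                                  environment = environment_config()) {
  ord <- order(vapply(events, event_sort_time, 0), seq_along(events))
  structure(list(
    experiment_duration = experiment_duration,
    events = events[ord],
    environment = environment
  ), class = "wl_experiment")
}

#' @export
print.wl_experiment <- function(x, ...) {
  cat("<behavioral experiment: ", x$experiment_duration, " ms, ",
      length(x$events), " event(s), ",
      length(x$environment$obstacles), " obstacle(s)>\n", sep = "")
  invisible(x)
}

violation <- function(where, message) {
  data.frame(where = where, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(where = character(), message = character(),
             stringsAsFactors = FALSE)
}

check_nonneg <- function(fields, values, where) {
  bad <- which(!vapply(values, function(v) is.numeric(v) && v >= 0, TRUE))
  if (length(bad) == 0L) return(no_violations())
  do.call(rbind, lapply(bad, function(i)
    violation(where, paste0("'", fields[i], "' must be a non-negative number"))))
}

.stim_magnitude_fields <- list(
  direct_touch = c("force", "contact_duration"),
  plate_tap = "intensity",
  chemical_drop = "concentration",
  osmotic_ring = c("concentration", "inner_radius", "outer_radius"),
  temperature_change = character(),
  electric_shock = c("amplitude", "duration", "frequency"),
  light = c("intensity", "wavelength")
)

validate_stimulus <- function(stim, where) {
  v <- no_violations()
  num_fields <- .stim_magnitude_fields[[stim$variant]]
  v <- rbind(v, check_nonneg(num_fields, stim[num_fields], where))
  if (stim$variant == "osmotic_ring" &&
      is.numeric(stim$inner_radius) && is.numeric(stim$outer_radius) &&
      !(stim$inner_radius < stim$outer_radius)) {
    v <- rbind(v, violation(where,
      "osmotic ring inner_radius must be smaller than outer_radius"))
  }
  if (stim$variant == "direct_touch" && is.numeric(stim$body_position) &&
      (stim$body_position < 0 || stim$body_position > 1)) {
    v <- rbind(v, violation(where,
      "body_position must lie in [0, 1] along the body"))
  }
  v
}

validate_event <- function(ev, duration, idx) {
  where <- paste0("event[", idx, "]")
  v <- no_violations()
  if (!ev$category %in% event_categories()) {
    return(violation(where, paste0("unknown category '", ev$category, "'")))
  }
  if (!identical(stimulus_modality(ev$stimulus), ev$modality)) {
    v <- rbind(v, violation(where, paste0(
      "modality '", ev$modality, "' inconsistent with stimulus variant '",
      ev$stimulus$variant, "'")))
  }
  in_range <- function(t) is.numeric(t) && t >= 0 && t <= duration
  if (ev$category == "instant") {
    if (is.null(ev$event_time)) {
      v <- rbind(v, violation(where, "instant event requires event_time"))
    } else if (!in_range(ev$event_time)) {
      v <- rbind(v, violation(where,
        "event_time outside [0, experiment_duration]"))
    }
    if (!is.null(ev$t0) || !is.null(ev$t1))
      v <- rbind(v, violation(where, "instant event must not carry t0/t1"))
  } else if (ev$category == "interval") {
    if (is.null(ev$t0) || is.null(ev$t1)) {
      v <- rbind(v, violation(where, "interval event requires t0 and t1"))
    } else {
      if (!(is.numeric(ev$t0) && is.numeric(ev$t1) && ev$t0 < ev$t1))
        v <- rbind(v, violation(where, "interval start must precede stop"))
      if (!in_range(ev$t0) || !(is.numeric(ev$t1) && ev$t1 >= 0 &&
                                ev$t1 <= duration))
        v <- rbind(v, violation(where,
          "interval times outside [0, experiment_duration]"))
    }
    if (!is.null(ev$event_time))
      v <- rbind(v, violation(where, "interval event must not carry event_time"))
  } else {  # experiment_wide
    if (!is.null(ev$event_time) || !is.null(ev$t0) || !is.null(ev$t1))
      v <- rbind(v, violation(where,
        "experiment-wide event must not carry time references"))
  }
  rbind(v, validate_stimulus(ev$stimulus, where))
}

validate_environment <- function(env) {
  v <- no_violations()
  plate <- env$plate
  if (!(is.numeric(plate$radius) && plate$radius > 0))
    v <- rbind(v, violation("plate", "radius must be > 0"))
  if (!(is.numeric(plate$border_height) && plate$border_height >= 0))
    v <- rbind(v, violation("plate", "border_height must be >= 0"))
  wd <- env$worm
  v <- rbind(v, check_nonneg(
    c("age", "hours_without_food", "body_length", "body_diameter"),
    wd[c("age", "hours_without_food", "body_length", "body_diameter")],
    "worm"))
  loc <- env$worm_location
  if (is.numeric(plate$radius) && plate$radius > 0 &&
      sqrt(loc$x^2 + loc$y^2) > plate$radius)
    v <- rbind(v, violation("worm_location",
      "worm location lies outside the plate footprint"))
  for (i in seq_along(env$obstacles)) {
    ob <- env$obstacles[[i]]
    where <- paste0("obstacle[", i, "]")
    if (!(is.numeric(ob$stiffness) && ob$stiffness > 0))
      v <- rbind(v, violation(where, "stiffness must be > 0"))
    for (f in c("height", "radius")) {
      if (!(is.numeric(ob[[f]]) && ob[[f]] > 0))
        v <- rbind(v, violation(where, paste0("'", f, "' must be > 0")))
    }
    if (is.numeric(plate$radius) && plate$radius > 0 &&
        sqrt(ob$distance_x^2 + ob$distance_y^2) > plate$radius)
      v <- rbind(v, violation(where,
        "obstacle placement lies outside the plate footprint"))
  }
  cr <- env$crowding
  if (!(is.numeric(cr$worm_count) && cr$worm_count >= 1 &&
        cr$worm_count == round(cr$worm_count)))
    v <- rbind(v, violation("crowding", "worm_count must be an integer >= 1"))
  if (!(is.numeric(cr$distribution_index) && cr$distribution_index >= 0))
    v <- rbind(v, violation("crowding",
      "distribution_index must be non-negative"))
  v
}

#' Validate an experiment definition
#'
#' Checks every type invariant: positive duration, per-category time
#' fields inside `[0, experiment_duration]`, interval ordering `t0 < t1`,
#' stimulus magnitudes, environment geometry (worm and obstacles inside
#' the plate footprint), and crowding. Violations are returned as data,
#' never raised.
#'
#' @param def a `wl_experiment`.
#' @return A data.frame with columns `where` and `message`; zero rows iff
#'   the definition is valid.
#' @export
validate_experiment <- function(def) {
  stopifnot(inherits(def, "wl_experiment"))
  v <- no_violations()
  D <- def$experiment_duration
  if (!(is.numeric(D) && length(D) == 1L && is.finite(D) && D > 0)) {
    v <- rbind(v, violation("experiment",
      "experiment_duration must be a positive number (ms)"))
    D <- Inf  # still report per-event structural problems
  }
  for (i in seq_along(def$events))
    v <- rbind(v, validate_event(def$events[[i]], D, i))
  rbind(v, validate_environment(def$environment))
}

#' Query the stimuli active at a time point
#'
#' Experiment-wide events are always active; interval events are active on
#' the half-open span `[t0, t1)`; instant events are active when
#' `|t - event_time| <= tolerance` (strict equality by default).
#'
#' @param def a valid `wl_experiment`.
#' @param t query time, ms, in `[0, experiment_duration]`.
#' @param tolerance half-width of the match window for instant events, ms.
#' @return The list of active `wl_timeline_event`s (in timeline order).
#' @export
active_stimuli <- function(def, t, tolerance = 0) {
  stopifnot(inherits(def, "wl_experiment"))
  if (!is.numeric(t) || t < 0 || t > def$experiment_duration)
    stop("query time ", t, " outside [0, ", def$experiment_duration, "] ms",
         call. = FALSE)
  keep <- vapply(def$events, function(ev) {
    switch(ev$category,
           experiment_wide = TRUE,
           interval = ev$t0 <= t && t < ev$t1,
           instant = abs(t - ev$event_time) <= tolerance)
  }, TRUE)
  def$events[keep]
}

random_stimulus <- function(variant) {
  r3 <- function(lo, hi) round(runif(1, lo, hi), 3)
  switch(variant,
    direct_touch = stim_direct_touch(
      body_position = r3(0, 1), circumferential_angle = r3(0, 360),
      force = r3(0.1, 10), contact_duration = r3(50, 500)),
    plate_tap = stim_plate_tap(intensity = r3(0.1, 5)),
    chemical_drop = stim_chemical_drop(
      substance_id = sample(c("NaCl", "biotin", "CuSO4", "glycerol"), 1),
      concentration = r3(0.1, 100), x = r3(-20, 20), y = r3(-20, 20)),
    osmotic_ring = {
      ri <- r3(2, 15)
      stim_osmotic_ring(
        substance_id = sample(c("glycerol", "fructose"), 1),
        concentration = r3(100, 1000),
        center_x = r3(-10, 10), center_y = r3(-10, 10),
        inner_radius = ri, outer_radius = ri + r3(1, 10))
    },
    temperature_change = stim_temperature_change(
      start_temp = r3(15, 25), end_temp = r3(15, 25),
      profile = sample(c("linear", "step"), 1)),
    electric_shock = stim_electric_shock(
      amplitude = r3(0.5, 50), duration = r3(10, 1000),
      frequency = r3(1, 100)),
    light = stim_light(intensity = r3(0.1, 5), wavelength = r3(350, 700),
                       x = r3(-20, 20), y = r3(-20, 20))
  )
}

#' Generate a random, valid experiment definition
#'
#' Deterministic per seed. Events cycle through every (category, stimulus
#' variant) combination before repeating, so all three categories and all
#' five modalities are covered once `n_events` is large enough; parameters
#' and times are drawn randomly within valid ranges.
#'
#' @param seed integer RNG seed.
#' @param n_events number of timeline events (>= 0).
#' @return A valid `wl_experiment`.
#' @export
generate_fixture_experiment <- function(seed, n_events = 8) {
  stopifnot(n_events >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  duration <- round(runif(1, 10000, 120000))
  variants <- names(.stim_modality)
  combos <- expand.grid(category = event_categories(), variant = variants,
                        stringsAsFactors = FALSE)
  events <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    cb <- combos[(i - 1L) %% nrow(combos) + 1L, ]
    stim <- random_stimulus(cb$variant)
    events[[i]] <- switch(cb$category,
      instant = timeline_event(stim, "instant",
                               event_time = round(runif(1, 0, duration), 3)),
      interval = {
        ts <- sort(round(runif(2, 0, duration), 3))
        if (ts[1] == ts[2]) {
          if (ts[1] >= 1) ts[1] <- ts[1] - 1 else ts[2] <- ts[2] + 1
        }
        timeline_event(stim, "interval", t0 = ts[1], t1 = ts[2])
      },
      experiment_wide = timeline_event(stim, "experiment_wide"))
  }
  n_obst <- sample(0:2, 1)
  obstacles <- lapply(seq_len(n_obst), function(i) {
    obstacle(height = round(runif(1, 1, 10), 3),
             radius = round(runif(1, 1, 8), 3),
             stiffness = round(runif(1, 5, 100), 3),
             distance_x = round(runif(1, -25, 25), 3),
             distance_y = round(runif(1, -25, 25), 3),
             angle = round(runif(1, 0, 360), 3))
  })
  env <- environment_config(
    worm = worm_data(age = round(runif(1, 0, 5), 3),
                     hours_without_food = round(runif(1, 0, 24), 3)),
    worm_location = list(x = round(runif(1, -20, 20), 3),
                         y = round(runif(1, -20, 20), 3),
                         orientation = round(runif(1, 0, 360), 3)),
    obstacles = obstacles)
  experiment_definition(duration, events, env)
}

#' Plate-centered coordinate of an obstacle
#'
#' Obstacle placement is stored as the (distance to the central axes,
#' angle) triple used by the XML dialect; this converts it to an x/y
#' plate coordinate.
#'
#' @param ob an [obstacle()].
#' @return Named numeric vector with `x` and `y`, mm.
#' @export
obstacle_coordinate <- function(ob) {
  c(x = ob$distance_x, y = ob$distance_y)
}
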