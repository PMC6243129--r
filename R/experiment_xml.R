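# XML serialisation of behavioral experiments. Element names follow the
# dialect's lowerCamelCase convention (experimentDuration,
# interactionAtSpecificTime, interactionFromt0tot1, experimentWideConf,
# eventStartTime, eventStopTime, wormData, electricShockConf, ...). The
# dialect is frozen in the shipped XSD (inst/xsd/behavioral-experiment.xsd).

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

.stim_element <- c(
  direct_touch = "directTouchConf", plate_tap = "plateTapConf",
  chemical_drop = "chemicalDropConf", osmotic_ring = "osmoticRingConf",
  temperature_change = "temperatureChangeConf",
  electric_shock = "electricShockConf", light = "lightConf"
)

# field order is fixed per variant -> deterministic output
.stim_fields <- list(
  direct_touch = c(bodyPosition = "body_position",
                   circumferentialAngle = "circumferential_angle",
                   force = "force", contactDuration = "contact_duration"),
  plate_tap = c(intensity = "intensity"),
  chemical_drop = c(substanceId = "substance_id",
                    concentration = "concentration",
                    locationX = "x", locationY = "y"),
  osmotic_ring = c(substanceId = "substance_id",
                   concentration = "concentration",
                   centerX = "center_x", centerY = "center_y",
                   innerRadius = "inner_radius", outerRadius = "outer_radius"),
  temperature_change = c(startTemp = "start_temp", endTemp = "end_temp",
                         profile = "profile"),
  electric_shock = c(amplitude = "amplitude", duration = "duration",
                     frequency = "frequency"),
  light = c(intensity = "intensity", wavelength = "wavelength",
            locationX = "x", locationY = "y")
)

.stim_string_fields <- c("substanceId", "profile")

add_text_child <- function(parent, name, value) {
  ch <- xml2::xml_add_child(parent, name)
  xml2::xml_text(ch) <- if (is.numeric(value)) fmt_num(value)
                        else if (is.logical(value)) tolower(as.character(value))
                        else as.character(value)
  ch
}

write_stimulus_xml <- function(parent, ev) {
  mod_node <- xml2::xml_add_child(parent, ev$modality)
  stim <- ev$stimulus
  conf <- xml2::xml_add_child(mod_node, .stim_element[[stim$variant]])
  fields <- .stim_fields[[stim$variant]]
  for (i in seq_along(fields))
    add_text_child(conf, names(fields)[i], stim[[fields[i]]])
  invisible(conf)
}

#' Serialise an experiment definition to XML
#'
#' Produces the behavioral-experiment XML dialect: `experimentDuration`
#' at the top, the timeline events under `experimentDefinition` (one
#' `interactionAtSpecificTime`, `interactionFromt0tot1` or
#' `experimentWideConf` element each, in canonical timeline order), and
#' the environment under `environmentDefinition`. Output element order
#' and number formatting are deterministic, so two writes of the same
#' definition are byte-identical.
#'
#' @param def a valid `wl_experiment`; invalid definitions are refused.
#' @param path optional file path; when given the document is also
#'   written there.
#' @return The XML document as a single string (invisibly when `path` is
#'   given).
#' @export
write_experiment <- function(def, path = NULL) {
  viol <- validate_experiment(def)
  if (nrow(viol) > 0L)
    stop("refusing to write an invalid experiment definition: ",
         paste0(viol$where, ": ", viol$message, collapse = "; "),
         call. = FALSE)
  doc <- xml2::xml_new_root("behavioralExperiment")
  add_text_child(doc, "experimentDuration", def$experiment_duration)

  defn <- xml2::xml_add_child(doc, "experimentDefinition")
  for (ev in def$events) {
    node <- switch(ev$category,
      instant = {
        n <- xml2::xml_add_child(defn, "interactionAtSpecificTime")
        add_text_child(n, "eventTime", ev$event_time)
        n
      },
      interval = {
        n <- xml2::xml_add_child(defn, "interactionFromt0tot1")
        add_text_child(n, "eventStartTime", ev$t0)
        add_text_child(n, "eventStopTime", ev$t1)
        n
      },
      experiment_wide = xml2::xml_add_child(defn, "experimentWideConf"))
    write_stimulus_xml(node, ev)
  }

  env <- def$environment
  envn <- xml2::xml_add_child(doc, "environmentDefinition")
  ws <- xml2::xml_add_child(envn, "wormStatus")
  wd <- xml2::xml_add_child(ws, "wormData")
  add_text_child(wd, "mutationId", env$worm$mutation_id)
  add_text_child(wd, "age", env$worm$age)
  add_text_child(wd, "sex", env$worm$sex)
  add_text_child(wd, "stage", env$worm$stage)
  add_text_child(wd, "hoursWithoutFood", env$worm$hours_without_food)
  add_text_child(wd, "bodyLength", env$worm$body_length)
  add_text_child(wd, "bodyDiameter", env$worm$body_diameter)
  wl <- xml2::xml_add_child(ws, "wormLocation")
  add_text_child(wl, "x", env$worm_location$x)
  add_text_child(wl, "y", env$worm_location$y)
  add_text_child(wl, "orientation", env$worm_location$orientation)
  pl <- xml2::xml_add_child(envn, "plateConf")
  add_text_child(pl, "shape", env$plate$shape)
  add_text_child(pl, "borderHeight", env$plate$border_height)
  add_text_child(pl, "radius", env$plate$radius)
  add_text_child(pl, "substrate", env$plate$substrate_code)
  add_text_child(pl, "dryness", env$plate$dryness)
  add_text_child(pl, "lid", env$plate$lid)
  obn <- xml2::xml_add_child(envn, "obstaclesConf")
  for (ob in env$obstacles) {
    o <- xml2::xml_add_child(obn, "obstacle")
    add_text_child(o, "shape", ob$shape)
    add_text_child(o, "height", ob$height)
    add_text_child(o, "radius", ob$radius)
    add_text_child(o, "stiffness", ob$stiffness)
    add_text_child(o, "distanceX", ob$distance_x)
    add_text_child(o, "distanceY", ob$distance_y)
    add_text_child(o, "angle", ob$angle)
  }
  cr <- xml2::xml_add_child(envn, "crowdingConf")
  add_text_child(cr, "wormCount", env$crowding$worm_count)
  add_text_child(cr, "distributionIndex", env$crowding$distribution_index)

  text <- as.character(doc)
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

node_children <- function(node) {
  kids <- xml2::xml_children(node)
  setNames(as.list(kids), xml2::xml_name(kids))
}

read_num <- function(node, name, parent_name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing"))
    stop("missing element '", name, "' in <", parent_name, ">", call. = FALSE)
  txt <- xml2::xml_text(ch)
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val))
    stop("non-numeric value '", txt, "' for <", name, ">", call. = FALSE)
  val
}

read_str <- function(node, name, parent_name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing"))
    stop("missing element '", name, "' in <", parent_name, ">", call. = FALSE)
  xml2::xml_text(ch)
}

expect_children <- function(node, allowed) {
  found <- xml2::xml_name(xml2::xml_children(node))
  unknown <- setdiff(found, allowed)
  if (length(unknown) > 0L)
    stop("unknown element(s) <", paste(unknown, collapse = ">, <"),
         "> in <", xml2::xml_name(node), ">", call. = FALSE)
}

read_stimulus_xml <- function(mod_node) {
  modality <- xml2::xml_name(mod_node)
  kids <- xml2::xml_children(mod_node)
  if (length(kids) != 1L)
    stop("modality <", modality, "> must contain exactly one stimulus ",
         "configuration element", call. = FALSE)
  conf <- kids[[1]]
  conf_name <- xml2::xml_name(conf)
  variant <- names(.stim_element)[match(conf_name, .stim_element)]
  if (is.na(variant))
    stop("unknown stimulus element <", conf_name, ">", call. = FALSE)
  if (!identical(unname(.stim_modality[[variant]]), modality))
    stop("stimulus <", conf_name, "> is not a ", modality, " stimulus",
         call. = FALSE)
  fields <- .stim_fields[[variant]]
  expect_children(conf, names(fields))
  vals <- list()
  for (i in seq_along(fields)) {
    xml_name <- names(fields)[i]
    vals[[fields[i]]] <-
      if (xml_name %in% .stim_string_fields) read_str(conf, xml_name, conf_name)
      else read_num(conf, xml_name, conf_name)
  }
  new_stimulus(variant, vals)
}

read_modality_child <- function(node) {
  allowed <- c(taxis_modalities(),
               "eventTime", "eventStartTime", "eventStopTime")
  expect_children(node, allowed)
  mods <- xml2::xml_children(node)
  mods <- mods[xml2::xml_name(mods) %in% taxis_modalities()]
  if (length(mods) != 1L)
    stop("<", xml2::xml_name(node), "> must contain exactly one taxis ",
         "modality element", call. = FALSE)
  mods[[1]]
}

#' Read a behavioral-experiment XML document
#'
#' Parses the behavioral-experiment dialect into a `wl_experiment`. The
#' mapping is strict: unknown elements, missing `experimentDuration` and
#' non-numeric fields all raise errors. Reading is loss-free with
#' [write_experiment()].
#'
#' @param document XML text, or a path to an XML file.
#' @param check_schema validate against the shipped XSD first.
#' @return A `wl_experiment`.
#' @export
read_experiment <- function(document, check_schema = TRUE) {
  doc <- xml2::read_xml(document)
  if (check_schema) {
    xsd <- xml2::read_xml(wormlab_file("xsd", "behavioral-experiment.xsd"))
    ok <- xml2::xml_validate(doc, xsd)
    if (!ok)
      stop("document does not conform to the behavioral-experiment schema: ",
           paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "behavioralExperiment")
    stop("root element must be <behavioralExperiment>", call. = FALSE)
  expect_children(root, c("experimentDuration", "experimentDefinition",
                          "environmentDefinition"))
  dur_node <- xml2::xml_find_first(root, "experimentDuration")
  if (inherits(dur_node, "xml_missing"))
    stop("missing <experimentDuration>", call. = FALSE)
  duration <- read_num(root, "experimentDuration", "behavioralExperiment")

  events <- list()
  defn <- xml2::xml_find_first(root, "experimentDefinition")
  if (!inherits(defn, "xml_missing")) {
    expect_children(defn, c("interactionAtSpecificTime",
                            "interactionFromt0tot1", "experimentWideConf"))
    for (node in as.list(xml2::xml_children(defn))) {
      kind <- xml2::xml_name(node)
      mod_node <- read_modality_child(node)
      stim <- read_stimulus_xml(mod_node)
      ev <- switch(kind,
        interactionAtSpecificTime = timeline_event(
          stim, "instant", event_time = read_num(node, "eventTime", kind)),
        interactionFromt0tot1 = timeline_event(
          stim, "interval",
          t0 = read_num(node, "eventStartTime", kind),
          t1 = read_num(node, "eventStopTime", kind)),
        experimentWideConf = timeline_event(stim, "experiment_wide"))
      events[[length(events) + 1L]] <- ev
    }
  }

  envn <- xml2::xml_find_first(root, "environmentDefinition")
  environment <- if (inherits(envn, "xml_missing")) environment_config()
                 else read_environment_xml(envn)

  experiment_definition(duration, events, environment)
}

read_environment_xml <- function(envn) {
  expect_children(envn, c("wormStatus", "plateConf", "obstaclesConf",
                          "crowdingConf"))
  ws <- xml2::xml_find_first(envn, "wormStatus")
  wd_node <- xml2::xml_find_first(ws, "wormData")
  expect_children(ws, c("wormData", "wormLocation"))
  expect_children(wd_node, c("mutationId", "age", "sex", "stage",
                             "hoursWithoutFood", "bodyLength",
                             "bodyDiameter"))
  worm <- worm_data(
    mutation_id = read_str(wd_node, "mutationId", "wormData"),
    age = read_num(wd_node, "age", "wormData"),
    sex = read_str(wd_node, "sex", "wormData"),
    stage = read_str(wd_node, "stage", "wormData"),
    hours_without_food = read_num(wd_node, "hoursWithoutFood", "wormData"),
    body_length = read_num(wd_node, "bodyLength", "wormData"),
    body_diameter = read_num(wd_node, "bodyDiameter", "wormData"))
  wl_node <- xml2::xml_find_first(ws, "wormLocation")
  expect_children(wl_node, c("x", "y", "orientation"))
  worm_location <- list(
    x = read_num(wl_node, "x", "wormLocation"),
    y = read_num(wl_node, "y", "wormLocation"),
    orientation = read_num(wl_node, "orientation", "wormLocation"))
  pl <- xml2::xml_find_first(envn, "plateConf")
  expect_children(pl, c("shape", "borderHeight", "radius", "substrate",
                        "dryness", "lid"))
  plate <- plate_config(
    shape = read_str(pl, "shape", "plateConf"),
    border_height = read_num(pl, "borderHeight", "plateConf"),
    radius = read_num(pl, "radius", "plateConf"),
    substrate_code = read_str(pl, "substrate", "plateConf"),
    dryness = read_num(pl, "dryness", "plateConf"),
    lid = identical(read_str(pl, "lid", "plateConf"), "true"))
  obn <- xml2::xml_find_first(envn, "obstaclesConf")
  obstacles <- list()
  if (!inherits(obn, "xml_missing")) {
    expect_children(obn, "obstacle")
    for (o in as.list(xml2::xml_children(obn))) {
      expect_children(o, c("shape", "height", "radius", "stiffness",
                           "distanceX", "distanceY", "angle"))
      obstacles[[length(obstacles) + 1L]] <- obstacle(
        shape = read_str(o, "shape", "obstacle"),
        height = read_num(o, "height", "obstacle"),
        radius = read_num(o, "radius", "obstacle"),
        stiffness = read_num(o, "stiffness", "obstacle"),
        distance_x = read_num(o, "distanceX", "obstacle"),
        distance_y = read_num(o, "distanceY", "obstacle"),
        angle = read_num(o, "angle", "obstacle"))
    }
  }
  cr <- xml2::xml_find_first(envn, "crowdingConf")
  crowd <- if (inherits(cr, "xml_missing")) crowding() else {
    expect_children(cr, c("wormCount", "distributionIndex"))
    crowding(worm_count = read_num(cr, "wormCount", "crowdingConf"),
             distribution_index = read_num(cr, "distributionIndex",
                                           "crowdingConf"))
  }
  environment_config(worm = worm, worm_location = worm_location,
                     plate = plate, obstacles = obstacles, crowding = crowd)
}

#' Enumerate the event categories and modalities the shipped schema fixes
#'
#' Introspects the packaged behavioral-experiment XSD: the duration-based
#' top-level elements (`interactionAtSpecificTime`,
#' `interactionFromt0tot1`, `experimentWideConf`) and the taxis modality
#' elements the schema's modality group admits.
#'
#' @return Character vector of element names.
#' @export
schema_event_categories <- function() {
  xsd <- xml2::read_xml(wormlab_file("xsd", "behavioral-experiment.xsd"))
  nodes <- xml2::xml_find_all(xsd, paste0(
    "//*[local-name()='complexType'][@name='experimentDefinitionType']",
    "/*[local-name()='choice']/*[local-name()='element']"))
  xml2::xml_attr(nodes, "name")
}

#' @rdname schema_event_categories
#' @export
schema_taxis_modalities <- function() {
  xsd <- xml2::read_xml(wormlab_file("xsd", "behavioral-experiment.xsd"))
  nodes <- xml2::xml_find_all(xsd, paste0(
    "//*[local-name()='group'][@name='taxisModality']",
    "/*[local-name()='choice']/*[local-name()='element']"))
  xml2::xml_attr(nodes, "name")
}

# path to a file shipped under inst/
wormlab_file <- function(...) {
  p <- system.file(..., package = "wormlab", mustWork = FALSE)
  if (!nzchar(p))
    stop("packaged file not found: ", file.path(...), call. = FALSE)
  p
}
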