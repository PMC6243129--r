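test_that("the schema fixes three event categories and five modalities", {
  expect_length(event_categories(), 3)
  expect_length(taxis_modalities(), 5)
  # every stimulus variant maps into exactly one modality
  variants <- names(wormlab:::.stim_modality)
  expect_length(variants, 7)
  expect_true(all(wormlab:::.stim_modality %in% taxis_modalities()))
})

test_that("validation flags ordering, range and geometry violations", {
  bad_interval <- experiment_definition(60000, list(
    timeline_event(stim_electric_shock(5, 100, 10), "interval",
                   t0 = 2000, t1 = 1000)))
  v <- validate_experiment(bad_interval)
  expect_true(any(grepl("start must precede stop", v$message)))

  late <- experiment_definition(1000, list(
    timeline_event(stim_plate_tap(1), "instant", event_time = 1001)))
  expect_true(any(grepl("outside \\[0, experiment_duration\\]",
                        validate_experiment(late)$message)))

  ring <- experiment_definition(1000, list(
    timeline_event(stim_osmotic_ring("glycerol", 500, inner_radius = 10,
                                     outer_radius = 5), "experiment_wide")))
  expect_true(any(grepl("inner_radius", validate_experiment(ring)$message)))

  off_plate <- experiment_definition(
    1000, environment = environment_config(
      worm_location = list(x = 60, y = 0, orientation = 0)))
  expect_true(any(grepl("worm location", validate_experiment(off_plate)$message)))

  expect_true(any(grepl("duration", validate_experiment(
    experiment_definition(-5))$message)))

  # validation is total and idempotent
  v1 <- validate_experiment(bad_interval)
  expect_identical(validate_experiment(bad_interval), v1)
})

test_that("the worked-example document validates cleanly and maps fully", {
  path <- system.file("extdata", "fixtures", "example_experiment.xml",
                      package = "wormlab")
  def <- read_experiment(path)
  expect_s3_class(def, "wl_experiment")
  expect_identical(nrow(validate_experiment(def)), 0L)
  expect_equal(def$experiment_duration, 60000)
  expect_length(def$events, 5)
  expect_setequal(
    unique(vapply(def$events, `[[`, "", "category")), event_categories())
  shock <- Filter(function(e) e$modality == "galvanotaxis", def$events)[[1]]
  expect_equal(shock$t0, 20000)
  expect_equal(shock$t1, 30000)
  expect_equal(shock$stimulus$amplitude, 5)
  expect_equal(shock$stimulus$frequency, 10)
})

test_that("the environment example recovers the printed parameters", {
  def <- read_experiment(system.file("extdata", "fixtures",
                                     "example_environment.xml",
                                     package = "wormlab"))
  env <- def$environment
  expect_equal(env$plate$radius, 50)
  expect_equal(env$plate$border_height, 15)
  expect_false(env$plate$lid)
  expect_equal(env$plate$dryness, 1)
  ob <- env$obstacles[[1]]
  expect_equal(ob$stiffness, 43.2)
  expect_equal(ob$height, 5)
  expect_equal(ob$radius, 5)
  expect_equal(env$worm$age, 1)
  expect_identical(env$worm$stage, "L1")
  expect_equal(env$worm$hours_without_food, 1)
  expect_equal(obstacle_coordinate(ob), c(x = 10, y = -15))
})

test_that("an empty timeline still parses", {
  doc <- paste0("<behavioralExperiment>",
                "<experimentDuration>1000</experimentDuration>",
                "</behavioralExperiment>")
  def <- read_experiment(doc)
  expect_length(def$events, 0)
  expect_identical(nrow(validate_experiment(def)), 0L)
})

test_that("strict reading rejects unknown elements and bad numbers", {
  bad1 <- paste0("<behavioralExperiment>",
                 "<experimentDuration>1000</experimentDuration>",
                 "<surpriseElement/></behavioralExperiment>")
  expect_error(read_experiment(bad1), "schema|unknown")
  expect_error(read_experiment(bad1, check_schema = FALSE), "unknown element")
  bad2 <- paste0("<behavioralExperiment>",
                 "<experimentDuration>soon</experimentDuration>",
                 "</behavioralExperiment>")
  expect_error(read_experiment(bad2, check_schema = FALSE), "non-numeric")
  expect_error(read_experiment("<behavioralExperiment/>",
                               check_schema = FALSE),
               "experimentDuration")
  expect_error(read_experiment("<notAnExperiment/>", check_schema = FALSE),
               "root element")
})

test_that("writer refuses invalid definitions and is deterministic", {
  bad <- experiment_definition(1000, list(
    timeline_event(stim_plate_tap(1), "instant", event_time = 5000)))
  expect_error(write_experiment(bad), "refusing to write")
  def <- generate_fixture_experiment(11, 5)
  expect_identical(write_experiment(def), write_experiment(def))
})

test_that("read/write round-trips hold across generated documents", {
  for (seed in 1:50) {
    def <- generate_fixture_experiment(seed, n_events = seed %% 9)
    doc <- write_experiment(def)
    back <- read_experiment(doc)
    # canonical-form identity: re-serialisation is byte-identical
    expect_identical(write_experiment(back), doc)
    # and the parsed structure matches field-for-field
    expect_equal(back$experiment_duration, def$experiment_duration)
    expect_length(back$events, length(def$events))
    for (k in seq_along(def$events)) {
      expect_identical(back$events[[k]]$category, def$events[[k]]$category)
      expect_equal(back$events[[k]]$stimulus, def$events[[k]]$stimulus)
    }
    expect_equal(back$environment, def$environment)
  }
})

test_that("generated fixtures are deterministic, valid and cover the grid", {
  expect_identical(write_experiment(generate_fixture_experiment(1, 10)),
                   write_experiment(generate_fixture_experiment(1, 10)))
  empty <- generate_fixture_experiment(5, 0)
  expect_length(empty$events, 0)
  expect_identical(nrow(validate_experiment(empty)), 0L)
  big <- generate_fixture_experiment(9, 21)
  expect_setequal(unique(vapply(big$events, `[[`, "", "category")),
                  event_categories())
  expect_setequal(unique(vapply(big$events, `[[`, "", "modality")),
                  taxis_modalities())
  for (seed in 1:100) {
    expect_identical(
      nrow(validate_experiment(generate_fixture_experiment(seed, 7))), 0L)
  }
})

test_that("active_stimuli matches an independent per-event scan", {
  # independent oracle: explicit per-category arithmetic
  oracle <- function(def, t, tol = 0) {
    Filter(function(ev) {
      if (ev$category == "experiment_wide") return(TRUE)
      if (ev$category == "interval")
        return(ev$t0 <= t && t < ev$t1)
      abs(t - ev$event_time) <= tol
    }, def$events)
  }
  set.seed(42)
  for (i in 1:60) {
    def <- generate_fixture_experiment(i, sample(0:15, 1))
    for (t in runif(5, 0, def$experiment_duration)) {
      expect_identical(active_stimuli(def, t), oracle(def, t))
    }
    # boundary probes around interval edges
    iv <- Filter(function(e) e$category == "interval", def$events)
    for (e in head(iv, 2)) {
      expect_true(any(vapply(active_stimuli(def, e$t0), identical, TRUE, e)))
      expect_false(any(vapply(active_stimuli(def, e$t1), identical, TRUE, e)))
    }
  }
})

test_that("instant events honor the tolerance window", {
  def <- experiment_definition(10000, list(
    timeline_event(stim_plate_tap(1), "instant", event_time = 5000)))
  expect_length(active_stimuli(def, 5000), 1)
  expect_length(active_stimuli(def, 5001), 0)
  expect_length(active_stimuli(def, 5001, tolerance = 1), 1)
  expect_error(active_stimuli(def, 10001), "outside")
  expect_error(active_stimuli(def, -1), "outside")
})

test_that("experiment-wide events are active at every sampled time", {
  def <- experiment_definition(30000, list(
    timeline_event(stim_osmotic_ring("glycerol", 500), "experiment_wide")))
  for (t in seq(0, 30000, length.out = 7))
    expect_length(active_stimuli(def, t), 1)
})
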