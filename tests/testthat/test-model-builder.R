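test_that("the core library contains the named point-neuron models and
           every type passes its own invariant checks", {
  lib <- load_core_library()
  expect_true(all(c("iafCell", "izhikevichCell", "hhRateGate",
                    "ionChannelHH", "pulseGenerator", "expOneSynapse",
                    "gapJunction") %in% names(lib)))
  for (ct in lib) {
    expect_s3_class(ct, "wl_component_type")
    # re-running the validator on a constructed type must be clean
    expect_silent(wormlab:::validate_component_type(ct))
  }
  expect_length(lib$izhikevichCell$state_variables, 2)
})

test_that("component types reject unresolved symbols, cycles, shadowing
           and dimension errors", {
  expect_error(component_type("t1", state_variables = c(v = "voltage"),
                              time_derivatives = c(v = "ghost / tau")),
               "unresolved|no declared dimension")
  expect_error(component_type("t2",
                              derived_variables = c(a = "b + 1", b = "a + 1")),
               "cyclic")
  expect_error(component_type("t3", parameters = c(v = "voltage"),
                              state_variables = c(v = "voltage")),
               "shadowed")
  expect_error(component_type("t4",
                              parameters = c(tau = "time"),
                              state_variables = c(v = "voltage"),
                              time_derivatives = c(v = "tau")),
               "wrong dimension")
  expect_error(component_type("t5", exposures = "nothing"),
               "undefined variable")
})

test_that("instantiation reports every binding problem by name", {
  lib <- load_core_library()
  err <- tryCatch(
    instantiate(lib$izhikevichCell, "z",
                c(a = "0.02", b = "0.2", c = "-65", d = "8", vpeak = "30",
                  tscale = "1 ms")),
    error = conditionMessage)
  expect_match(err, "iscale")
  err2 <- tryCatch(
    instantiate(lib$iafCell, "c", c(C = "0.2 ms", gL = "10 nS",
                                    EL = "-65 mV", Vth = "-50 mV",
                                    Vreset = "-65 mV", bogus = "1")),
    error = conditionMessage)
  expect_match(err2, "dimensionally inconsistent")
  expect_match(err2, "unknown parameter 'bogus'")
  ok <- default_component("izhikevich", "z")
  expect_length(ok$bindings, length(lib$izhikevichCell$parameters))
})

test_that("two components of one type share dynamics and differ only in
           bindings", {
  lib <- load_core_library()
  a <- instantiate(lib$iafCell, "a", c(C = "0.2 nF", gL = "10 nS",
                                       EL = "-65 mV", Vth = "-50 mV",
                                       Vreset = "-65 mV"))
  b <- instantiate(lib$iafCell, "b", c(C = "0.4 nF", gL = "5 nS",
                                       EL = "-60 mV", Vth = "-45 mV",
                                       Vreset = "-60 mV"))
  expect_identical(a$type, b$type)
  expect_false(identical(a$bindings, b$bindings))
})

test_that("model composition resolves requirements and reports dangling
           or duplicate links", {
  m <- iaf_pulse_model()
  expect_s3_class(m, "wl_neuron_model")
  expect_setequal(names(m$components), c("cell", "stim"))

  cell <- default_component("iaf", "cell")
  expect_error(compose_model(list(cell)), "unresolved requirement")
  stim <- default_component("pulse", "stim")
  expect_error(
    compose_model(list(cell, stim),
                  links = list(list(from = "stim/i", to = "cell/iSyn"),
                               list(from = "stim/i", to = "cell/iSyn"))),
    "duplicate link")
  expect_error(
    compose_model(list(cell, stim),
                  links = list(list(from = "stim/i", to = "cell/nope"))),
    "not a requirement")
  # dimension-incompatible link: voltage exposure into current requirement
  gate <- instantiate(load_core_library()$hhRateGate, "gate",
                      c(ra = "1 per_ms", va = "-40 mV", ka = "10 mV",
                        rb = "1 per_ms", vb = "-40 mV", kb = "10 mV"))
  expect_error(
    compose_model(list(cell, gate),
                  links = list(list(from = "cell/v", to = "cell/iSyn"),
                               list(from = "cell/v", to = "gate/v"))),
    "dimension-incompatible")
  # decomposition returns the original component set
  expect_identical(m$components$cell$bindings, cell$bindings)
})

test_that("HH gate dynamics settle on the two-rate steady state
           x_inf = alpha / (alpha + beta)", {
  lib <- load_core_library()
  # clamp the gate at a fixed voltage using a cell held subthreshold
  gate <- instantiate(lib$hhRateGate, "gate",
                      c(ra = "0.1 per_ms", va = "-40 mV", ka = "18 mV",
                        rb = "0.125 per_ms", vb = "-65 mV", kb = "20 mV"))
  cell <- default_component("iaf", "cell")
  stim <- instantiate(lib$pulseGenerator, "stim",
                      c(delay = "0 ms", duration = "500 ms",
                        amplitude = "0 nA"))
  m <- compose_model(list(cell, stim, gate),
                     links = list(list(from = "stim/i", to = "cell/iSyn"),
                                  list(from = "cell/v", to = "gate/v")),
                     root = "cell")
  res <- run_simulation(simulation_spec(m, duration = 200, dt = 0.05))
  x_end <- res$traces[nrow(res$traces), "gate/x"]
  v <- -0.065  # resting potential, V
  alpha <- 0.1e3 * exp((v - (-0.040)) / 0.018)
  beta <- 0.125e3 * exp(((-0.065) - v) / 0.020)
  expect_equal(unname(x_end), alpha / (alpha + beta), tolerance = 1e-6)
  # on-start initialisation already places the gate at steady state
  expect_equal(unname(res$traces[1, "gate/x"]), alpha / (alpha + beta),
               tolerance = 1e-6)
})

test_that("LEMS export/import round-trips fixture models semantically
           and is byte-stable", {
  lib <- load_core_library()
  models <- list(
    iaf_pulse_model(),
    iaf_pulse_model(amplitude = "0.7 nA", delay = "5 ms"),
    compose_model(list(default_component("izhikevich", "cell"),
                       default_component("pulse", "stim")),
                  links = list(list(from = "stim/i", to = "cell/iSyn")),
                  root = "cell"),
    compose_model(list())
  )
  for (m in models) {
    doc <- export_lems(m)
    back <- import_lems(doc)
    expect_true(wormlab:::model_equal(m, back))
    expect_identical(export_lems(back), doc)
  }
})

test_that("the empty model exports to a minimal importable document", {
  doc <- export_lems(compose_model(list()))
  expect_match(doc, "<Lems")
  back <- import_lems(doc)
  expect_length(back$components, 0)
})

test_that("import rejects constructs outside the implemented subset", {
  doc <- paste0(
    "<Lems><ComponentType name=\"x\"><Dynamics>",
    "<KineticScheme name=\"ks\"/>",
    "</Dynamics></ComponentType></Lems>")
  expect_error(import_lems(doc), "unsupported LEMS construct")
  expect_error(import_lems("<Lems><Structure/></Lems>"),
               "unsupported LEMS construct")
  expect_error(import_lems("<NotLems/>"), "root element")
})

test_that("a hand-written Izhikevich document imports with full bindings", {
  path <- system.file("extdata", "fixtures", "izhikevich_model.xml",
                      package = "wormlab")
  m <- import_lems(path)
  expect_identical(m$root, "cell")
  expect_gte(length(m$components$cell$bindings), 4)
  expect_equal(m$components$cell$bindings$a$value, 0.02)
  expect_equal(m$components$cell$bindings$d$value, 8)
  # the shipped document conforms to the frozen subset schema
  xsd <- xml2::read_xml(system.file("xsd", "lems-subset.xsd",
                                    package = "wormlab"))
  expect_true(xml2::xml_validate(xml2::read_xml(path), xsd))
})

test_that("exported documents validate against the shipped subset schema", {
  xsd <- xml2::read_xml(system.file("xsd", "lems-subset.xsd",
                                    package = "wormlab"))
  doc <- xml2::read_xml(export_lems(iaf_pulse_model()))
  expect_true(xml2::xml_validate(doc, xsd))
})
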