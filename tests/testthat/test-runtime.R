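closed_form_isi <- function(tau_ms = 20, RI_mV = 50, theta_mV = 15) {
  tau_ms * log(RI_mV / (RI_mV - theta_mV))
}

test_that("flatten produces the expected update-system structure", {
  sys1 <- flatten(iaf_pulse_model())
  cell <- sys1$units$cell
  expect_length(cell$states, 1)
  expect_length(cell$compiled$conditions, 1)
  izh <- flatten(compose_model(
    list(default_component("izhikevich", "cell"),
         default_component("pulse", "stim")),
    links = list(list(from = "stim/i", to = "cell/iSyn")), root = "cell"))
  expect_length(izh$units$cell$states, 2)
  expect_length(izh$units$cell$compiled$conditions, 1)
  expect_error(
    component_type("cyc", derived_variables = c(p = "q", q = "p")),
    "cyclic")
})

test_that("with zero drive the membrane relaxes monotonically to rest
           with no spikes", {
  m <- iaf_pulse_model(amplitude = "0 nA")
  res <- run_simulation(simulation_spec(m, duration = 50, dt = 0.05))
  expect_length(res$spikes$cell, 0)
  v <- res$traces[, "cell/v"]
  expect_equal(unname(v[1]), -0.065)
  expect_true(all(abs(v - (-0.065)) < 1e-12))
  # off-equilibrium start decays monotonically
  cfgv <- instantiate(load_core_library()$iafCell, "cell",
                      c(C = "0.2 nF", gL = "10 nS", EL = "-65 mV",
                        Vth = "-50 mV", Vreset = "-55 mV"))
  stim <- instantiate(load_core_library()$pulseGenerator, "stim",
                      c(delay = "0 ms", duration = "5 ms",
                        amplitude = "2 nA"))
  m2 <- compose_model(list(cfgv, stim),
                      links = list(list(from = "stim/i", to = "cell/iSyn")),
                      root = "cell")
  res2 <- run_simulation(simulation_spec(m2, duration = 150, dt = 0.05))
  v2 <- res2$traces[, "cell/v"]
  after <- v2[res2$time_ms > 6]
  expect_true(all(diff(after) <= 1e-15))
  expect_lt(abs(after[length(after)] - (-0.065)), 1e-4)
})

test_that("interspike interval matches the leaky integrate-and-fire
           closed form within 2% at dt = 0.01 ms", {
  m <- iaf_pulse_model(amplitude = "0.5 nA")
  res <- run_simulation(simulation_spec(m, duration = 100, dt = 0.01))
  isi <- diff(res$spikes$cell)
  expect_gt(length(isi), 5)
  expect_lt(max(abs(isi - closed_form_isi())) / closed_form_isi(), 0.02)
})

test_that("the integrator converges at first order and spike times shift
           by O(dt) under refinement", {
  # subthreshold charging has the closed form
  # v(t) = EL + RI (1 - exp(-t/tau)); no event quantization interferes
  v_err <- function(dt) {
    m <- iaf_pulse_model(amplitude = "0.1 nA")  # RI = 10 mV < threshold
    res <- run_simulation(simulation_spec(m, duration = 20, dt = dt))
    v_end <- res$traces[nrow(res$traces), "cell/v"]
    exact <- -0.065 + 0.010 * (1 - exp(-20 / 20))
    abs(v_end - exact)
  }
  errs <- vapply(c(0.2, 0.1, 0.05, 0.025), v_err, 0)
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 1.7 & ratios < 2.3))

  # spike times move by at most O(dt) when dt is halved
  first_spike <- function(dt) {
    m <- iaf_pulse_model(amplitude = "0.5 nA")
    run_simulation(simulation_spec(m, duration = 20, dt = dt))$spikes$cell[1]
  }
  dts <- c(0.16, 0.08, 0.04, 0.02)
  times <- vapply(dts, first_spike, 0)
  shifts <- abs(diff(times))
  expect_true(all(shifts <= 10 * dts[-length(dts)]))
  expect_lt(abs(times[length(times)] - closed_form_isi()), 0.1)
})

test_that("identical cells coupled by a gap junction from identical
           states stay identical", {
  cn <- two_cell_connectome("gap_junction")
  cfg <- network_configuration(cn, default_component("iaf", "cellDefault"))
  cfg <- assign_synapses(cfg, synapse_selector(kind = "gap_junction"),
                         default_component("gap_junction", "gap"))
  cfg <- auto_select_recorded_variables(cfg)
  inj <- list(list(target = "A", waveform = pulse_waveform(0, 100, 0.3)),
              list(target = "B", waveform = pulse_waveform(0, 100, 0.3)))
  res <- run_simulation(simulation_spec(cfg, duration = 100, dt = 0.05,
                                        injections = inj))
  expect_identical(res$traces[, "A/v"], res$traces[, "B/v"])
  expect_identical(res$spikes$A, res$spikes$B)
})

test_that("with zero injections and zero-conductance coupling each
           trajectory equals the isolated-cell trajectory", {
  cn <- two_cell_connectome("gap_junction")
  cfg <- network_configuration(cn, default_component("iaf", "cellDefault"))
  zero_gap <- instantiate(load_core_library()$gapJunction, "gap0",
                          c(conductance = "0 nS"))
  cfg <- assign_synapses(cfg, synapse_selector(kind = "gap_junction"),
                         zero_gap)
  cfg <- auto_select_recorded_variables(cfg)
  inj <- list(list(target = "A", waveform = pulse_waveform(5, 60, 0.5)))
  res <- run_simulation(simulation_spec(cfg, duration = 80, dt = 0.05,
                                        injections = inj))
  iso <- run_simulation(simulation_spec(
    iaf_pulse_model(amplitude = "0.5 nA", delay = "5 ms",
                    duration = "55 ms"),
    duration = 80, dt = 0.05))
  expect_equal(unname(res$traces[, "A/v"]),
               unname(iso$traces[, "cell/v"]), tolerance = 1e-12)
  expect_true(all(res$traces[, "B/v"] == -0.065))
})

test_that("identical specs give bit-identical results", {
  cfg <- configured_toy_network()
  inj <- list(list(target = "S1", waveform = pulse_waveform(2, 40, 0.6)))
  r1 <- run_simulation(simulation_spec(cfg, duration = 50, dt = 0.05,
                                       injections = inj))
  r2 <- run_simulation(simulation_spec(cfg, duration = 50, dt = 0.05,
                                       injections = inj))
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("export -> import -> run reproduces spike times exactly", {
  m <- iaf_pulse_model(amplitude = "0.6 nA")
  direct <- run_simulation(simulation_spec(m, duration = 60, dt = 0.02))
  back <- import_lems(export_lems(m))
  rerun <- run_simulation(simulation_spec(back, duration = 60, dt = 0.02))
  expect_identical(direct$spikes$cell, rerun$spikes$cell)
  expect_identical(direct$traces, rerun$traces)
})

test_that("RK4 cross-check agrees with Euler in the fine-dt limit", {
  m <- iaf_pulse_model(amplitude = "0.5 nA")
  euler <- run_simulation(simulation_spec(m, duration = 20, dt = 0.01))
  rk4 <- run_simulation(simulation_spec(m, duration = 20, dt = 0.01,
                                        method = "rk4"))
  expect_lt(abs(euler$spikes$cell[1] - rk4$spikes$cell[1]), 0.05)
})

test_that("trace grids have floor(duration/dt)+1 points and overflow is
           reported with position", {
  m <- iaf_pulse_model(amplitude = "0 nA")
  res <- run_simulation(simulation_spec(m, duration = 10, dt = 0.3))
  expect_equal(nrow(res$traces), floor(10 / 0.3) + 1)
  expect_error(simulation_spec(m, duration = 10, dt = 0),
               "0 < dt <= duration")
  expect_error(simulation_spec(m, duration = 10, dt = 0.1,
                               injections = list(list(
                                 target = "ghost",
                                 waveform = pulse_waveform(0, 1, 1)))),
               "unknown unit 'ghost'|unknown")

  runaway <- component_type("runaway",
                            state_variables = c(x = "dimensionless"),
                            time_derivatives = c(x = "x * x / tau + inc"),
                            on_start = c(x = "10"),
                            parameters = c(tau = "time",
                                           inc = "per_time"))
  comp <- instantiate(runaway, "r", c(tau = "1 ms", inc = "1 per_ms"))
  mr <- compose_model(list(comp))
  expect_error(run_simulation(simulation_spec(mr, duration = 50, dt = 0.5)),
               "overflow at t = .* in unit 'r'")
})

test_that("transduction turns touch events into pulses on the exact
           active span with linear magnitude scaling", {
  expect_length(transduce(experiment_definition(1000)), 0)

  def <- experiment_definition(10000, list(
    timeline_event(stim_direct_touch(0.5, force = 2,
                                     contact_duration = 100),
                   "interval", t0 = 1000, t1 = 3000)))
  inj <- transduce(def)
  expect_length(inj, 6)  # six touch receptor neurons
  expect_setequal(vapply(inj, `[[`, "", "target"),
                  touch_receptor_neurons())
  w <- inj[[1]]$waveform
  expect_equal(waveform_value(w, 999), 0)
  expect_equal(waveform_value(w, 1000), 0.02)  # 0.01 nA/uN * 2 uN
  expect_equal(waveform_value(w, 2999.9), 0.02)
  expect_equal(waveform_value(w, 3000), 0)
  # doubling the force doubles the amplitude
  def2 <- experiment_definition(10000, list(
    timeline_event(stim_direct_touch(0.5, force = 4,
                                     contact_duration = 100),
                   "interval", t0 = 1000, t1 = 3000)))
  expect_equal(waveform_value(transduce(def2)[[1]]$waveform, 2000), 0.04)

  # instant touch: support equals the contact duration
  def3 <- experiment_definition(10000, list(
    timeline_event(stim_direct_touch(0.5, force = 1,
                                     contact_duration = 250),
                   "instant", event_time = 500)))
  w3 <- transduce(def3)[[1]]$waveform
  expect_equal(w3$breaks, c(500, 750))

  # integrated charge equals amplitude x span (quadrature oracle)
  ts <- seq(0, 10000, by = 1)
  vals <- waveform_value(w, ts)
  charge <- sum(vals) * 1  # nA * ms
  expect_equal(charge, 0.02 * 2000, tolerance = 1e-3)

  bad_map <- transduction_map(list(list(variant = "direct_touch",
                                        targets = "GHOST", gain = 1)))
  expect_error(transduce(def, bad_map, toy_connectome()), "unknown neuron")
  # non-mapped modalities are ignored by the default map
  def4 <- experiment_definition(10000, list(
    timeline_event(stim_light(2), "experiment_wide")))
  expect_length(transduce(def4), 0)
})
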