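test_that("the packaged fixture loads with exactly 302 neurons and clean
           invariants", {
  cn <- celegans_connectome()
  expect_identical(nrow(cn$neurons), 302L)
  expect_false(anyDuplicated(cn$neurons$name) > 0)
  expect_setequal(unique(cn$neurons$category),
                  c("sensory", "inter", "motor"))
  expect_true(all(cn$connections$kind %in% c("chemical", "gap_junction")))
  expect_true(all(c(cn$connections$pre, cn$connections$post) %in%
                    cn$neurons$name))
})

test_that("toy tables load and table errors are caught", {
  cn <- toy_connectome()
  expect_identical(nrow(cn$neurons), 5L)
  expect_identical(nrow(cn$connections), 5L)

  nn <- cn$neurons; cc <- cn$connections
  cc_bad <- rbind(cc, data.frame(pre = "S1", post = "GHOST",
                                 kind = "chemical", multiplicity = 1,
                                 neurotransmitter = "glutamate"))
  expect_error(load_connectome(nn, cc_bad), "dangling")
  expect_error(load_connectome(rbind(nn, nn[1, ]), cc), "duplicate neuron")
  cc_kind <- cc; cc_kind$kind[1] <- "psychic"
  expect_error(load_connectome(nn, cc_kind), "unknown connection kind")
  cc_gj <- rbind(cc, data.frame(pre = "S2", post = "S1",
                                kind = "gap_junction", multiplicity = 1,
                                neurotransmitter = "none"))
  expect_error(load_connectome(nn, cc_gj), "stored more than once")
})

test_that("model assignment follows ordered-last-wins precedence", {
  cn <- celegans_connectome()
  cfg <- network_configuration(cn, default_component("iaf", "cellDefault"))
  izh <- default_component("izhikevich", "cellIzh")
  cfg <- assign_models(cfg, neuron_selector(names = "AVAL"), izh)
  expect_length(cfg$neuron_overrides, 1)
  expect_identical(resolved_model(cfg, "AVAL")$type$name, "izhikevichCell")
  expect_identical(resolved_model(cfg, "AVAR")$type$name, "iafCell")
  n_default <- sum(vapply(cn$neurons$name, function(n)
    resolved_model(cfg, n)$type$name == "iafCell", TRUE))
  expect_identical(n_default, 301L)

  # category selector on the toy fixture
  tcfg <- network_configuration(toy_connectome(),
                                default_component("iaf", "cellDefault"))
  tcfg <- assign_models(tcfg, neuron_selector(category = "sensory"), izh)
  expect_length(tcfg$neuron_overrides, 2)

  # second assignment to the same neuron wins
  iaf2 <- default_component("iaf", "cellB")
  tcfg <- assign_models(tcfg, neuron_selector(names = "S1"), iaf2)
  expect_identical(resolved_model(tcfg, "S1")$id, "cellB")
  expect_warning(assign_models(tcfg, neuron_selector(names = character()),
                               izh),
                 "matched no neurons")
  expect_error(assign_models(tcfg, synapse_selector(kind = "chemical"), izh),
               "neuron-selection mode")
})

test_that("parameter overrides re-instantiate the resolved model", {
  cfg <- network_configuration(toy_connectome(),
                               default_component("iaf", "cellDefault"))
  cfg <- assign_parameters(cfg, neuron_selector(names = "I1"),
                           c(EL = "-60 mV"))
  m <- resolved_model(cfg, "I1")
  expect_equal(m$bindings$EL$value, -60)
  expect_equal(resolved_model(cfg, "S1")$bindings$EL$value, -65)
})

test_that("synapse assignment enforces kind compatibility", {
  cfg <- network_configuration(toy_connectome(),
                               default_component("iaf", "cellDefault"))
  syn <- default_component("exc_synapse", "syn")
  gap <- default_component("gap_junction", "gap")
  expect_error(assign_synapses(cfg, synapse_selector(kind = "gap_junction"),
                               syn),
               "assigned to gap junction")
  expect_error(assign_synapses(cfg, synapse_selector(kind = "chemical"),
                               gap),
               "assigned to chemical")
  expect_error(assign_synapses(cfg, neuron_selector(names = "S1"), syn),
               "synapse-selection mode")
  cfg <- assign_synapses(cfg,
                         synapse_selector(neurotransmitter = "GABA"), syn)
  ids <- wormlab:::connection_synapse_ids(cfg)
  expect_identical(sum(!is.na(ids)), 1L)  # one GABA edge in the toy table
})

test_that("export is blocked while any connection is unmatched", {
  cfg <- network_configuration(toy_connectome(),
                               default_component("iaf", "cellDefault"))
  cfg <- assign_synapses(cfg, synapse_selector(kind = "chemical"),
                         default_component("exc_synapse", "syn"))
  expect_error(export_network(cfg), "S1 -> S2 \\(gap_junction\\)")
})

test_that("recorded-variable auto-selection follows the exposure+state
           rule and is idempotent", {
  cfg <- configured_toy_network(preset = "izhikevich")
  per_neuron <- table(cfg$recorded$neuron)
  expect_true(all(per_neuron == 2))  # izhikevich: v and u
  cfg2 <- auto_select_recorded_variables(cfg)
  expect_identical(cfg2$recorded, cfg$recorded)

  iaf_cfg <- configured_toy_network(preset = "iaf")
  expect_true(all(table(iaf_cfg$recorded$neuron) == 1))

  empty_cn <- load_connectome(
    data.frame(name = character(), class = character(),
               category = character(), x = numeric(), y = numeric(),
               z = numeric()),
    data.frame(pre = character(), post = character(), kind = character(),
               multiplicity = numeric(), neurotransmitter = character()))
  empty_cfg <- auto_select_recorded_variables(
    network_configuration(empty_cn, default_component("iaf", "c")))
  expect_identical(nrow(empty_cfg$recorded), 0L)

  no_model <- network_configuration(toy_connectome(), NULL)
  expect_error(auto_select_recorded_variables(no_model),
               "no resolved model")
  bad <- set_recorded_variables  # editing with a nonexistent variable fails
  expect_error(bad(cfg, data.frame(neuron = "S1", variable = "ghost")),
               "does not exist")
})

test_that("network export/import preserves nodes, edge multiset and
           parameter overrides", {
  cfg <- configured_toy_network()
  cfg <- assign_parameters(cfg, neuron_selector(names = "M1"),
                           c(Vth = "-48 mV"))
  cfg <- auto_select_recorded_variables(cfg)
  doc <- export_network(cfg)
  back <- import_network(doc)
  expect_identical(nrow(back$connectome$neurons),
                   nrow(cfg$connectome$neurons))
  key <- function(cn) sort(paste(cn$connections$pre, cn$connections$post,
                                 cn$connections$kind,
                                 cn$connections$multiplicity))
  expect_identical(key(back$connectome), key(cfg$connectome))
  expect_equal(resolved_model(back, "M1")$bindings$Vth$value, -48)
  expect_identical(export_network(back), doc)
  # export is deterministic across runs
  expect_identical(export_network(cfg), doc)
})

test_that("topology is immutable under configuration", {
  cn <- toy_connectome()
  cfg <- configured_toy_network(cn)
  cfg <- assign_models(cfg, neuron_selector(category = "motor"),
                       default_component("izhikevich", "izh"))
  cfg <- assign_parameters(cfg, neuron_selector(names = "S1"),
                           c(C = "0.3 nF"))
  expect_identical(cfg$connectome$neurons, cn$neurons)
  expect_identical(cfg$connectome$connections, cn$connections)
})

test_that("postsynaptic partners equal a brute-force adjacency scan", {
  cn <- toy_connectome()
  p <- postsynaptic_partners(cn, "S1")
  expect_identical(p$postsynaptic, "I1")
  expect_identical(p$gap_neighbors, "S2")
  expect_identical(postsynaptic_partners(cn, "M2")$postsynaptic,
                   character())
  expect_error(postsynaptic_partners(cn, "GHOST"), "unknown neuron")

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    names_r <- paste0("N", seq_len(n))
    nn <- data.frame(name = names_r, class = names_r, category = "inter",
                     x = 0, y = 0, z = 0)
    pre <- sample(names_r, 3 * n, replace = TRUE)
    post <- sample(names_r, 3 * n, replace = TRUE)
    keep <- pre != post
    cc <- unique(data.frame(pre = pre[keep], post = post[keep],
                            kind = "chemical", multiplicity = 1,
                            neurotransmitter = "glutamate"))
    cn_r <- load_connectome(nn, cc)
    target <- sample(names_r, 1)
    # brute force: loop over every edge
    expected <- character()
    for (i in seq_len(nrow(cc))) {
      if (cc$pre[i] == target) expected <- c(expected, cc$post[i])
    }
    expect_identical(postsynaptic_partners(cn_r, target)$postsynaptic,
                     sort(unique(expected)))
  }
})

test_that("highlight sets mirror the postsynaptic relation", {
  cn <- two_cell_connectome("chemical")
  h <- highlight_sets(cn, "A")
  expect_identical(h$selected, "A")
  expect_identical(h$postsynaptic, "B")
  expect_identical(highlight_sets(cn, "B")$postsynaptic, character())
})
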