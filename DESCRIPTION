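Package: wormlab
Title: Behavioral Experiment Encoding, Declarative Neuron Models and
    Connectome Simulation for C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless toolkit for defining Caenorhabditis elegans
    behavioral experiments and executing them on point-neuron network
    models. Provides a duration-based XML format for behavioral
    experiments (instantaneous, interval and experiment-wide stimuli over
    five taxis modalities, plus plate/worm/obstacle environment
    configuration), a declarative building-block system for neuron models
    in the style of the Low Entropy Model Specification (ComponentType
    dynamics templates, parameterized Components, dimensional checking,
    LEMS XML export/import), fixed-topology connectome configuration with
    model and synapse assignment and NeuroML-style network export, a
    reference interpreter that integrates exported models and networks
    (integrate-and-fire, Izhikevich, Hodgkin-Huxley-style gates, chemical
    synapses and gap junctions), and a results layer with CSV trace
    export, JSON-lines locomotion recordings and a deterministic
    synthetic-results generator. A command-line interface wires the
    modules into the define-build-configure-simulate-export workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
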