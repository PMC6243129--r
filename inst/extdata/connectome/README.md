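# Packaged connectome fixture

Two tab-separated tables describing a fixed-topology adult-hermaphrodite
C. elegans network:

- `celegans_neurons_synthetic.tsv` — one row per neuron: `name`, `class`,
  `category` (sensory / inter / motor), soma position `x`, `y`, `z` in um
  (anterior-posterior axis on x, body length 1 mm).
- `celegans_connections_synthetic.tsv` — one row per connection: `pre`,
  `post`, `kind` (`chemical` or `gap_junction`), `multiplicity`,
  `neurotransmitter`. Gap junctions are symmetric and stored once per
  unordered pair (alphabetical order).

## Provenance

The neuron *names* and class structure are the canonical 302 neurons of
the adult hermaphrodite nervous system (standard anatomical knowledge;
the published wiring reconstructions use the same name set). Everything
else is **synthetic**, as the `_synthetic` filenames indicate:

- soma positions are plausible placements by anatomical region (head /
  ventral cord / mid-body / tail), not measured coordinates;
- the sensory/inter/motor category assignment is an approximation at the
  class level;
- the connection list is generated deterministically (seed 42, script
  `scratch/make_connectome.R`) with category-biased wiring
  (sensory -> interneuron -> motor) and putative-neurotransmitter labels
  (GABA for the classic GABAergic classes, acetylcholine / glutamate
  otherwise). It does **not** reproduce any published synapse table, and
  per-edge multiplicities are random.

The fixture exists so that whole-network configuration, export and the
structural 302-neuron invariant can be exercised offline; analyses of
real connectivity must load a published wiring dataset through
`load_connectome()` instead.
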