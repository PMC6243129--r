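# Fixed-topology connectome: named neurons with functional categories and
# soma positions, chemical synapses (directed) and gap junctions
# (symmetric, stored once per unordered pair). Topology is immutable:
# configuration only annotates it.

#' Load a connectome from neuron and connection tables
#'
#' @param neurons a data.frame or path to a TSV with columns `name`,
#'   `class`, `category` (`sensory`/`inter`/`motor`) and soma position
#'   `x`, `y`, `z` (um).
#' @param connections a data.frame or path to a TSV with columns `pre`,
#'   `post`, `kind` (`chemical`/`gap_junction`), `multiplicity`,
#'   `neurotransmitter`.
#' @return A validated `wl_connectome`.
#' @export
load_connectome <- function(neurons, connections) {
  if (is.character(neurons))
    neurons <- read.delim(neurons, stringsAsFactors = FALSE)
  if (is.character(connections))
    connections <- read.delim(connections, stringsAsFactors = FALSE)
  need_n <- c("name", "class", "category", "x", "y", "z")
  need_c <- c("pre", "post", "kind", "multiplicity", "neurotransmitter")
  if (!all(need_n %in% names(neurons)))
    stop("neuron table must have columns: ", paste(need_n, collapse = ", "),
         call. = FALSE)
  if (!all(need_c %in% names(connections)))
    stop("connection table must have columns: ",
         paste(need_c, collapse = ", "), call. = FALSE)
  dup <- neurons$name[duplicated(neurons$name)]
  if (length(dup) > 0L)
    stop("duplicate neuron name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_cat <- setdiff(unique(neurons$category),
                     c("sensory", "inter", "motor"))
  if (length(bad_cat) > 0L)
    stop("unknown functional category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  bad_kind <- setdiff(unique(connections$kind),
                      c("chemical", "gap_junction"))
  if (length(bad_kind) > 0L)
    stop("unknown connection kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  dangling <- setdiff(unique(c(connections$pre, connections$post)),
                      neurons$name)
  if (length(dangling) > 0L)
    stop("dangling connection endpoint(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  gj <- connections[connections$kind == "gap_junction", , drop = FALSE]
  if (nrow(gj) > 0L) {
    key <- paste(pmin(gj$pre, gj$post), pmax(gj$pre, gj$post))
    if (anyDuplicated(key))
      stop("gap junction pair(s) stored more than once: ",
           paste(unique(key[duplicated(key)]), collapse = ", "),
           call. = FALSE)
  }
  structure(list(neurons = neurons, connections = connections),
            class = "wl_connectome")
}

#' @export
print.wl_connectome <- function(x, ...) {
  cat("<connectome: ", nrow(x$neurons), " neurons, ",
      sum(x$connections$kind == "chemical"), " chemical synapses, ",
      sum(x$connections$kind == "gap_junction"), " gap junctions>\n",
      sep = "")
  invisible(x)
}

#' The packaged 302-neuron connectome fixture
#'
#' Canonical adult-hermaphrodite neuron names and classes with synthetic
#' soma positions and a synthetic, deterministic connection list (see the
#' fixture README under `extdata/connectome/` for provenance). Intended
#' for structural invariants, configuration and export; not a published
#' wiring dataset.
#'
#' @return A `wl_connectome` with exactly 302 neurons.
#' @export
#' @examples
#' cn <- celegans_connectome()
#' nrow(cn$neurons)
celegans_connectome <- function() {
  load_connectome(
    wormlab_file("extdata", "connectome", "celegans_neurons_synthetic.tsv"),
    wormlab_file("extdata", "connectome",
                 "celegans_connections_synthetic.tsv"))
}

check_neuron <- function(connectome, neuron) {
  if (!neuron %in% connectome$neurons$name)
    stop("unknown neuron '", neuron, "'", call. = FALSE)
}

#' Postsynaptic partners and gap-junction neighbors of a neuron
#'
#' Postsynaptic partners are the `post` endpoints of chemical connections
#' with `pre = neuron`; gap-junction neighbors are reported separately
#' (gap junctions are symmetric).
#'
#' @param connectome a `wl_connectome`.
#' @param neuron neuron name.
#' @return `list(postsynaptic = <chr>, gap_neighbors = <chr>)`, both
#'   sorted.
#' @export
postsynaptic_partners <- function(connectome, neuron) {
  check_neuron(connectome, neuron)
  cc <- connectome$connections
  chem <- cc[cc$kind == "chemical" & cc$pre == neuron, "post"]
  gj <- cc[cc$kind == "gap_junction" &
             (cc$pre == neuron | cc$post == neuron), , drop = FALSE]
  neighbors <- ifelse(gj$pre == neuron, gj$post, gj$pre)
  list(postsynaptic = sort(unique(chem)),
       gap_neighbors = sort(unique(neighbors)))
}
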