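# Circuit extraction from synapse-level connectivity tables. The rules
# implemented here are the ones used to delimit the startle circuit from
# a whole-body serial-EM reconstruction: a seed-based inclusion filter
# (>= 3 synapses from >= 2 collar-receptor neurons), a bilateral rescue of
# weakly connected partners, exclusion of soma-less fragments and glia,
# and restriction of the second layer to motoneurons (cells innervating
# muscles or ciliary bands).

#' Construct a circuit graph from neuron and synapse tables
#'
#' @param nodes Data frame with columns `neuron_id`, `name`, `cell_class`,
#'   `group`, `side`, `segment`, `has_soma`, `partner_id`.
#' @param edges Data frame with columns `pre_id`, `post_id`,
#'   `synapse_count`; duplicate (pre, post) rows are summed. Each synapse
#'   carries weight 1 regardless of its anatomical extent, so counts are
#'   taken at face value.
#' @return A list of class `circuit_graph` with elements `nodes`, `edges`
#'   and `self_loops` (self-loops are retained in `edges` but reported).
#' @export
circuit_graph <- function(nodes, edges) {
  need_n <- c("neuron_id", "name", "cell_class", "group", "side", "segment",
              "has_soma", "partner_id")
  need_e <- c("pre_id", "post_id", "synapse_count")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stopf("neuron table lacks columns: %s", paste(miss, collapse = ", "))
  miss <- setdiff(need_e, names(edges))
  if (length(miss)) stopf("synapse table lacks columns: %s", paste(miss, collapse = ", "))

  dup <- nodes$neuron_id[duplicated(nodes$neuron_id)]
  if (length(dup)) stopf("duplicate neuron_id: %s", paste(unique(dup), collapse = ", "))

  bad_class <- !(nodes$cell_class %in% CELL_CLASSES)
  if (any(bad_class)) {
    warnf("unknown cell_class for %d neuron(s) (%s); mapped to 'fragment'",
          sum(bad_class),
          paste(unique(nodes$cell_class[bad_class]), collapse = ", "))
    nodes$cell_class[bad_class] <- "fragment"
  }

  bad_ref <- which(!(edges$pre_id %in% nodes$neuron_id) |
                     !(edges$post_id %in% nodes$neuron_id))
  if (length(bad_ref)) {
    ids <- unique(c(edges$pre_id[bad_ref], edges$post_id[bad_ref]))
    ids <- setdiff(ids, nodes$neuron_id)
    stopf("synapse rows %s reference unknown neuron id(s): %s",
          paste(head(bad_ref, 5), collapse = ", "),
          paste(head(ids, 5), collapse = ", "))
  }
  if (any(edges$synapse_count < 1))
    stopf("synapse_count must be >= 1 on every edge")

  # partner relation must be symmetric and irreflexive
  has_p <- !is.na(nodes$partner_id)
  if (any(nodes$partner_id[has_p] == nodes$neuron_id[has_p]))
    stopf("a neuron cannot be its own bilateral partner")
  p_of_p <- nodes$partner_id[match(nodes$partner_id[has_p], nodes$neuron_id)]
  if (any(is.na(p_of_p)) || any(p_of_p != nodes$neuron_id[has_p]))
    stopf("partner relation is not symmetric")
  if (any(nodes$side == "unpaired" & has_p))
    stopf("unpaired neurons must not carry a partner_id")

  edges <- aggregate(synapse_count ~ pre_id + post_id, data = edges, FUN = sum)
  edges <- edges[order(edges$pre_id, edges$post_id), need_e]
  rownames(edges) <- NULL
  loops <- edges[edges$pre_id == edges$post_id, ]
  structure(list(nodes = nodes, edges = edges, self_loops = loops),
            class = "circuit_graph")
}

#' @export
print.circuit_graph <- function(x, ...) {
  cat(sprintf("<circuit_graph> %d neurons, %d edges, %d synapses",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$synapse_count)))
  if (nrow(x$self_loops)) cat(sprintf(" (%d self-loops)", nrow(x$self_loops)))
  cat("\n")
  invisible(x)
}

#' Read neuron and synapse CSV tables into a circuit graph
#'
#' @param neuron_csv,synapse_csv Paths to CSV files in the schemas written
#'   by [write_connectome()].
#' @return A [circuit_graph()].
#' @export
read_circuit_tables <- function(neuron_csv, synapse_csv) {
  for (p in c(neuron_csv, synapse_csv))
    if (!file.exists(p)) stopf("file not found: %s", p)
  circuit_graph(read.csv(neuron_csv), read.csv(synapse_csv))
}

#' Parse a neuron name into group, segment, side and index
#'
#' Names in the non-grouped connectivity tables follow the pattern
#' `<group>_sg<k><l|r><i>`; for example `INsplitCR_sg2r1` is split
#' interneuron 1 in the second segment on the right side. A trailing
#' `<l|r><i>` without a segment token is also understood (head and
#' pygidial cells); anything else falls through to the untagged case.
#'
#' @param name Character vector of neuron names.
#' @return A data frame with columns `group`, `segment`, `side`, `index`
#'   (index is `NA` for untagged names).
#' @examples
#' parse_neuron_name("INsplitCR_sg2r1")
#' parse_neuron_name("pygPBunp")
#' @export
parse_neuron_name <- function(name) {
  out <- data.frame(group = name, segment = "unknown", side = "unpaired",
                    index = NA_integer_, stringsAsFactors = FALSE)
  side_of <- c(l = "left", r = "right")

  full <- regmatches(name, regexec("^(.*?)_?sg([0-9]+)([lr])([0-9]+)$", name))
  partial <- regmatches(name, regexec("^(.*?)_([lr])([0-9]+)$", name))
  for (i in seq_along(name)) {
    m <- full[[i]]
    if (length(m) == 5 && nzchar(m[2])) {
      out$group[i] <- m[2]
      out$segment[i] <- paste0("sg", m[3])
      out$side[i] <- side_of[[m[4]]]
      out$index[i] <- as.integer(m[5])
      next
    }
    m <- partial[[i]]
    if (length(m) == 4 && nzchar(m[2])) {
      out$group[i] <- m[2]
      out$side[i] <- side_of[[m[3]]]
      out$index[i] <- as.integer(m[4])
    }
  }
  out
}

#' Select direct synaptic targets of the seed population
#'
#' A neuron qualifies as a first-layer member if it receives at least
#' `min_synapses` synapses in total from at least `min_distinct_seeds`
#' distinct seed neurons. Defaults are the published thresholds (3
#' synapses, 2 seeds). Seeds themselves are never returned.
#'
#' @param graph A [circuit_graph()].
#' @param seeds Vector of seed neuron ids (must be nodes of `graph`).
#' @param min_synapses Minimum total synapse count from seeds.
#' @param min_distinct_seeds Minimum number of distinct presynaptic seeds.
#' @return Sorted vector of qualifying neuron ids.
#' @export
select_direct_targets <- function(graph, seeds, min_synapses = 3,
                                  min_distinct_seeds = 2) {
  stopifnot(inherits(graph, "circuit_graph"))
  if (!all(seeds %in% graph$nodes$neuron_id))
    stopf("seeds not present in graph: %s",
          paste(setdiff(seeds, graph$nodes$neuron_id), collapse = ", "))
  if (!length(seeds)) {
    warnf("empty seed set; no targets selected")
    return(integer(0))
  }
  e <- graph$edges
  e <- e[e$pre_id %in% seeds & !(e$post_id %in% seeds), , drop = FALSE]
  if (!nrow(e)) return(integer(0))
  tot <- tapply(e$synapse_count, e$post_id, sum)
  nsd <- tapply(e$pre_id, e$post_id, function(x) length(unique(x)))
  ids <- as.integer(names(tot))
  sort(ids[tot >= min_synapses & nsd >= min_distinct_seeds])
}

#' Rescue weakly connected bilateral partners of selected neurons
#'
#' Neurons with seed input that fail the primary inclusion rule (fewer
#' synapses or only one upstream seed) are added if their bilateral
#' counterpart is already part of the first selected set. Semantics are
#' single-pass: rescued neurons do not themselves rescue, so a second
#' pass over `union(selected, additions)` adds nothing new.
#'
#' @inheritParams select_direct_targets
#' @param selected Ids returned by [select_direct_targets()].
#' @return Sorted vector of additional ids (disjoint from `selected`).
#' @export
bilateral_rescue <- function(graph, seeds, selected) {
  stopifnot(inherits(graph, "circuit_graph"))
  if (!length(selected)) return(integer(0))
  e <- graph$edges
  e <- e[e$pre_id %in% seeds & !(e$post_id %in% seeds), , drop = FALSE]
  cand <- setdiff(unique(e$post_id), selected)
  if (!length(cand)) return(integer(0))
  partner <- graph$nodes$partner_id[match(cand, graph$nodes$neuron_id)]
  sort(cand[!is.na(partner) & partner %in% selected])
}

#' Exclude unqualified candidates (fragments, glia, optionally unpaired)
#'
#' Mirrors the manual curation step of the reconstruction: soma-less
#' fragments are dropped even when they pass the synapse filter, as are
#' glial cells. Removal of unpaired neurons is opt-in per cell class via
#' `require_bilateral`, because the published circuit kept one unpaired
#' sensory-motor neuron (the pygidial pygPB^unp^ analog) while dropping
#' other unpaired cells.
#'
#' @inheritParams select_direct_targets
#' @param candidates Vector of candidate neuron ids.
#' @param require_bilateral Character vector of cell classes for which
#'   `side == "unpaired"` disqualifies a candidate (default none).
#' @return List with `kept` (sorted ids) and `excluded` (data frame with
#'   columns `neuron_id`, `reason` in `fragment`/`glia`/`unpaired`).
#' @export
exclude_unqualified <- function(graph, candidates,
                                require_bilateral = character(0)) {
  stopifnot(inherits(graph, "circuit_graph"))
  meta <- graph$nodes[match(candidates, graph$nodes$neuron_id), ]
  reason <- rep(NA_character_, length(candidates))
  reason[!meta$has_soma] <- "fragment"
  reason[is.na(reason) & meta$cell_class == "glia"] <- "glia"
  reason[is.na(reason) & meta$side == "unpaired" &
           meta$cell_class %in% require_bilateral] <- "unpaired"
  excluded <- data.frame(neuron_id = candidates[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  list(kept = sort(candidates[is.na(reason)]), excluded = excluded)
}

#' Select the motoneuron layer downstream of the first circuit layer
#'
#' Returns the postsynaptic targets of `layer1` that belong to the
#' motoneuron class, operationally defined as carrying
#' `cell_class == "motoneuron"` or having at least one outgoing edge onto
#' a muscle or ciliary-band effector. On fully labelled data the two
#' routes agree; the union is returned so unlabelled motoneurons with
#' clear effector output are still captured.
#'
#' @inheritParams select_direct_targets
#' @param layer1 Ids of the first circuit layer (selected + rescued).
#' @return Sorted vector of motoneuron ids.
#' @export
select_motoneuron_layer <- function(graph, layer1) {
  stopifnot(inherits(graph, "circuit_graph"))
  e <- graph$edges
  targets <- unique(e$post_id[e$pre_id %in% layer1])
  targets <- setdiff(targets, layer1)
  if (!length(targets)) return(integer(0))
  meta <- graph$nodes[match(targets, graph$nodes$neuron_id), ]
  eff_ids <- graph$nodes$neuron_id[graph$nodes$cell_class %in% EFFECTOR_CLASSES]
  drives_eff <- targets %in% e$pre_id[e$post_id %in% eff_ids]
  sort(targets[meta$cell_class == "motoneuron" | drives_eff])
}

#' Extract the full startle circuit from seeds
#'
#' Convenience wrapper chaining [select_direct_targets()],
#' [bilateral_rescue()], [exclude_unqualified()] and
#' [select_motoneuron_layer()], then appending the effectors innervated
#' by the motoneuron layer.
#'
#' @inheritParams select_direct_targets
#' @inheritParams exclude_unqualified
#' @return List with components `seeds`, `selected`, `rescued`,
#'   `excluded` (data frame with reasons), `layer1` (kept selected +
#'   rescued), `motoneurons`, `effectors` and `members` (all of the
#'   above combined).
#' @export
extract_circuit <- function(graph, seeds, min_synapses = 3,
                            min_distinct_seeds = 2,
                            require_bilateral = character(0)) {
  selected <- select_direct_targets(graph, seeds, min_synapses, min_distinct_seeds)
  rescued <- bilateral_rescue(graph, seeds, selected)
  screened <- exclude_unqualified(graph, c(selected, rescued), require_bilateral)
  layer1 <- screened$kept
  mns <- select_motoneuron_layer(graph, layer1)
  e <- graph$edges
  eff_ids <- graph$nodes$neuron_id[graph$nodes$cell_class %in% EFFECTOR_CLASSES]
  effectors <- sort(intersect(unique(e$post_id[e$pre_id %in% c(layer1, mns)]), eff_ids))
  list(seeds = sort(seeds), selected = selected, rescued = rescued,
       excluded = screened$excluded, layer1 = layer1,
       motoneurons = mns, effectors = effectors,
       members = sort(unique(c(seeds, layer1, mns, effectors))))
}

#' Collapse a neuron-level circuit into a grouped network
#'
#' Member-level edges are summed into group-level edges; the total
#' synapse count is conserved exactly, and each edge carries a display
#' weight equal to the common logarithm of its synapse total (the
#' convention used to draw arrow thickness in grouped wiring diagrams).
#'
#' @inheritParams select_direct_targets
#' @param members Ids to include; every member must carry a group label.
#' @return A list of class `grouped_network` with `nodes` (`group`,
#'   `member_count`) and `edges` (`source`, `target`, `total_synapses`,
#'   `display_weight`).
#' @export
group_network <- function(graph, members) {
  stopifnot(inherits(graph, "circuit_graph"))
  if (!length(members)) {
    return(structure(list(
      nodes = data.frame(group = character(0), member_count = integer(0)),
      edges = data.frame(source = character(0), target = character(0),
                         total_synapses = integer(0),
                         display_weight = numeric(0))),
      class = "grouped_network"))
  }
  meta <- graph$nodes[match(members, graph$nodes$neuron_id), ]
  no_grp <- is.na(meta$group) | !nzchar(meta$group)
  if (any(no_grp))
    stopf("members without a group label: %s",
          paste(members[no_grp], collapse = ", "))
  nodes <- aggregate(list(member_count = meta$neuron_id),
                     by = list(group = meta$group), FUN = length)
  e <- graph$edges
  e <- e[e$pre_id %in% members & e$post_id %in% members, , drop = FALSE]
  if (nrow(e)) {
    grp <- function(ids) graph$nodes$group[match(ids, graph$nodes$neuron_id)]
    agg <- aggregate(list(total_synapses = e$synapse_count),
                     by = list(source = grp(e$pre_id), target = grp(e$post_id)),
                     FUN = sum)
    agg$display_weight <- log10(agg$total_synapses)
    agg <- agg[order(agg$source, agg$target), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(source = character(0), target = character(0),
                      total_synapses = integer(0), display_weight = numeric(0))
  }
  structure(list(nodes = nodes, edges = agg), class = "grouped_network")
}

#' @export
print.grouped_network <- function(x, ...) {
  cat(sprintf("<grouped_network> %d groups, %d edges, %d synapses\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$total_synapses)))
  invisible(x)
}

#' Filter weak edges from a grouped network
#'
#' Display convention of the published wiring diagrams: interactions with
#' fewer than five synapses were filtered from the full sensory-motor
#' network, fewer than two from the side-sorted network. Nodes are
#' retained.
#'
#' @param network A [group_network()] result.
#' @param min_synapses Minimum synapse total an edge must reach to be kept.
#' @return The filtered `grouped_network`.
#' @export
filter_edges <- function(network, min_synapses) {
  stopifnot(inherits(network, "grouped_network"))
  if (min_synapses < 1) stopf("`min_synapses` must be >= 1")
  network$edges <- network$edges[network$edges$total_synapses >= min_synapses, ]
  rownames(network$edges) <- NULL
  network
}

#' Display weight of a grouped edge
#'
#' Arrow line thickness in the wiring diagrams equals the common
#' logarithm of the synapse count.
#'
#' @param total_synapses Positive integer synapse total(s).
#' @return `log10(total_synapses)`.
#' @export
edge_display_weight <- function(total_synapses) {
  if (any(total_synapses < 1)) stopf("`total_synapses` must be >= 1")
  log10(total_synapses)
}

#' Convert a grouped network to an igraph object
#' @param network A `grouped_network`.
#' @return An igraph directed graph with node attribute `member_count`
#'   and edge attributes `total_synapses`, `display_weight`.
#' @export
as_igraph_network <- function(network) {
  stopifnot(inherits(network, "grouped_network"))
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Export / import a grouped network
#'
#' CSV and GraphML exports round-trip without loss of node or edge
#' attributes; DOT is write-only (one edge statement per edge).
#'
#' @param network A `grouped_network`.
#' @param path Output path. For `format = "csv"` the edge table is
#'   written to `path` and the node table to `path` with a `_nodes.csv`
#'   suffix.
#' @param format One of `"csv"`, `"graphml"`, `"dot"`.
#' @return The path(s) written, invisibly.
#' @export
export_network <- function(network, path, format = c("csv", "graphml", "dot")) {
  stopifnot(inherits(network, "grouped_network"))
  format <- match.arg(format)
  if (format == "csv") {
    nodes_path <- sub("\\.csv$", "_nodes.csv", path)
    if (identical(nodes_path, path)) nodes_path <- paste0(path, "_nodes.csv")
    write.csv(network$edges, path, row.names = FALSE)
    write.csv(network$nodes, nodes_path, row.names = FALSE)
    return(invisible(c(path, nodes_path)))
  }
  g <- as_igraph_network(network)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    nodes_path <- sub("\\.csv$", "_nodes.csv", path)
    if (identical(nodes_path, path)) nodes_path <- paste0(path, "_nodes.csv")
    edges <- read.csv(path)
    nodes <- read.csv(nodes_path)
    return(structure(list(nodes = nodes, edges = edges),
                     class = "grouped_network"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(group = igraph::V(g)$name,
                      member_count = igraph::V(g)$member_count)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(source = el$from, target = el$to,
                      total_synapses = el$total_synapses,
                      display_weight = el$display_weight)
  structure(list(nodes = nodes, edges = edges), class = "grouped_network")
}
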