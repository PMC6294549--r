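# Network-level readouts of the extracted circuit: fewest-synapse
# sensorimotor pathways, shared-target convergence between interneuron
# classes, laterality of motoneuron output, bilateral-symmetry scores and
# segmental synapse distributions.

#' @noRd
circuit_igraph <- function(graph) {
  el <- data.frame(from = as.character(graph$edges$pre_id),
                   to = as.character(graph$edges$post_id),
                   synapse_count = graph$edges$synapse_count)
  igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = as.character(graph$nodes$neuron_id)))
}

#' Minimum-hop pathways from seeds to effectors
#'
#' Startle initiation is assumed to use the paths with the fewest
#' intervening synapses, so pathway search minimises hop count and
#' ignores edge weights; the weakest edge along each path is reported for
#' downstream filtering. For every target reachable within `max_hops`,
#' all minimum-hop paths from any source are returned (breadth-first
#' semantics); unreachable targets are reported as such.
#'
#' @param graph A [circuit_graph()].
#' @param sources,targets Neuron id vectors (subsets of the graph nodes).
#' @param max_hops Maximum number of synaptic steps to consider.
#' @return A data frame with one row per minimum-hop path (`source`,
#'   `target`, `hop_count`, `min_edge_weight`, `reachable`, and a list
#'   column `path` of node-id vectors); unreachable targets contribute a
#'   single row with `reachable = FALSE` and `NA` hops.
#' @export
shortest_pathways <- function(graph, sources, targets, max_hops = 4) {
  stopifnot(inherits(graph, "circuit_graph"))
  all_ids <- graph$nodes$neuron_id
  if (!all(c(sources, targets) %in% all_ids))
    stopf("sources/targets not present in graph")
  g <- circuit_igraph(graph)
  d <- igraph::distances(g, v = as.character(sources),
                         to = as.character(targets), mode = "out")
  wt <- function(a, b) {
    graph$edges$synapse_count[graph$edges$pre_id == a & graph$edges$post_id == b]
  }
  rows <- list()
  for (tg in targets) {
    dcol <- d[, as.character(tg)]
    best <- suppressWarnings(min(dcol))
    if (!is.finite(best) || best > max_hops || best < 1) {
      row <- data.frame(source = NA_integer_, target = tg,
                        hop_count = NA_integer_,
                        min_edge_weight = NA_integer_, reachable = FALSE)
      row$path <- I(list(integer(0)))
      rows[[length(rows) + 1L]] <- row
      next
    }
    for (src in sources[dcol == best]) {
      sp <- igraph::all_shortest_paths(g, from = as.character(src),
                                       to = as.character(tg), mode = "out")
      for (p in sp$vpaths) {
        ids <- as.integer(names(p))
        w <- min(mapply(wt, head(ids, -1), tail(ids, -1)))
        row <- data.frame(source = src, target = tg,
                          hop_count = length(ids) - 1L,
                          min_edge_weight = w, reachable = TRUE)
        row$path <- I(list(ids))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shared-target partition (Venn regions) of source groups
#'
#' Computes, for k source groups, the 2^k - 1 disjoint regions of the
#' Venn diagram over their distinct postsynaptic targets passing the
#' class filter. Membership counts neurons, not synapses.
#'
#' @param graph A [circuit_graph()].
#' @param source_groups Character vector of 2 to 5 group labels.
#' @param target_filter Cell class(es) a target must carry (default
#'   motoneurons, matching the published comparison of interneuron
#'   classes converging on ventral-nerve-cord motoneurons).
#' @return A list of class `convergence_partition`: `regions` (data frame
#'   with `region` and `size`), `members` (named list of id vectors) and
#'   `groups`.
#' @export
shared_targets <- function(graph, source_groups, target_filter = "motoneuron") {
  stopifnot(inherits(graph, "circuit_graph"))
  k <- length(source_groups)
  if (k < 2 || k > 5) stopf("between 2 and 5 source groups required")
  unknown <- setdiff(source_groups, graph$nodes$group)
  if (length(unknown)) stopf("unknown group(s): %s", paste(unknown, collapse = ", "))

  ok_targets <- graph$nodes$neuron_id[graph$nodes$cell_class %in% target_filter]
  tsets <- lapply(source_groups, function(g) {
    pre <- graph$nodes$neuron_id[graph$nodes$group == g]
    sort(intersect(unique(graph$edges$post_id[graph$edges$pre_id %in% pre]),
                   ok_targets))
  })
  names(tsets) <- source_groups
  universe <- sort(unique(unlist(tsets)))
  member_of <- vapply(tsets, function(s) universe %in% s,
                      logical(length(universe)))
  if (length(universe) == 1L) member_of <- matrix(member_of, nrow = 1L,
                                                  dimnames = list(NULL, source_groups))
  combos <- lapply(seq_len(2^k - 1), function(m) as.logical(bitwAnd(m, 2^(seq_len(k) - 1))))
  regions <- lapply(combos, function(cmb) {
    sel <- apply(member_of, 1L, function(row) all(row == cmb))
    universe[sel]
  })
  labels <- vapply(combos, function(cmb)
    paste(source_groups[cmb], collapse = "&"), character(1))
  names(regions) <- labels
  structure(list(
    regions = data.frame(region = labels,
                         size = vapply(regions, length, integer(1))),
    members = regions, groups = source_groups
  ), class = "convergence_partition")
}

#' Classify motoneuron laterality from effector-target sides
#'
#' The anatomical distinction between ipsilateral and decussating
#' (midline-crossing) motoneurons is approximated here from connectivity:
#' the side of each postsynaptic muscle or ciliary-band effector is
#' compared with the soma side. All targets on the soma side gives
#' `ipsilateral`, all opposite gives `contralateral`, both gives `mixed`
#' (the pattern of motoneurons with both ipsilateral and decussating
#' branches), and no sided effector targets gives `undetermined`. This is
#' a proxy for axon trajectory, which connectivity tables do not encode.
#'
#' @param neuron_ids Neuron id vector.
#' @param graph A [circuit_graph()].
#' @return Character vector in
#'   `c("ipsilateral", "contralateral", "mixed", "undetermined")`.
#' @export
classify_laterality <- function(neuron_ids, graph) {
  stopifnot(inherits(graph, "circuit_graph"))
  nodes <- graph$nodes
  eff <- nodes$neuron_id[nodes$cell_class %in% EFFECTOR_CLASSES]
  vapply(neuron_ids, function(id) {
    my_side <- nodes$side[match(id, nodes$neuron_id)]
    if (is.na(my_side) || my_side == "unpaired") return("undetermined")
    posts <- graph$edges$post_id[graph$edges$pre_id == id]
    posts <- intersect(posts, eff)
    sides <- nodes$side[match(posts, nodes$neuron_id)]
    sides <- sides[sides %in% c("left", "right")]
    if (!length(sides)) return("undetermined")
    ipsi <- any(sides == my_side); contra <- any(sides != my_side)
    if (ipsi && contra) "mixed" else if (ipsi) "ipsilateral" else "contralateral"
  }, character(1))
}

#' Bilateral symmetry of wiring downstream of the seeds
#'
#' For each neuron group reachable from the seed set, the set of target
#' group labels contacted by the group's left-side members is compared
#' with that of its right-side members by the Jaccard index; the overall
#' score is the mean over groups. A perfectly mirrored circuit scores 1
#' in every group; wiring present on one side only scores 0.
#'
#' @param graph A [circuit_graph()].
#' @param seeds_left,seeds_right Seed ids partitioned by body side.
#' @return A list of class `bilateral_symmetry`: `per_group` (named
#'   numeric vector) and `overall` (their mean), or `NA` with a warning
#'   when one seed side is empty.
#' @export
bilateral_symmetry_score <- function(graph, seeds_left, seeds_right) {
  stopifnot(inherits(graph, "circuit_graph"))
  if (!length(seeds_left) || !length(seeds_right)) {
    warnf("one seed side is empty; symmetry undetermined")
    return(structure(list(per_group = numeric(0), overall = NA_real_),
                     class = "bilateral_symmetry"))
  }
  g <- circuit_igraph(graph)
  seeds <- as.character(c(seeds_left, seeds_right))
  reach_ids <- unique(unlist(lapply(seeds, function(s)
    names(igraph::subcomponent(g, s, mode = "out")))))
  nodes <- graph$nodes
  down <- nodes[nodes$neuron_id %in% as.integer(reach_ids), ]
  grp_of <- function(ids) nodes$group[match(ids, nodes$neuron_id)]

  per_group <- c()
  for (g_lab in unique(down$group)) {
    members_l <- down$neuron_id[down$group == g_lab & down$side == "left"]
    members_r <- down$neuron_id[down$group == g_lab & down$side == "right"]
    if (!length(members_l) && !length(members_r)) next
    tl <- unique(grp_of(graph$edges$post_id[graph$edges$pre_id %in% members_l]))
    tr <- unique(grp_of(graph$edges$post_id[graph$edges$pre_id %in% members_r]))
    if (!length(tl) && !length(tr)) next  # group with no outgoing wiring
    jac <- length(intersect(tl, tr)) / length(union(tl, tr))
    per_group[g_lab] <- jac
  }
  structure(list(per_group = per_group,
                 overall = if (length(per_group)) mean(per_group) else NA_real_),
            class = "bilateral_symmetry")
}

#' @export
print.bilateral_symmetry <- function(x, ...) {
  cat(sprintf("<bilateral_symmetry> overall %.3f over %d groups\n",
              x$overall, length(x$per_group)))
  invisible(x)
}

#' Segmental distribution of synaptic output
#'
#' Tallies synapse totals from each source group onto labelled effector
#' targets by target segment and effector type (group label). Row sums
#' per source group equal that group's total synaptic output onto
#' labelled targets (exact conservation).
#'
#' @param graph A [circuit_graph()].
#' @param source_groups Character vector of source group labels.
#' @param target_classes Cell classes counted as targets (default muscle
#'   and ciliary-band effectors).
#' @return Data frame with columns `source_group`, `segment`,
#'   `target_type`, `total_synapses`. Source groups with no output
#'   contribute a zero row.
#' @export
segmental_profile <- function(graph, source_groups,
                              target_classes = EFFECTOR_CLASSES) {
  stopifnot(inherits(graph, "circuit_graph"))
  nodes <- graph$nodes
  out <- list()
  for (g_lab in source_groups) {
    pre <- nodes$neuron_id[nodes$group == g_lab]
    e <- graph$edges[graph$edges$pre_id %in% pre, , drop = FALSE]
    tmeta <- nodes[match(e$post_id, nodes$neuron_id), ]
    keep <- tmeta$cell_class %in% target_classes
    e <- e[keep, , drop = FALSE]; tmeta <- tmeta[keep, , drop = FALSE]
    if (!nrow(e)) {
      out[[g_lab]] <- data.frame(source_group = g_lab, segment = NA_character_,
                                 target_type = NA_character_, total_synapses = 0L)
      next
    }
    agg <- aggregate(list(total_synapses = e$synapse_count),
                     by = list(segment = tmeta$segment,
                               target_type = tmeta$group), FUN = sum)
    agg$source_group <- g_lab
    out[[g_lab]] <- agg[, c("source_group", "segment", "target_type",
                            "total_synapses")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
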