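test_that("table reading builds the graph and aggregates duplicate synapse rows", {
  dir <- withr::local_tempdir()
  nodes <- data.frame(neuron_id = 1:3, name = c("a", "b", "c"),
                      cell_class = "interneuron", group = c("A", "B", "C"),
                      side = "unpaired", segment = "sg1", has_soma = TRUE,
                      partner_id = NA_integer_)
  edges <- data.frame(pre_id = c(1, 1, 1, 2), post_id = c(2, 2, 3, 3),
                      synapse_count = c(2, 3, 1, 4))
  write.csv(nodes, file.path(dir, "n.csv"), row.names = FALSE)
  write.csv(edges, file.path(dir, "s.csv"), row.names = FALSE)
  g <- read_circuit_tables(file.path(dir, "n.csv"), file.path(dir, "s.csv"))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 3)  # duplicate (1,2) rows summed
  expect_equal(g$edges$synapse_count[g$edges$pre_id == 1 & g$edges$post_id == 2], 5)
})

test_that("malformed tables are rejected with informative errors", {
  nodes <- data.frame(neuron_id = c(1, 1), name = "a", cell_class = "glia",
                      group = "A", side = "unpaired", segment = "sg1",
                      has_soma = TRUE, partner_id = NA_integer_)
  e <- data.frame(pre_id = 1, post_id = 1, synapse_count = 1)
  expect_error(circuit_graph(nodes, e), "duplicate neuron_id")

  nodes <- nodes[1, ]
  expect_error(circuit_graph(nodes, data.frame(pre_id = 1, post_id = 99,
                                               synapse_count = 1)),
               "unknown neuron id.*99")
  expect_warning(
    circuit_graph(transform(nodes, cell_class = "mystery"), e),
    "unknown cell_class")
})

test_that("neuron names parse into group, segment, side and index", {
  p <- parse_neuron_name("INsplitCR_sg2r1")
  expect_equal(unname(unlist(p)), c("INsplitCR", "sg2", "right", "1"))
  p2 <- parse_neuron_name("pygPBunp")
  expect_equal(unname(unlist(p2[, 1:3])), c("pygPBunp", "unknown", "unpaired"))
  expect_true(is.na(p2$index))
  p3 <- parse_neuron_name("")
  expect_equal(p3$group, "")
  expect_equal(p3$side, "unpaired")
  # vectorized, with the side-only fallback
  p4 <- parse_neuron_name(c("MNcrab_sg3l2", "Loop_r1"))
  expect_equal(p4$segment, c("sg3", "unknown"))
  expect_equal(p4$side, c("left", "right"))
  expect_equal(p4$group, c("MNcrab", "Loop"))
})

test_that("inclusion rule counts total synapses and distinct seeds", {
  g <- toy_graph()
  sel <- select_direct_targets(g, toy_seeds())
  # X pair (2+1 from two seeds) in; Y_r (3+2) in; Y_l (1 from 1 seed) out;
  # Z (2 syn, 1 seed) out; fragment and glia pass the raw rule
  expect_identical(sel, c(5L, 6L, 8L, 10L, 11L))
  expect_identical(sel, oracle_select(g, toy_seeds()))
  # thresholds are parameters
  expect_identical(select_direct_targets(g, toy_seeds(), 5, 1),
                   oracle_select(g, toy_seeds(), 5, 1))
  expect_warning(out <- select_direct_targets(g, integer(0)), "empty seed")
  expect_length(out, 0)
})

test_that("bilateral rescue is single-pass and adds only partnered neurons", {
  g <- toy_graph()
  sel <- select_direct_targets(g, toy_seeds())
  add <- bilateral_rescue(g, toy_seeds(), sel)
  expect_identical(add, 7L)  # Y_l rescued via selected partner Y_r
  expect_identical(add, oracle_rescue(g, toy_seeds(), sel))
  expect_length(intersect(add, sel), 0)
  # second pass over the enlarged set is a no-op
  expect_length(bilateral_rescue(g, toy_seeds(), union(sel, add)), 0)
  expect_length(bilateral_rescue(g, toy_seeds(), integer(0)), 0)
})

test_that("exclusion removes fragments and glia; unpaired removal is opt-in", {
  g <- toy_graph()
  cand <- c(5L, 6L, 7L, 8L, 9L, 10L, 11L)
  res <- exclude_unqualified(g, cand)
  expect_identical(res$kept, c(5L, 6L, 7L, 8L, 9L))
  expect_identical(res$excluded$reason[res$excluded$neuron_id == 10], "fragment")
  expect_identical(res$excluded$reason[res$excluded$neuron_id == 11], "glia")
  # opt-in unpaired exclusion per cell class drops Z but keeps paired cells
  res2 <- exclude_unqualified(g, cand, require_bilateral = "interneuron")
  expect_false(9L %in% res2$kept)
  expect_identical(res2$excluded$reason[res2$excluded$neuron_id == 9], "unpaired")
  res3 <- exclude_unqualified(g, c(5L, 6L))
  expect_equal(nrow(res3$excluded), 0)
})

test_that("motoneuron layer keeps effector-driving targets only", {
  g <- toy_graph()
  layer1 <- c(5L, 6L, 7L, 8L)
  mns <- select_motoneuron_layer(g, layer1)
  expect_identical(mns, c(12L, 13L))  # M pair in, J (no effector output) out
  expect_length(select_motoneuron_layer(g, 16L), 0)  # J has no outputs
})

test_that("grouping conserves synapse totals and computes log10 display weights", {
  g <- toy_graph()
  members <- c(1:8, 12:15)
  gn <- group_network(g, members)
  internal <- g$edges[g$edges$pre_id %in% members & g$edges$post_id %in% members, ]
  expect_identical(sum(gn$edges$total_synapses), sum(internal$synapse_count))
  # two X neurons each contacting an M neuron with 4 synapses -> edge (X, M, 8)
  xm <- gn$edges[gn$edges$source == "X" & gn$edges$target == "M", ]
  expect_equal(xm$total_synapses, 8)
  expect_equal(xm$display_weight, log10(8))
  expect_equal(gn$nodes$member_count[gn$nodes$group == "CRa"], 2)
  expect_error(group_network(g, c(5L, NA)), "without a group")

  # single-neuron groups reproduce the neuron-level graph
  g1 <- toy_graph()
  g1$nodes$group <- g1$nodes$name
  gn1 <- group_network(g1, g1$nodes$neuron_id)
  expect_equal(nrow(gn1$edges), nrow(g1$edges))
  expect_true(all(gn1$nodes$member_count == 1))
})

test_that("edge filtering respects the <min boundary and is idempotent", {
  g <- toy_graph()
  gn <- group_network(g, g$nodes$neuron_id[g$nodes$has_soma])
  f5 <- filter_edges(gn, 5)
  expect_true(all(f5$edges$total_synapses >= 5))
  # boundary: an edge with exactly 5 synapses survives a <5 filter
  gn_b <- gn; gn_b$edges$total_synapses <- c(4L, 5L, rep(6L, nrow(gn$edges) - 2))
  f <- filter_edges(gn_b, 5)
  expect_false(4L %in% f$edges$total_synapses)
  expect_true(5L %in% f$edges$total_synapses)
  expect_identical(filter_edges(f5, 5), f5)
  expect_identical(filter_edges(gn, 1)$edges, gn$edges)
  expect_error(filter_edges(gn, 0), ">= 1")
})

test_that("display weight is the common logarithm", {
  expect_equal(edge_display_weight(10), 1)
  expect_equal(edge_display_weight(1), 0)
  expect_equal(edge_display_weight(5), 0.69897, tolerance = 1e-5)
  expect_error(edge_display_weight(0), ">= 1")
})

test_that("grouped networks round-trip through CSV and GraphML; DOT has one line per edge", {
  g <- toy_graph()
  gn <- group_network(g, g$nodes$neuron_id[g$nodes$has_soma])
  dir <- withr::local_tempdir()

  csv <- file.path(dir, "net.csv")
  export_network(gn, csv, format = "csv")
  back <- read_network(csv, format = "csv")
  expect_equal(back$edges$total_synapses, gn$edges$total_synapses)
  expect_equal(back$nodes, gn$nodes)

  gml <- file.path(dir, "net.graphml")
  export_network(gn, gml, format = "graphml")
  back2 <- read_network(gml, format = "graphml")
  o <- order(back2$edges$source, back2$edges$target)
  expect_equal(back2$edges$total_synapses[o], gn$edges$total_synapses)
  expect_equal(sort(back2$nodes$group), sort(gn$nodes$group))

  dot <- file.path(dir, "net.dot")
  export_network(gn, dot, format = "dot")
  lines <- readLines(dot)
  expect_equal(sum(grepl("->", lines)), nrow(gn$edges))

  # empty network still exports a valid document
  empty <- group_network(g, integer(0))
  expect_silent(export_network(empty, file.path(dir, "empty.graphml"),
                               format = "graphml"))
})

test_that("selection matches the brute-force oracle on random graphs", {
  for (s in 1:10) {
    g <- random_graph(n_nodes = sample(20:200, 1), n_edges = 400, seed = s)
    seeds <- sample(g$nodes$neuron_id, 6)
    expect_identical(select_direct_targets(g, seeds),
                     oracle_select(g, seeds))
    sel <- select_direct_targets(g, seeds)
    expect_identical(bilateral_rescue(g, seeds, sel),
                     oracle_rescue(g, seeds, sel))
  }
})

test_that("filtering at min 1 commutes with grouping", {
  g <- random_graph(80, 300, seed = 42)
  gn <- group_network(g, g$nodes$neuron_id)
  expect_identical(filter_edges(gn, 1), gn)
})
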