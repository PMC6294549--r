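# Shared fixtures and independent brute-force oracles.

# Hand-built toy circuit exercising every extraction rule:
#   1/2  CRa left/right (seed pair)      3/4  CRb left/right (seed pair)
#   5/6  X  pair: 2 syn from CRa_l + 1 from CRb_l -> passes 3-from-2 rule
#   7/8  Y  pair: Y_r passes (3 + 2 from both seeds); Y_l has only 1 syn
#        from 1 seed -> rescued via partner
#   9    Z  unpaired interneuron, 2 syn from one seed -> never included
#   10   F  soma-less fragment passing the synapse rule -> excluded
#   11   G  glia passing the synapse rule -> excluded
#   12/13 M motoneuron pair targeted by X; innervates muscle 14/15
#   14/15 MUS muscle pair
#   16   J  interneuron targeted by X with no effector output
toy_graph <- function() {
  nodes <- data.frame(
    neuron_id = 1:16,
    name = c("CRa_l1", "CRa_r1", "CRb_l1", "CRb_r1", "X_l1", "X_r1",
             "Y_l1", "Y_r1", "Z", "frag1", "glia1", "M_l1", "M_r1",
             "MUS_l1", "MUS_r1", "J_l1"),
    cell_class = c(rep("sensory", 4), rep("interneuron", 5), "fragment",
                   "glia", "motoneuron", "motoneuron", "muscle_effector",
                   "muscle_effector", "interneuron"),
    group = c("CRa", "CRa", "CRb", "CRb", "X", "X", "Y", "Y", "Z",
              "frag", "glia", "M", "M", "MUS", "MUS", "J"),
    side = c("left", "right", "left", "right", "left", "right", "left",
             "right", "unpaired", "unpaired", "unpaired", "left", "right",
             "left", "right", "left"),
    segment = c(rep("head", 4), rep("sg1", 4), "pygidium", "unknown",
                "head", "sg1", "sg1", "sg2", "sg2", "sg1"),
    has_soma = c(rep(TRUE, 9), FALSE, rep(TRUE, 6)),
    partner_id = c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L, NA, NA, NA, 13L, 12L,
                   15L, 14L, NA))
  edges <- data.frame(
    pre_id  = c(1L, 3L, 2L, 4L, 1L, 2L, 4L, 1L, 1L, 3L, 1L, 3L,
                5L, 6L, 12L, 13L, 5L),
    post_id = c(5L, 5L, 6L, 6L, 7L, 8L, 8L, 9L, 10L, 10L, 11L, 11L,
                12L, 13L, 14L, 15L, 16L),
    synapse_count = c(2L, 1L, 2L, 1L, 1L, 3L, 2L, 2L, 4L, 3L, 3L, 2L,
                      4L, 4L, 3L, 3L, 2L))
  circuit_graph(nodes, edges)
}

toy_seeds <- function() 1:4

# Brute-force oracle for the seed-based inclusion rule: a literal loop
# over every non-seed node, independent of the package's aggregation.
oracle_select <- function(graph, seeds, min_syn = 3, min_seeds = 2) {
  out <- integer(0)
  for (id in setdiff(graph$nodes$neuron_id, seeds)) {
    e <- graph$edges[graph$edges$post_id == id & graph$edges$pre_id %in% seeds, ]
    if (nrow(e) && sum(e$synapse_count) >= min_syn &&
        length(unique(e$pre_id)) >= min_seeds)
      out <- c(out, id)
  }
  sort(out)
}

oracle_rescue <- function(graph, seeds, selected) {
  out <- integer(0)
  for (id in setdiff(graph$nodes$neuron_id, c(seeds, selected))) {
    e <- graph$edges[graph$edges$post_id == id & graph$edges$pre_id %in% seeds, ]
    if (!nrow(e)) next
    p <- graph$nodes$partner_id[graph$nodes$neuron_id == id]
    if (!is.na(p) && p %in% selected) out <- c(out, id)
  }
  sort(out)
}

# Minimum-hop oracle by Boolean matrix powers (independent of igraph).
oracle_hops <- function(graph, from, to, max_hops = 10) {
  ids <- graph$nodes$neuron_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  A[cbind(match(graph$edges$pre_id, ids), match(graph$edges$post_id, ids))] <- TRUE
  reach <- A
  hops <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  hops[reach] <- 1L
  P <- A
  for (k in 2:max_hops) {
    P <- (P %*% A) > 0
    new <- P & is.na(hops)
    hops[new] <- k
  }
  hops[as.character(from), as.character(to), drop = FALSE]
}

# Exact Wilcoxon-Pratt oracle: full enumeration over all 2^m sign vectors.
oracle_wilcoxon_pratt <- function(d, alternative = "greater") {
  r <- rank(abs(d), ties.method = "average")
  nz <- d != 0
  rk <- r[nz]
  m <- length(rk)
  W <- sum(rk[d[nz] > 0])
  if (m == 0) return(list(W = 0, p = 1))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  sums <- as.vector(signs %*% rk)
  p_g <- mean(sums >= W - 1e-9)
  p_l <- mean(sums <= W + 1e-9)
  p <- switch(alternative, greater = p_g, less = p_l,
              two.sided = min(1, 2 * min(p_g, p_l)))
  list(W = W, p = p)
}

# Random sparse circuit for property tests.
random_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  n_pair <- floor(n_nodes / 2)
  ids <- seq_len(2 * n_pair)
  partner <- as.integer(ifelse(ids %% 2 == 1, ids + 1, ids - 1))
  nodes <- data.frame(
    neuron_id = ids,
    name = paste0("n", ids),
    cell_class = sample(c("sensory", "interneuron", "motoneuron",
                          "muscle_effector"), 2 * n_pair, replace = TRUE),
    group = paste0("g", ceiling(ids / 2)),
    side = rep(c("left", "right"), n_pair),
    segment = sample(c("head", "sg1", "sg2", "sg3"), 2 * n_pair, replace = TRUE),
    has_soma = TRUE, partner_id = partner)
  pre <- sample(ids, n_edges, replace = TRUE)
  post <- sample(ids, n_edges, replace = TRUE)
  keep <- pre != post
  edges <- data.frame(pre_id = pre[keep], post_id = post[keep],
                      synapse_count = sample(1:6, sum(keep), replace = TRUE))
  suppressWarnings(circuit_graph(nodes, edges))
}

# Map an edge table through the bilateral partner map.
mirror_edges <- function(graph) {
  p <- graph$nodes$partner_id[match(graph$edges$pre_id, graph$nodes$neuron_id)]
  q <- graph$nodes$partner_id[match(graph$edges$post_id, graph$nodes$neuron_id)]
  data.frame(pre_id = ifelse(is.na(p), graph$edges$pre_id, p),
             post_id = ifelse(is.na(q), graph$edges$post_id, q),
             synapse_count = graph$edges$synapse_count)
}

edge_key <- function(e) sort(paste(e$pre_id, e$post_id, e$synapse_count))
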