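#' Configuration for the synthetic connectome generator
#'
#' Describes a layered, bilaterally symmetric sensory-motor network of the
#' kind reconstructed for the larval startle circuit: collar-receptor (CR)
#' seed neurons feeding interneuron relays, which feed motoneurons, which
#' innervate muscle and ciliary-band effectors. Neurons come in left/right
#' pairs unless a group is declared unpaired; edges carry integer synapse
#' counts; the right body side mirrors the left except where
#' `asymmetry_rate` breaks a mirrored edge.
#'
#' @param n_segments Number of chaeta-bearing trunk segments (default 3,
#'   the nectochaete body plan). Segmentally iterated groups distribute
#'   their members round-robin over `sg1 ... sg<n_segments>`.
#' @param groups_per_layer Named list mapping each layer, in order from
#'   sensory seeds to effectors, to a character vector of group names.
#'   Layer names `sensory`, `interneuron`, `motoneuron` set the cell class
#'   of their groups; groups in the final (`effector`) layer are
#'   `ciliated_effector` when listed in `ciliated_groups`, otherwise
#'   `muscle_effector`.
#' @param neurons_per_group_per_side Neurons per group on each body side
#'   (>= 1).
#' @param synapse_count_distribution List with elements `family`
#'   (currently `"nbinom"`), `mean` and `dispersion`; per-connection
#'   synapse counts are drawn as `1 + NegBinom(mu = mean - 1,
#'   size = dispersion)` so every realised connection has at least one
#'   synapse. Overdispersed counts stress the >=3 / >=5 edge filters.
#' @param seed_group Character vector of group names designated as the
#'   sensory seed population (the CR analog).
#' @param asymmetry_rate Probability in \[0, 1\] that a mirrored (right-side
#'   copy) edge is dropped, breaking exact bilateral symmetry.
#' @param orphan_fragment_rate Probability in \[0, 1\] that a soma-less
#'   orphan fragment is attached downstream of the seeds for each
#'   first-layer neuron; fragments receive enough seed synapses to pass
#'   the inclusion rule and therefore exercise the soma exclusion.
#' @param unpaired_groups Groups realised as single unpaired neurons
#'   (midline cells such as the MC ciliomotor analog).
#' @param ciliated_groups Effector-layer groups that are ciliary bands
#'   rather than muscles.
#' @param head_groups,pygidial_groups Groups whose somata sit in the head
#'   or pygidium; all other groups are segmentally iterated over the trunk.
#' @param wiring Two-column data frame (`from`, `to`) of group-level
#'   connectivity. The default wires each layer onto the next with a few
#'   seed-to-motoneuron shortcuts, mirroring the direct CR-to-MC and
#'   CR-to-MNcrab contacts of the reconstructed circuit.
#' @param connection_prob Probability that a given (pre, post) neuron pair
#'   of a wired group pair is connected (seed inputs onto the first layer
#'   are guaranteed, see Details).
#' @param rng_seed Integer seed; all draws derive from it.
#'
#' @details Every first-layer neuron is guaranteed synaptic input from at
#'   least two distinct seed neurons with at least two synapses each, so
#'   the ground truth of the seed-based inclusion rule (>= 3 synapses from
#'   >= 2 seeds) is known by construction and recorded in the generator
#'   output.
#'
#' @return An object of class `connectome_config`.
#' @seealso [gen_connectome()]
#' @export
connectome_config <- function(n_segments = 3,
                              groups_per_layer = NULL,
                              neurons_per_group_per_side = 2,
                              synapse_count_distribution = list(
                                family = "nbinom", mean = 4, dispersion = 2),
                              seed_group = c("CRhead", "CRpyg"),
                              asymmetry_rate = 0,
                              orphan_fragment_rate = 0,
                              unpaired_groups = "MC",
                              ciliated_groups = c("prototroch", "bodytroch"),
                              head_groups = c("CRhead", "INrope", "INCM",
                                              "MC", "Loop", "MNant",
                                              "prototroch"),
                              pygidial_groups = "CRpyg",
                              wiring = NULL,
                              connection_prob = 0.6,
                              rng_seed = 1L) {
  check_prob(asymmetry_rate, "asymmetry_rate")
  check_prob(orphan_fragment_rate, "orphan_fragment_rate")
  check_prob(connection_prob, "connection_prob")
  if (neurons_per_group_per_side < 1)
    stopf("`neurons_per_group_per_side` must be >= 1")
  if (n_segments < 1) stopf("`n_segments` must be >= 1")
  d <- synapse_count_distribution
  if (!is.list(d) || is.null(d$family))
    stopf("`synapse_count_distribution` must be a list with a `family` element")
  if (!identical(d$family, "nbinom"))
    stopf("unsupported synapse count distribution family: %s", d$family)
  if (is.null(d$mean) || d$mean < 1 || is.null(d$dispersion) || d$dispersion <= 0)
    stopf("nbinom synapse counts need `mean` >= 1 and `dispersion` > 0")

  if (is.null(groups_per_layer)) {
    groups_per_layer <- list(
      sensory     = c("CRhead", "CRpyg"),
      interneuron = c("INrope", "INsplit", "INcomm", "INCM"),
      motoneuron  = c("MC", "Loop", "MNant", "MNcrab", "MNspider", "MNbow"),
      effector    = c("prototroch", "bodytroch", "MUSlong", "MUSob", "MUSpara")
    )
  }
  all_groups <- unlist(groups_per_layer, use.names = FALSE)
  if (anyDuplicated(all_groups))
    stopf("group names must be unique across layers")
  if (!all(seed_group %in% all_groups))
    stopf("seed_group not found among groups: %s",
          paste(setdiff(seed_group, all_groups), collapse = ", "))

  if (is.null(wiring)) {
    wiring <- rbind(
      data.frame(from = "CRhead",
                 to = c("INrope", "INsplit", "INcomm", "INCM", "MC", "MNcrab")),
      data.frame(from = "CRpyg", to = c("INsplit", "INcomm", "MNcrab")),
      data.frame(from = "INrope", to = c("Loop", "MNcrab", "MNspider", "MNbow")),
      data.frame(from = "INsplit", to = c("MNcrab", "MNspider", "MNbow")),
      data.frame(from = "INcomm", to = c("MNcrab", "MNspider")),
      data.frame(from = "INCM", to = c("Loop", "MNant")),
      data.frame(from = "MC", to = "prototroch"),
      data.frame(from = "Loop", to = c("prototroch", "bodytroch")),
      data.frame(from = "MNant", to = c("prototroch", "bodytroch")),
      data.frame(from = "MNcrab", to = c("MUSlong", "MUSob", "MUSpara")),
      data.frame(from = "MNspider", to = c("MUSlong", "MUSob")),
      data.frame(from = "MNbow", to = c("MUSob", "MUSpara"))
    )
  }
  missing <- setdiff(unique(c(wiring$from, wiring$to)), all_groups)
  if (length(missing))
    stopf("wiring refers to unknown groups: %s", paste(missing, collapse = ", "))

  structure(list(
    n_segments = as.integer(n_segments),
    groups_per_layer = groups_per_layer,
    neurons_per_group_per_side = as.integer(neurons_per_group_per_side),
    synapse_count_distribution = d,
    seed_group = seed_group,
    asymmetry_rate = asymmetry_rate,
    orphan_fragment_rate = orphan_fragment_rate,
    unpaired_groups = unpaired_groups,
    ciliated_groups = ciliated_groups,
    head_groups = head_groups,
    pygidial_groups = pygidial_groups,
    wiring = wiring,
    connection_prob = connection_prob,
    rng_seed = as.integer(rng_seed)
  ), class = "connectome_config")
}

#' Draw per-connection synapse counts (>= 1)
#' @noRd
draw_counts <- function(n, dist) {
  1L + rnbinom(n, size = dist$dispersion, mu = max(dist$mean - 1, 0))
}

#' Generate a synthetic layered connectome with known ground truth
#'
#' Builds the neuron roster group by group (left/right pairs unless
#' unpaired), wires the left body side according to the configured
#' group-level wiring, mirrors every edge through the bilateral partner
#' map, and then breaks mirrored edges at `asymmetry_rate`. Soma-less
#' orphan fragments receiving supra-threshold seed input are appended at
#' `orphan_fragment_rate`. Ground truth for the seed-based inclusion rule
#' is tallied by a direct pass over the final edge table, independently
#' of the selection functions it is used to test.
#'
#' @param cfg A [connectome_config()].
#' @return A list of class `synthetic_connectome` with elements
#'   * `neurons`: data frame (`neuron_id`, `name`, `cell_class`, `group`,
#'     `side`, `segment`, `has_soma`, `partner_id`),
#'   * `synapses`: data frame (`pre_id`, `post_id`, `synapse_count`),
#'     aggregated per (pre, post) pair,
#'   * `ground_truth`: list with `seed_ids`, `rule_pass` (ids meeting the
#'     raw >= 3-synapses-from->= 2-seeds rule), `layer1_members` (rule_pass
#'     minus soma-less fragments and glia), `orphan_fragments`, and
#'     `rescue_candidates` (ids with seed input that fail the rule but
#'     whose partner passes it).
#' @examples
#' net <- gen_connectome(connectome_config(rng_seed = 7))
#' nrow(net$neurons); nrow(net$synapses)
#' @export
gen_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "connectome_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$rng_seed)

  layer_names <- names(cfg$groups_per_layer)
  n_layers <- length(layer_names)
  class_of_layer <- function(i, layer) {
    if (i == n_layers) return(NA_character_) # decided per group below
    switch(layer, sensory = "sensory", interneuron = "interneuron",
           motoneuron = "motoneuron", "interneuron")
  }

  trunk_segments <- paste0("sg", seq_len(cfg$n_segments))
  neurons <- list()
  next_id <- 1L
  for (i in seq_along(cfg$groups_per_layer)) {
    for (g in cfg$groups_per_layer[[i]]) {
      cls <- class_of_layer(i, layer_names[i])
      if (is.na(cls))
        cls <- if (g %in% cfg$ciliated_groups) "ciliated_effector" else "muscle_effector"
      unpaired <- g %in% cfg$unpaired_groups
      n_per_side <- cfg$neurons_per_group_per_side
      segs <- if (g %in% cfg$head_groups) rep("head", n_per_side)
              else if (g %in% cfg$pygidial_groups) rep("pygidium", n_per_side)
              else trunk_segments[((seq_len(n_per_side) - 1L) %% cfg$n_segments) + 1L]
      if (unpaired) {
        neurons[[length(neurons) + 1L]] <- data.frame(
          neuron_id = next_id, name = g, cell_class = cls, group = g,
          side = "unpaired", segment = segs[1L], has_soma = TRUE,
          partner_id = NA_integer_)
        next_id <- next_id + 1L
      } else {
        for (k in seq_len(n_per_side)) {
          seg_tok <- if (segs[k] %in% trunk_segments) segs[k] else ""
          idl <- next_id; idr <- next_id + 1L
          neurons[[length(neurons) + 1L]] <- data.frame(
            neuron_id = c(idl, idr),
            name = paste0(g, "_", seg_tok, c("l", "r"), k),
            cell_class = cls, group = g, side = c("left", "right"),
            segment = segs[k], has_soma = TRUE,
            partner_id = c(idr, idl))
          next_id <- next_id + 2L
        }
      }
    }
  }
  neurons <- do.call(rbind, neurons)

  partner <- function(ids) {
    p <- neurons$partner_id[match(ids, neurons$neuron_id)]
    ifelse(is.na(p), ids, p)
  }
  seed_ids <- neurons$neuron_id[neurons$group %in% cfg$seed_group]
  dist <- cfg$synapse_count_distribution

  # Wire the left body side (unpaired neurons participate as-is).
  is_leftish <- neurons$side %in% c("left", "unpaired")
  pre_rows <- post_rows <- counts <- integer(0)
  first_layer_groups <- unique(cfg$wiring$to[cfg$wiring$from %in% cfg$seed_group])
  for (r in seq_len(nrow(cfg$wiring))) {
    gf <- cfg$wiring$from[r]; gt <- cfg$wiring$to[r]
    pre <- neurons$neuron_id[neurons$group == gf & is_leftish]
    post <- neurons$neuron_id[neurons$group == gt & is_leftish]
    if (!length(pre) || !length(post)) next
    seed_row <- gf %in% cfg$seed_group
    for (p in post) {
      if (seed_row) {
        # guarantee >= 2 distinct seed inputs with >= 2 synapses each
        base <- sample(pre, size = min(2L, length(pre)))
        w <- pmax(draw_counts(length(base), dist), 2L)
        pre_rows <- c(pre_rows, base); post_rows <- c(post_rows, rep(p, length(base)))
        counts <- c(counts, w)
        extra <- setdiff(pre, base)
        keep <- extra[runif(length(extra)) < cfg$connection_prob]
      } else {
        keep <- pre[runif(length(pre)) < cfg$connection_prob]
        if (!length(keep)) keep <- sample(pre, 1L)  # keep layers connected
      }
      if (length(keep)) {
        pre_rows <- c(pre_rows, keep)
        post_rows <- c(post_rows, rep(p, length(keep)))
        counts <- c(counts, draw_counts(length(keep), dist))
      }
    }
  }

  # Orphan fragments downstream of the seeds.
  gt_orphans <- integer(0)
  if (cfg$orphan_fragment_rate > 0) {
    n_first <- sum(neurons$group %in% first_layer_groups & is_leftish)
    n_frag <- rbinom(1L, n_first, cfg$orphan_fragment_rate)
    if (n_frag > 0) {
      frag_ids <- seq(next_id, length.out = n_frag)
      frag <- data.frame(
        neuron_id = frag_ids,
        name = paste0("fragment", seq_len(n_frag)),
        cell_class = "fragment", group = "fragment",
        side = "unpaired", segment = "unknown", has_soma = FALSE,
        partner_id = NA_integer_)
      neurons <- rbind(neurons, frag)
      next_id <- next_id + n_frag
      left_seeds <- seed_ids[neurons$side[match(seed_ids, neurons$neuron_id)] %in%
                               c("left", "unpaired")]
      for (f in frag_ids) {
        src <- sample(left_seeds, size = min(2L, length(left_seeds)))
        pre_rows <- c(pre_rows, src)
        post_rows <- c(post_rows, rep(f, length(src)))
        counts <- c(counts, pmax(draw_counts(length(src), dist), 2L))
      }
      gt_orphans <- frag_ids
    }
  }

  # Mirror through the partner map, then break mirrored edges.
  m_pre <- partner(pre_rows); m_post <- partner(post_rows)
  self_mirrored <- m_pre == pre_rows & m_post == post_rows
  m_pre <- m_pre[!self_mirrored]; m_post <- m_post[!self_mirrored]
  m_counts <- counts[!self_mirrored]
  if (cfg$asymmetry_rate > 0 && length(m_counts)) {
    keep <- runif(length(m_counts)) >= cfg$asymmetry_rate
    m_pre <- m_pre[keep]; m_post <- m_post[keep]; m_counts <- m_counts[keep]
  }
  syn <- data.frame(pre_id = c(pre_rows, m_pre),
                    post_id = c(post_rows, m_post),
                    synapse_count = c(counts, m_counts))
  syn <- aggregate(synapse_count ~ pre_id + post_id, data = syn, FUN = sum)
  syn$synapse_count <- as.integer(syn$synapse_count)
  syn <- syn[order(syn$pre_id, syn$post_id), c("pre_id", "post_id", "synapse_count")]
  rownames(syn) <- NULL

  # Ground truth by direct tally over the final edge table.
  from_seeds <- syn[syn$pre_id %in% seed_ids & !(syn$post_id %in% seed_ids), ]
  tot <- tapply(from_seeds$synapse_count, from_seeds$post_id, sum)
  nseed <- tapply(from_seeds$pre_id, from_seeds$post_id, function(x) length(unique(x)))
  post_ids <- as.integer(names(tot))
  rule_pass <- post_ids[tot >= 3 & nseed >= 2]
  meta <- neurons[match(rule_pass, neurons$neuron_id), ]
  layer1 <- rule_pass[meta$has_soma & meta$cell_class != "glia"]
  fail <- setdiff(post_ids, rule_pass)
  rescue <- fail[partner(fail) %in% rule_pass & partner(fail) != fail]

  structure(list(
    neurons = neurons,
    synapses = syn,
    ground_truth = list(
      seed_ids = sort(seed_ids),
      rule_pass = sort(rule_pass),
      layer1_members = sort(layer1),
      orphan_fragments = sort(gt_orphans),
      rescue_candidates = sort(rescue)
    )
  ), class = "synthetic_connectome")
}

#' Write / read synthetic connectome tables
#'
#' Writers emit plain CSV in the schemas consumed by
#' [read_circuit_tables()]; the ground-truth sidecar is JSON. Generated
#' tables round-trip through these functions without loss.
#'
#' @param net A `synthetic_connectome` from [gen_connectome()].
#' @param dir Output directory (created if absent).
#' @return `write_connectome()` returns the three file paths invisibly;
#'   `read_ground_truth()` returns the ground-truth list.
#' @export
write_connectome <- function(net, dir) {
  stopifnot(inherits(net, "synthetic_connectome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(neurons = file.path(dir, "neurons.csv"),
             synapses = file.path(dir, "synapses.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write.csv(net$neurons, paths[["neurons"]], row.names = FALSE)
  write.csv(net$synapses, paths[["synapses"]], row.names = FALSE)
  jsonlite::write_json(net$ground_truth, paths[["ground_truth"]],
                       auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

#' @rdname write_connectome
#' @param path Path to a ground-truth JSON sidecar.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(gt, as.integer)
}

# RNG state helpers: generators restore the caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}
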