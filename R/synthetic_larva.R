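## Synthetic segmented-larva connectome generator.
##
## Emulates the structure of a whole-body EM reconstruction of a three-day
## old annelid larva: six body regions, left/right homolog cell pairs (most
## cell types have exactly two cells, one per side), classes SN/IN/MN/
## effector plus soma-less fragments, monadic chemical synapses with a
## feed-forward SN -> IN -> MN -> effector bias, planted connectivity
## modules, and mirror-symmetric left-right connectivity with tunable
## noise. Ground truth (module labels, homolog pairs) is returned so
## downstream analyses can be tested by parameter recovery.

CLASS_ABBREV <- c(sensory = "SN", interneuron = "IN", motoneuron = "MN",
                  effector = "EF")
SEG_ABBREV <- c(head = "h", segment_0 = "s0", segment_1 = "s1",
                segment_2 = "s2", segment_3 = "s3", pygidium = "py")
CLASS_ORDER <- c(sensory = 1, interneuron = 2, motoneuron = 3, effector = 4)

#' Body-plan configuration for the synthetic larva
#'
#' @param n_types_per_class_per_segment Named integer vector: how many cell
#'   types of each class to create in every body region. Default emulates a
#'   body in which sensory and interneuron types dominate.
#' @param segments Ordered body regions (default the six regions of the
#'   three-day-old larva).
#' @param cells_per_type Cells per type; the default 2 gives one left and
#'   one right homolog, matching the observation that most neuronal cell
#'   types are represented by exactly two cells. 1 gives a single midline
#'   cell.
#' @param fragment_fraction Soma-less fragments to add, as a fraction of
#'   the number of typed cells (`n_frag = round(fraction * n_cells)`).
#' @param seed Integer seed for the body-plan stage.
#' @return A `body_plan_config` list.
#' @export
body_plan_config <- function(n_types_per_class_per_segment =
                               c(sensory = 3, interneuron = 3,
                                 motoneuron = 2, effector = 2),
                             segments = SEGMENTS,
                             cells_per_type = 2,
                             fragment_fraction = 0.15,
                             seed = 1L) {
  stopifnot(cells_per_type >= 1, fragment_fraction >= 0,
            fragment_fraction < 1,
            all(names(n_types_per_class_per_segment) %in%
                  names(CLASS_ABBREV)))
  structure(list(n_types_per_class_per_segment =
                   n_types_per_class_per_segment,
                 segments = segments, cells_per_type = cells_per_type,
                 fragment_fraction = fragment_fraction,
                 seed = as.integer(seed)),
            class = "body_plan_config")
}

#' Connectivity configuration for the synthetic larva
#'
#' Connection probabilities act on directed cell-type pairs; mirroring acts
#' on the type-level edge list, after which individual synapses are
#' instantiated on skeleton nodes.
#'
#' @param n_modules Number of planted connectivity modules (types are
#'   partitioned into modules; both homologs of a type share its module).
#' @param p_within,p_between Directed type-pair connection probability
#'   inside / across modules. `p_within >= p_between` is required so that
#'   planted structure is recoverable.
#' @param class_order_bias Multiplier (>= 1) enforcing the feed-forward
#'   SN -> IN -> MN -> effector direction: backward class transitions keep
#'   only `p / class_order_bias` of the base probability.
#' @param mirror_noise Fraction (epsilon in \[0,1\]) of left-side type
#'   edges whose right-side mirror is resampled (new target type, weight
#'   and laterality); 0 gives exactly mirror-symmetric connectivity.
#' @param synapses_per_edge_mean,synapses_per_edge_dispersion Mean (> 1)
#'   and dispersion of the per-edge synapse count, modelled as
#'   `1 + NegBin(mu = mean - 1, size = dispersion)` so edge weights are
#'   overdispersed counts >= 1 with the stated mean.
#' @param p_contralateral Probability that an edge's postsynaptic partner
#'   is the contralateral rather than ipsilateral homolog; links the two
#'   body halves into one connected graph (mirrored exactly at
#'   `mirror_noise = 0`).
#' @param fragment_synapse_rate Poisson mean of incoming and of outgoing
#'   synapses per fragment.
#' @return A `connectivity_config` list.
#' @export
connectivity_config <- function(n_modules = 3, p_within = 0.2,
                                p_between = 0.02, class_order_bias = 5,
                                mirror_noise = 0,
                                synapses_per_edge_mean = 2.5,
                                synapses_per_edge_dispersion = 1.5,
                                p_contralateral = 0.2,
                                fragment_synapse_rate = 1) {
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            p_within >= p_between, mirror_noise >= 0, mirror_noise <= 1,
            class_order_bias >= 1, synapses_per_edge_mean > 1,
            p_contralateral >= 0, p_contralateral <= 1)
  structure(list(n_modules = as.integer(n_modules), p_within = p_within,
                 p_between = p_between, class_order_bias = class_order_bias,
                 mirror_noise = mirror_noise,
                 synapses_per_edge_mean = synapses_per_edge_mean,
                 synapses_per_edge_dispersion = synapses_per_edge_dispersion,
                 p_contralateral = p_contralateral,
                 fragment_synapse_rate = fragment_synapse_rate),
            class = "connectivity_config")
}

#' Geometry parameters for synthetic skeletons
#'
#' Simple arbors: a soma-rooted main neurite plus a Poisson number of short
#' terminal twigs, mirrored exactly across the sagittal (x = 0) plane for
#' homolog pairs. All lengths in nanometres.
#'
#' @param backbone_nodes Nodes on the main neurite (soma included).
#' @param backbone_step Spacing between backbone nodes.
#' @param twig_rate Poisson mean of the number of twigs.
#' @param twig_nodes Nodes per twig.
#' @param twig_step Spacing between twig nodes.
#' @param segment_spacing Anterior-posterior distance between body regions.
#' @param side_offset Lateral distance of somata from the midline.
#' @param jitter Gaussian positional noise on the soma.
#' @return A `skeleton_geometry` list.
#' @export
skeleton_geometry <- function(backbone_nodes = 8, backbone_step = 2500,
                              twig_rate = 2, twig_nodes = 2,
                              twig_step = 800, segment_spacing = 25000,
                              side_offset = 6000, jitter = 500) {
  structure(list(backbone_nodes = backbone_nodes,
                 backbone_step = backbone_step, twig_rate = twig_rate,
                 twig_nodes = twig_nodes, twig_step = twig_step,
                 segment_spacing = segment_spacing,
                 side_offset = side_offset, jitter = jitter),
            class = "skeleton_geometry")
}

#' Generate the cell table of a synthetic larva
#'
#' Lays out `cells_per_type` cells for every (class, segment, type index)
#' combination, assigning sides (`cells_per_type = 2`: exactly one left and
#' one right homolog per type) and appending soma-less fragments.
#'
#' @param cfg A [body_plan_config()].
#' @return List with `cells` (annotation `data.frame`) and `ground_truth`
#'   (list with `homolog_pairs` and `types` tables). Deterministic under
#'   `cfg$seed`.
#' @export
generate_body_plan <- function(cfg) {
  stopifnot(inherits(cfg, "body_plan_config"))
  set.seed(cfg$seed)
  rows <- list()
  types <- list()
  for (seg in cfg$segments) {
    for (cls in names(cfg$n_types_per_class_per_segment)) {
      n_t <- cfg$n_types_per_class_per_segment[[cls]]
      if (n_t < 1) next
      for (i in seq_len(n_t)) {
        type_label <- sprintf("%s%s_%d", CLASS_ABBREV[[cls]],
                              SEG_ABBREV[[seg]], i)
        k <- cfg$cells_per_type
        sides <- if (k == 1) "middle"
                 else c(rep(c("left", "right"), k %/% 2),
                        if (k %% 2) "middle")
        suffix <- substr(sides, 1, 1)
        if (k > 2) suffix <- paste0(suffix, rep(seq_len(ceiling(k / 2)),
                                                each = 2)[seq_len(k)])
        rows[[length(rows) + 1L]] <- data.frame(
          cell_name = paste0(type_label, "_", suffix),
          cell_class = cls, cell_type = type_label, segment = seg,
          side = sides, stringsAsFactors = FALSE)
        types[[length(types) + 1L]] <- data.frame(
          cell_type = type_label, cell_class = cls, segment = seg,
          n_cells = k, stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, rows)
  n_frag <- round(cfg$fragment_fraction * nrow(cells))
  if (n_frag > 0)
    cells <- rbind(cells, data.frame(
      cell_name = sprintf("fragment_%d", seq_len(n_frag)),
      cell_class = "fragment", cell_type = NA_character_,
      segment = NA_character_, side = NA_character_,
      stringsAsFactors = FALSE))
  cells$skeleton_id <- seq_len(nrow(cells))
  cells$annotations <- ""
  cells <- cells[, c("cell_name", "skeleton_id", "cell_class", "cell_type",
                     "segment", "side", "annotations")]
  type_tab <- do.call(rbind, types)
  paired <- type_tab$cell_type[type_tab$n_cells == 2]
  homolog_pairs <- data.frame(
    cell_type = paired,
    left = paste0(paired, "_l"), right = paste0(paired, "_r"),
    stringsAsFactors = FALSE)
  list(cells = cells,
       ground_truth = list(homolog_pairs = homolog_pairs, types = type_tab))
}

## one skeleton: soma-rooted backbone plus Poisson twigs; returns the
## node table and keeps a running cable-length sum as an attribute so
## morphometry can be checked against the generator's own bookkeeping
build_arbor <- function(soma, direction, geom) {
  dirn <- direction / sqrt(sum(direction^2))
  coords <- matrix(NA_real_, nrow = 0, ncol = 3)
  parent <- integer()
  coords <- rbind(coords, soma)
  parent <- c(parent, NA_integer_)
  cable <- 0
  for (i in seq_len(geom$backbone_nodes - 1)) {
    prev <- nrow(coords)
    step <- dirn * geom$backbone_step +
      rnorm(3, 0, geom$backbone_step * 0.05)
    coords <- rbind(coords, coords[prev, ] + step)
    parent <- c(parent, prev)
    cable <- cable + sqrt(sum(step^2))
  }
  n_twigs <- rpois(1, geom$twig_rate)
  backbone_ids <- seq_len(nrow(coords))
  for (t in seq_len(n_twigs)) {
    at <- sample(backbone_ids[-1], 1)
    tdir <- rnorm(3)
    tdir <- tdir / sqrt(sum(tdir^2))
    prev <- at
    for (j in seq_len(geom$twig_nodes)) {
      step <- tdir * geom$twig_step + rnorm(3, 0, geom$twig_step * 0.05)
      coords <- rbind(coords, coords[prev, ] + step)
      parent <- c(parent, prev)
      cable <- cable + sqrt(sum(step^2))
      prev <- nrow(coords)
    }
  }
  list(coords = coords, parent = parent, cable_nm = cable)
}

mirror_nodes <- function(nodes) {
  nodes$x <- -nodes$x
  nodes
}

#' Generate synthetic skeletons for a cell table
#'
#' Left-side cells get a randomly grown arbor; the right homolog is its
#' exact mirror image across the sagittal plane (x -> -x). Fragments are
#' short soma-less node chains.
#'
#' @param cells Cell table from [generate_body_plan()].
#' @param geom A [skeleton_geometry()].
#' @param seed Integer seed.
#' @return Named list of [skeleton()] objects (names = skeleton ids). Each
#'   skeleton carries the generator's own running cable-length sum (nm) as
#'   attribute `"gen_cable_nm"`.
#' @export
generate_skeletons <- function(cells, geom = skeleton_geometry(),
                               seed = 1L) {
  set.seed(seed)
  seg_index <- setNames(seq_along(SEGMENTS) - 1L, SEGMENTS)
  skels <- vector("list", nrow(cells))
  names(skels) <- as.character(cells$skeleton_id)
  ## grow left/middle arbors first so right homologs can mirror them
  arbors <- list()
  for (i in seq_len(nrow(cells))) {
    cls <- cells$cell_class[i]
    if (cls == "fragment") {
      start <- rnorm(3, c(0, 30000, 0), 15000)
      arb <- list(coords = rbind(start, start + c(500, 500, 0),
                                 start + c(1000, 1000, 0)),
                  parent = c(NA_integer_, 1L, 2L),
                  cable_nm = 2 * sqrt(500^2 + 500^2))
      nodes <- data.frame(node_id = seq_len(3), parent_id = arb$parent,
                          x = arb$coords[, 1], y = arb$coords[, 2],
                          z = arb$coords[, 3], radius = 40, tags = "")
      sk <- skeleton(cells$skeleton_id[i], cells$cell_name[i], nodes)
      attr(sk, "gen_cable_nm") <- arb$cable_nm
      skels[[i]] <- sk
      next
    }
    side <- cells$side[i]
    if (side == "right" && !is.na(cells$cell_type[i])) {
      key <- paste0(cells$cell_type[i], ":left")
      if (!is.null(arbors[[key]])) {
        left <- arbors[[key]]
        nodes <- mirror_nodes(left$nodes)
        sk <- skeleton(cells$skeleton_id[i], cells$cell_name[i], nodes)
        attr(sk, "gen_cable_nm") <- left$cable_nm
        skels[[i]] <- sk
        next
      }
    }
    x0 <- switch(side, left = -geom$side_offset, right = geom$side_offset,
                 0)
    y0 <- seg_index[[cells$segment[i]]] * geom$segment_spacing
    soma <- c(x0, y0, 0) + rnorm(3, 0, geom$jitter)
    dirn <- c(rnorm(1, 0, 0.2), 1, rnorm(1, 0, 0.2))
    arb <- build_arbor(soma, dirn, geom)
    nodes <- data.frame(node_id = seq_len(nrow(arb$coords)),
                        parent_id = arb$parent,
                        x = arb$coords[, 1], y = arb$coords[, 2],
                        z = arb$coords[, 3],
                        radius = c(2000, rep(60, nrow(arb$coords) - 1)),
                        tags = c("soma",
                                 rep("", nrow(arb$coords) - 1)))
    sk <- skeleton(cells$skeleton_id[i], cells$cell_name[i], nodes)
    attr(sk, "gen_cable_nm") <- arb$cable_nm
    skels[[i]] <- sk
    if (side == "left" && !is.na(cells$cell_type[i]))
      arbors[[paste0(cells$cell_type[i], ":left")]] <-
        list(nodes = nodes, cable_nm = arb$cable_nm)
  }
  skels
}

draw_edge_weight <- function(n, cc) {
  1L + rnbinom(n, size = cc$synapses_per_edge_dispersion,
               mu = cc$synapses_per_edge_mean - 1)
}

#' Generate synapses with planted modules and mirror symmetry
#'
#' Samples a directed type-level edge list (within-module probability
#' `p_within`, across `p_between`, backward class transitions damped by
#' `class_order_bias`), mirrors it to the right body side, resamples an
#' `mirror_noise` fraction of the right-side mirrors, then instantiates
#' each type edge as `weight` individual monadic synapses on skeleton
#' nodes. Effector cells receive but never send synapses. Fragments send
#' and receive a small Poisson number of synapses.
#'
#' @param cells Cell table from [generate_body_plan()].
#' @param skeletons Skeleton list from [generate_skeletons()].
#' @param cc A [connectivity_config()].
#' @param seed Integer seed.
#' @return List with `connectors` (connector `data.frame`) and `module_of`
#'   (named integer vector: planted module id per typed cell).
#' @export
generate_synapses <- function(cells, skeletons, cc, seed = 1L) {
  stopifnot(inherits(cc, "connectivity_config"))
  set.seed(seed)
  typed <- cells[!is.na(cells$cell_type), ]
  types <- unique(typed$cell_type)
  type_class <- setNames(typed$cell_class[match(types, typed$cell_type)],
                         types)
  ## planted partition over types; both homologs of a type share its module
  module_of_type <- setNames(
    rep_len(seq_len(cc$n_modules), length(types))[sample(length(types))],
    types)
  pre_types <- types[type_class[types] != "effector"]
  members <- split(typed$cell_name, typed$cell_type)
  side_of <- setNames(typed$side, typed$cell_name)

  member_on <- function(ty, side) {
    m <- members[[ty]]
    hit <- m[side_of[m] == side]
    if (length(hit)) hit[1] else m[1]  # fall back for midline types
  }

  ## left-side type-level edge list
  left_edges <- list()
  for (t1 in pre_types) {
    for (t2 in types) {
      if (t1 == t2) next
      p <- if (module_of_type[[t1]] == module_of_type[[t2]])
        cc$p_within else cc$p_between
      if (CLASS_ORDER[[type_class[[t1]]]] > CLASS_ORDER[[type_class[[t2]]]])
        p <- p / cc$class_order_bias
      if (runif(1) < p)
        left_edges[[length(left_edges) + 1L]] <- list(
          pre = t1, post = t2, w = draw_edge_weight(1, cc),
          contra = runif(1) < cc$p_contralateral)
    }
  }

  ## right side: exact mirror, then resample an epsilon fraction
  right_edges <- lapply(left_edges, function(e) {
    if (runif(1) < cc$mirror_noise) {
      post <- sample(setdiff(types, e$pre), 1)
      list(pre = e$pre, post = post, w = draw_edge_weight(1, cc),
           contra = runif(1) < cc$p_contralateral)
    } else e
  })

  rows <- list()
  instantiate <- function(e, pre_side) {
    pre_cell <- member_on(e$pre, pre_side)
    post_side <- if (e$contra) setdiff(c("left", "right"), pre_side)[1]
                 else pre_side
    post_cell <- member_on(e$post, post_side)
    pre_sk <- skeletons[[as.character(
      typed$skeleton_id[typed$cell_name == pre_cell])]]
    post_sk <- skeletons[[as.character(
      typed$skeleton_id[typed$cell_name == post_cell])]]
    data.frame(
      pre_skeleton = pre_sk$skeleton_id,
      pre_node = sample(pre_sk$nodes$node_id, e$w, replace = TRUE),
      post_skeleton = post_sk$skeleton_id,
      post_node = sample(post_sk$nodes$node_id, e$w, replace = TRUE))
  }
  for (e in left_edges) rows[[length(rows) + 1L]] <- instantiate(e, "left")
  for (e in right_edges) rows[[length(rows) + 1L]] <- instantiate(e, "right")

  ## fragments: a few synapses each, never from effectors
  frag <- cells[cells$cell_class == "fragment", ]
  if (nrow(frag) && cc$fragment_synapse_rate > 0) {
    senders <- typed$cell_name[typed$cell_class != "effector"]
    receivers <- typed$cell_name
    for (i in seq_len(nrow(frag))) {
      fsk <- skeletons[[as.character(frag$skeleton_id[i])]]
      n_in <- rpois(1, cc$fragment_synapse_rate)
      n_out <- rpois(1, cc$fragment_synapse_rate)
      if (n_in > 0 && length(senders)) {
        pre_cells <- sample(senders, n_in, replace = TRUE)
        for (pc in pre_cells) {
          psk <- skeletons[[as.character(
            typed$skeleton_id[typed$cell_name == pc])]]
          rows[[length(rows) + 1L]] <- data.frame(
            pre_skeleton = psk$skeleton_id,
            pre_node = sample(psk$nodes$node_id, 1),
            post_skeleton = fsk$skeleton_id,
            post_node = sample(fsk$nodes$node_id, 1))
        }
      }
      if (n_out > 0 && length(receivers)) {
        post_cells <- sample(receivers, n_out, replace = TRUE)
        for (pc in post_cells) {
          psk <- skeletons[[as.character(
            typed$skeleton_id[typed$cell_name == pc])]]
          rows[[length(rows) + 1L]] <- data.frame(
            pre_skeleton = fsk$skeleton_id,
            pre_node = sample(fsk$nodes$node_id, 1),
            post_skeleton = psk$skeleton_id,
            post_node = sample(psk$nodes$node_id, 1))
        }
      }
    }
  }

  connectors <- if (length(rows)) do.call(rbind, rows) else
    empty_connectors()[, -1]
  connectors <- cbind(connector_id = seq_len(nrow(connectors)), connectors)
  rownames(connectors) <- NULL
  module_of <- setNames(module_of_type[typed$cell_type], typed$cell_name)
  list(connectors = connectors, module_of = module_of)
}

#' Planted-partition connectome graph
#'
#' Directed synapse-weighted benchmark graph with known module structure:
#' cells are split into equal blocks and every ordered cell pair is
#' connected with probability `p_within` (same block) or `p_between`
#' (different blocks); edge weights are overdispersed synapse counts
#' (`1 + NegBin`). Unlike [simulate_larva()], connection probabilities act
#' directly on cell pairs and there is no left-right mirroring, so the
#' planted blocks are the only community structure — the fixture for
#' module-recovery tests.
#'
#' @param n_blocks Number of planted modules.
#' @param cells_per_block Cells per module.
#' @param p_within,p_between Directed cell-pair connection probabilities.
#' @param synapses_per_edge_mean,synapses_per_edge_dispersion Edge-weight
#'   distribution (`1 + NegBin(mu = mean - 1, size = dispersion)`).
#' @param seed Integer seed.
#' @return List with `graph` (directed weighted `igraph`, vertices carry
#'   `cell_class = "interneuron"`) and `module_of` (named integer vector
#'   of planted block labels).
#' @export
planted_partition_graph <- function(n_blocks = 3, cells_per_block = 20,
                                    p_within = 0.4, p_between = 0.01,
                                    synapses_per_edge_mean = 2.5,
                                    synapses_per_edge_dispersion = 1.5,
                                    seed = 1L) {
  stopifnot(p_within >= p_between)
  set.seed(seed)
  n <- n_blocks * cells_per_block
  cells <- sprintf("cell_%03d", seq_len(n))
  block <- setNames(rep(seq_len(n_blocks), each = cells_per_block), cells)
  pair <- expand.grid(from = cells, to = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pair <- pair[pair$from != pair$to, ]
  p <- ifelse(block[pair$from] == block[pair$to], p_within, p_between)
  keep <- runif(nrow(pair)) < p
  el <- pair[keep, , drop = FALSE]
  el$weight <- 1L + rnbinom(nrow(el),
                            size = synapses_per_edge_dispersion,
                            mu = synapses_per_edge_mean - 1)
  g <- igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = cells, cell_class = "interneuron",
                          cell_type = cells, segment = "head",
                          side = "middle", stringsAsFactors = FALSE))
  list(graph = g, module_of = block)
}

## child seeds for the three generator stages, derived deterministically
## from the single global seed (kept below 2^31)
derive_seeds <- function(seed) {
  (as.numeric(seed) * 7919 + c(body = 1, skeleton = 2, synapse = 3)) %%
    2147483647
}

#' Simulate a full synthetic larva dataset with ground truth
#'
#' Runs [generate_body_plan()], [generate_skeletons()] and
#' [generate_synapses()] under child seeds derived deterministically from
#' one global seed (`child = (seed * 7919 + stage) mod (2^31 - 1)`, stage
#' 1-3), and assembles a validated [larva_dataset()].
#'
#' @param bp A [body_plan_config()].
#' @param cc A [connectivity_config()].
#' @param geom A [skeleton_geometry()].
#' @param seed Global integer seed (overrides `bp$seed` when given).
#' @return List with `dataset` (a `larva_dataset`) and `ground_truth`
#'   (homolog pairs, type table, planted `module_of`).
#' @export
simulate_larva <- function(bp = body_plan_config(),
                           cc = connectivity_config(),
                           geom = skeleton_geometry(),
                           seed = bp$seed) {
  seeds <- derive_seeds(seed)
  bp$seed <- as.integer(seeds[["body"]])
  plan <- generate_body_plan(bp)
  skels <- generate_skeletons(plan$cells, geom,
                              seed = as.integer(seeds[["skeleton"]]))
  syn <- generate_synapses(plan$cells, skels, cc,
                           seed = as.integer(seeds[["synapse"]]))
  ds <- larva_dataset(skels, syn$connectors, plan$cells, check = TRUE)
  gt <- plan$ground_truth
  gt$module_of <- syn$module_of
  list(dataset = ds, ground_truth = gt)
}
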