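## Quantitative neuroanatomy on skeletons: cable length with twig pruning,
## Gaussian smoothing, Sholl profiles, radial synapse density, polarity.
##
## Convention: skeleton coordinates are nm; cable lengths are reported in
## microns. Sholl runs on smoothed, unpruned skeletons; cable length on
## unsmoothed, pruned skeletons.

skeleton_edge_table <- function(skel) {
  n <- skel$nodes
  child <- which(!is.na(n$parent_id))
  if (!length(child))
    return(data.frame(parent = integer(), child = integer(),
                      length_nm = numeric()))
  pidx <- match(n$parent_id[child], n$node_id)
  data.frame(parent = n$node_id[pidx], child = n$node_id[child],
             length_nm = sqrt((n$x[child] - n$x[pidx])^2 +
                              (n$y[child] - n$y[pidx])^2 +
                              (n$z[child] - n$z[pidx])^2))
}

node_root_distances <- function(skel) {
  n <- skel$nodes
  r <- match(skeleton_root(skel), n$node_id)
  sqrt((n$x - n$x[r])^2 + (n$y - n$y[r])^2 + (n$z - n$z[r])^2)
}

soma_node <- function(skel) {
  hit <- skel$nodes$node_id[node_has_tag(skel$nodes$tags, "soma")]
  if (!length(hit)) stop("no soma: skeleton ", skel$cell_name,
                         " is a soma-less fragment")
  hit[1]
}

#' Remove terminal twigs below a length threshold
#'
#' A twig is the path from a tip up to (but excluding) the nearest branch
#' point. All twigs shorter than `prune_below` are identified on the
#' original topology and removed in a single pass (no cascade: a branch
#' point that becomes terminal is not re-pruned). An unbranched skeleton
#' has no twigs and is never pruned away.
#'
#' @param skel A [skeleton()].
#' @param prune_below Length threshold in microns (default 2).
#' @return The pruned skeleton.
#' @export
prune_twigs <- function(skel, prune_below = 2) {
  n <- skel$nodes
  if (nrow(n) < 2 || prune_below <= 0) return(skel)
  et <- skeleton_edge_table(skel)
  n_children <- table(factor(et$parent, levels = n$node_id))
  tips <- n$node_id[n_children[as.character(n$node_id)] == 0]
  branch <- n$node_id[n_children[as.character(n$node_id)] >= 2]
  parent_of <- setNames(n$parent_id, as.character(n$node_id))
  elen <- setNames(et$length_nm, as.character(et$child))
  drop <- integer()
  for (tip in tips) {
    path <- integer(); len <- 0; cur <- tip
    repeat {
      p <- parent_of[[as.character(cur)]]
      if (is.na(p)) { path <- NULL; break }       # reached root: no twig
      path <- c(path, cur)
      len <- len + elen[[as.character(cur)]]
      if (p %in% branch) break
      cur <- p
    }
    if (!is.null(path) && len / 1000 < prune_below)
      drop <- c(drop, path)
  }
  if (length(drop)) {
    skel$nodes <- n[!n$node_id %in% drop, , drop = FALSE]
    rownames(skel$nodes) <- NULL
    skel$has_soma <- any(node_has_tag(skel$nodes$tags, "soma"))
  }
  skel
}

#' Cable length of a skeleton
#'
#' Terminal twigs shorter than `prune_below` microns are removed
#' ([prune_twigs()], single pass), then the Euclidean lengths of the
#' remaining parent-child segments are summed.
#'
#' @param skel A rooted [skeleton()].
#' @param prune_below Twig-prune threshold in microns (default 2; set 0 to
#'   skip pruning).
#' @return Cable length in microns. A single-node skeleton has length 0.
#' @export
cable_length <- function(skel, prune_below = 2) {
  if (nrow(skel$nodes) < 2) return(0)
  trimmed <- prune_twigs(skel, prune_below)
  sum(skeleton_edge_table(trimmed)$length_nm) / 1000
}

#' Gaussian smoothing of skeleton coordinates
#'
#' Node coordinates are smoothed along each unbranched segment by
#' Gaussian-weighted local linear regression of x, y, z against arc
#' length (bandwidth `sigma`). Segment endpoints — root, branch points and
#' tips — are anchored, and topology is unchanged. Because the smoother is
#' locally linear it reproduces straight segments exactly. Intended for
#' rendering and Sholl profiles, never for synapse assignment.
#'
#' @param skel A rooted [skeleton()].
#' @param sigma Smoothing bandwidth in nm (default 6000); 0 returns the
#'   skeleton unchanged.
#' @return The smoothed skeleton.
#' @export
smooth_skeleton <- function(skel, sigma = 6000) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0 || nrow(skel$nodes) < 3) return(skel)
  n <- skel$nodes
  et <- skeleton_edge_table(skel)
  n_children <- table(factor(et$parent, levels = n$node_id))
  anchor <- n$node_id[is.na(n$parent_id) |
                        n_children[as.character(n$node_id)] != 1]
  parent_of <- setNames(n$parent_id, as.character(n$node_id))
  elen <- setNames(et$length_nm, as.character(et$child))
  idx <- setNames(seq_len(nrow(n)), as.character(n$node_id))
  ## walk up from each non-root anchor to the previous anchor: that path
  ## is one unbranched segment
  for (a in setdiff(anchor, n$node_id[is.na(n$parent_id)])) {
    path <- a; cur <- a
    repeat {
      p <- parent_of[[as.character(cur)]]
      path <- c(path, p)
      if (p %in% anchor) break
      cur <- p
    }
    path <- rev(path)                    # proximal anchor ... distal anchor
    if (length(path) < 3) next
    s <- cumsum(c(0, elen[as.character(path[-1])]))
    rows <- idx[as.character(path)]
    for (coord in c("x", "y", "z")) {
      v <- n[[coord]][rows]
      sm <- v
      for (j in seq_along(path)[-c(1, length(path))]) {
        w <- exp(-((s - s[j])^2) / (2 * sigma^2))
        ## weighted least squares line through (s, v), evaluated at s[j]
        sw <- sum(w); sbar <- sum(w * s) / sw; vbar <- sum(w * v) / sw
        den <- sum(w * (s - sbar)^2)
        slope <- if (den > 0) sum(w * (s - sbar) * (v - vbar)) / den else 0
        sm[j] <- vbar + slope * (s[j] - sbar)
      }
      n[[coord]][rows] <- sm
    }
  }
  skel$nodes <- n
  skel
}

#' Sholl profile of a skeleton
#'
#' Counts, for each radius r = step, 2 step, ..., the parent-child
#' segments whose endpoint Euclidean distances to the root straddle the
#' sphere of radius r (nearer endpoint at distance <= r, farther endpoint
#' > r). As r approaches 0 the count equals the root's degree; beyond the
#' arbor extent it is 0.
#'
#' @param skel A rooted [skeleton()].
#' @param step Radius step in nm (> 0).
#' @param max_radius Optional largest radius of the grid (defaults to the
#'   arbor extent rounded up to a multiple of `step`).
#' @return A `data.frame` of class `sholl_profile` with columns `radius`
#'   (nm) and `crossings`.
#' @export
sholl <- function(skel, step = 1000, max_radius = NULL) {
  stopifnot(step > 0)
  d <- node_root_distances(skel)
  dist_of <- setNames(d, as.character(skel$nodes$node_id))
  et <- skeleton_edge_table(skel)
  if (is.null(max_radius))
    max_radius <- if (max(d) > 0) ceiling(max(d) / step) * step else step
  radii <- seq(step, max_radius, by = step)
  dn <- pmin(dist_of[as.character(et$parent)],
             dist_of[as.character(et$child)])
  df <- pmax(dist_of[as.character(et$parent)],
             dist_of[as.character(et$child)])
  crossings <- vapply(radii, function(r)
    sum(dn <= r & df > r), integer(1))
  structure(data.frame(radius = radii, crossings = crossings),
            class = c("sholl_profile", "data.frame"))
}

#' Radial synapse density of one cell
#'
#' Euclidean distances from the soma to the skeleton nodes bearing
#' synapses (presynaptic or postsynaptic sites of the cell), histogrammed
#' in fixed-width bins. `density` is the per-bin fraction of the cell's
#' synapses.
#'
#' @param skel A soma-bearing [skeleton()].
#' @param connectors Connector `data.frame`.
#' @param bin Bin width in nm (default 1000).
#' @param role `"pre"` (the cell's presynaptic sites) or `"post"`.
#' @param max_radius Optional outer edge of the grid (defaults to the
#'   arbor extent).
#' @return `data.frame` with `bin_start`, `bin_end` (nm), `count`,
#'   `density`. Counts sum to the number of the cell's synapses in that
#'   role.
#' @export
radial_synapse_density <- function(skel, connectors, bin = 1000,
                                   role = c("pre", "post"),
                                   max_radius = NULL) {
  role <- match.arg(role)
  soma <- soma_node(skel)
  n <- skel$nodes
  si <- match(soma, n$node_id)
  rows <- connectors[connectors[[paste0(role, "_skeleton")]] ==
                       skel$skeleton_id, , drop = FALSE]
  node_ids <- rows[[paste0(role, "_node")]]
  ni <- match(node_ids, n$node_id)
  d <- sqrt((n$x[ni] - n$x[si])^2 + (n$y[ni] - n$y[si])^2 +
              (n$z[ni] - n$z[si])^2)
  if (is.null(max_radius)) {
    ext <- max(node_root_distances(skel), bin)
    max_radius <- ceiling(ext / bin) * bin
  }
  edges <- seq(0, max_radius, by = bin)
  count <- vapply(seq_len(length(edges) - 1), function(i)
    sum(d >= edges[i] & d < edges[i + 1]), integer(1))
  total <- sum(count)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             count = count,
             density = if (total > 0) count / total else rep(0, length(count)))
}

#' Class-averaged radial synapse density
#'
#' Per-cell radial profiles ([radial_synapse_density()]) of all
#' soma-bearing cells of one class, computed on a shared radius grid and
#' averaged.
#'
#' @param ds A [larva_dataset()].
#' @param cell_class Class to average over.
#' @param bin Bin width in nm.
#' @param role `"pre"` or `"post"`.
#' @return `data.frame` with `bin_start`, `bin_end`, `mean_count`,
#'   `mean_density` and `n_cells`.
#' @export
class_radial_density <- function(ds, cell_class, bin = 1000,
                                 role = c("pre", "post")) {
  role <- match.arg(role)
  ids <- ds$cells$skeleton_id[ds$cells$cell_class == cell_class]
  skels <- ds$skeletons[as.character(ids)]
  skels <- Filter(function(s) s$has_soma, skels)
  if (!length(skels)) stop("no soma-bearing cells of class ", cell_class)
  ext <- max(vapply(skels, function(s) max(node_root_distances(s), bin),
                    numeric(1)))
  max_radius <- ceiling(ext / bin) * bin
  profs <- lapply(skels, radial_synapse_density, connectors = ds$connectors,
                  bin = bin, role = role, max_radius = max_radius)
  counts <- sapply(profs, `[[`, "count")
  dens <- sapply(profs, `[[`, "density")
  data.frame(bin_start = profs[[1]]$bin_start,
             bin_end = profs[[1]]$bin_end,
             mean_count = rowMeans(counts),
             mean_density = rowMeans(dens),
             n_cells = length(skels))
}

#' Synaptic polarity of every cell
#'
#' Counts each cell's presynaptic and postsynaptic sites from the
#' connector table. The pre-fraction `n_pre / (n_pre + n_post)` separates
#' the cell classes: sensory neurons are output-dominated, effectors
#' input-only. Because synapses are monadic, total pre equals total post
#' equals the connector count.
#'
#' @param ds A [larva_dataset()].
#' @return List with `records` (`data.frame`: `cell_name`, `cell_class`,
#'   `n_pre`, `n_post`, `pre_fraction`, `NA` when the cell has no
#'   synapses) and `class_summary` (per-class median pre/post counts).
#' @export
polarity_table <- function(ds) {
  sk2cell <- skeleton_to_cell(ds)
  pre <- table(factor(sk2cell[as.character(ds$connectors$pre_skeleton)],
                      levels = ds$cells$cell_name))
  post <- table(factor(sk2cell[as.character(ds$connectors$post_skeleton)],
                       levels = ds$cells$cell_name))
  records <- data.frame(
    cell_name = ds$cells$cell_name, cell_class = ds$cells$cell_class,
    n_pre = as.integer(pre[ds$cells$cell_name]),
    n_post = as.integer(post[ds$cells$cell_name]),
    stringsAsFactors = FALSE)
  tot <- records$n_pre + records$n_post
  records$pre_fraction <- ifelse(tot > 0, records$n_pre / tot, NA_real_)
  class_summary <- do.call(rbind, lapply(
    split(records, records$cell_class), function(d)
      data.frame(cell_class = d$cell_class[1], n_cells = nrow(d),
                 median_pre = median(d$n_pre),
                 median_post = median(d$n_post))))
  rownames(class_summary) <- NULL
  list(records = records, class_summary = class_summary)
}
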