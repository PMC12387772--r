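## Sensory-to-effector path classification, intersegmental and head-trunk
## connectivity censuses.

#' Classify sensory neurons by their shortest paths to effectors
#'
#' For every sensory neuron, the number of hops (edges, unweighted
#' breadth-first search on the directed graph) to the nearest effector is
#' computed. Category labels are multi-label: a sensory neuron with a
#' direct synapse onto an effector (`sensory_motor`, 1 hop) may also be
#' `premotor` (a direct synapse onto a motoneuron); neurons reaching an
#' effector in 2+ hops are labelled by hop count, and neurons with no
#' directed path to any effector form the `no_path` set.
#'
#' @param g Connectome graph (cell level, or a type-level graph from
#'   [group_by_type()] — both carry `cell_class` on the vertices).
#' @return List with `records` (`data.frame`: `cell_name`,
#'   `hops_to_effector` (`Inf` if unreachable), `direct_to_effector`,
#'   `direct_to_motoneuron`, `categories` (semicolon-joined)), `counts`
#'   (named category counts), `max_hops` and `no_path` (cell names).
#' @export
classify_sensory_paths <- function(g) {
  cls <- igraph::V(g)$cell_class
  sn <- igraph::V(g)$name[cls == "sensory"]
  eff <- igraph::V(g)$name[cls == "effector"]
  mn <- igraph::V(g)$name[cls == "motoneuron"]
  if (!length(sn)) stop("no sensory neurons in graph")
  if (!length(eff)) stop("no effector cells in graph")
  d <- igraph::distances(g, v = sn, to = eff, mode = "out", weights = NA)
  hops <- apply(d, 1, min)
  adj <- igraph::as_data_frame(g, what = "edges")
  direct_eff <- vapply(sn, function(s)
    any(adj$from == s & adj$to %in% eff), logical(1))
  direct_mn <- vapply(sn, function(s)
    any(adj$from == s & adj$to %in% mn), logical(1))
  categories <- lapply(seq_along(sn), function(i) {
    cats <- character()
    if (direct_eff[i]) cats <- c(cats, "sensory_motor")
    if (direct_mn[i]) cats <- c(cats, "premotor")
    if (is.finite(hops[i]) && hops[i] >= 2)
      cats <- c(cats, sprintf("%d_hops", hops[i]))
    if (!is.finite(hops[i])) cats <- c(cats, "no_path")
    cats
  })
  records <- data.frame(
    cell_name = sn, hops_to_effector = unname(hops),
    direct_to_effector = unname(direct_eff),
    direct_to_motoneuron = unname(direct_mn),
    categories = vapply(categories, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  all_cats <- unlist(categories)
  list(records = records,
       counts = if (length(all_cats)) table(all_cats) else table(character()),
       max_hops = if (any(is.finite(hops))) max(hops[is.finite(hops)])
                  else NA_real_,
       no_path = sn[!is.finite(hops)])
}

#' Segment-to-segment synapse count matrix
#'
#' Entry (r1, r2) is the summed synapse count from cells with soma in body
#' region r1 onto cells with soma in region r2. Cells without a segment
#' annotation are excluded; their count is recorded in the
#' `"n_unannotated"` attribute. With `by_class = TRUE` rows and columns
#' are (class, segment) strata.
#'
#' @param g Connectome graph.
#' @param by_class Stratify by cell class as well as segment.
#' @return Integer matrix with region (or `class.region`) dimnames.
#' @export
segment_matrix <- function(g, by_class = FALSE) {
  seg <- igraph::V(g)$segment
  annotated <- !is.na(seg) & seg %in% SEGMENTS
  if (!any(annotated)) stop("no segment-annotated cells in graph")
  labels <- if (by_class)
    paste(igraph::V(g)$cell_class, seg, sep = ".") else seg
  lab <- setNames(labels, igraph::V(g)$name)
  keep <- setNames(annotated, igraph::V(g)$name)
  el <- igraph::as_data_frame(g, what = "edges")
  el <- el[keep[el$from] & keep[el$to], , drop = FALSE]
  if (by_class) {
    present_seg <- SEGMENTS[SEGMENTS %in% seg[annotated]]
    cls <- sort(unique(igraph::V(g)$cell_class[annotated]))
    levs <- as.vector(outer(cls, present_seg, paste, sep = "."))
    levs <- levs[levs %in% lab[names(keep)[keep]]]
  } else {
    levs <- SEGMENTS[SEGMENTS %in% seg[annotated]]
  }
  m <- matrix(0L, length(levs), length(levs), dimnames = list(levs, levs))
  for (i in seq_len(nrow(el)))
    m[lab[[el$from[i]]], lab[[el$to[i]]]] <-
      m[lab[[el$from[i]]], lab[[el$to[i]]]] + el$weight[i]
  attr(m, "n_unannotated") <- sum(!annotated)
  m
}

#' Head-trunk connectivity census
#'
#' Counts, per head cell, the synapses made onto cells with somata in the
#' trunk (segments 0-3 and pygidium) — the descending pathway — and, per
#' trunk cell, synapses onto head cells (ascending). Presynaptic cells are
#' ranked by descending synapse count; the distribution of target cell
#' classes is tabulated for each direction.
#'
#' @param g Connectome graph.
#' @return List with `head_to_trunk` and `trunk_to_head` (`data.frame`s:
#'   `cell_name`, `n_synapses`, `n_targets`, ranked by `n_synapses`
#'   descending) and `target_classes` (direction x target-class synapse
#'   count table).
#' @export
head_trunk_census <- function(g) {
  seg <- setNames(igraph::V(g)$segment, igraph::V(g)$name)
  cls <- setNames(igraph::V(g)$cell_class, igraph::V(g)$name)
  trunk_regions <- setdiff(SEGMENTS, "head")
  region <- ifelse(is.na(seg), NA,
                   ifelse(seg == "head", "head",
                          ifelse(seg %in% trunk_regions, "trunk", NA)))
  names(region) <- names(seg)
  el <- igraph::as_data_frame(g, what = "edges")
  el$pre_region <- region[el$from]
  el$post_region <- region[el$to]

  census_direction <- function(from_region, to_region) {
    sub <- el[!is.na(el$pre_region) & !is.na(el$post_region) &
                el$pre_region == from_region &
                el$post_region == to_region, , drop = FALSE]
    if (!nrow(sub))
      return(list(cells = data.frame(cell_name = character(),
                                     n_synapses = integer(),
                                     n_targets = integer()),
                  classes = integer()))
    per_cell <- aggregate(list(n_synapses = sub$weight),
                          by = list(cell_name = sub$from), FUN = sum)
    per_cell$n_targets <- as.integer(
      table(sub$from)[per_cell$cell_name])
    per_cell <- per_cell[order(-per_cell$n_synapses, per_cell$cell_name), ]
    rownames(per_cell) <- NULL
    classes <- tapply(sub$weight, cls[sub$to], sum)
    list(cells = per_cell, classes = classes)
  }
  h2t <- census_direction("head", "trunk")
  t2h <- census_direction("trunk", "head")
  all_classes <- sort(unique(c(names(h2t$classes), names(t2h$classes))))
  target_classes <- rbind(
    head_to_trunk = sapply(all_classes, function(k)
      if (k %in% names(h2t$classes)) h2t$classes[[k]] else 0L),
    trunk_to_head = sapply(all_classes, function(k)
      if (k %in% names(t2h$classes)) t2h$classes[[k]] else 0L))
  if (!length(all_classes)) target_classes <- matrix(0L, 2, 0,
    dimnames = list(c("head_to_trunk", "trunk_to_head"), NULL))
  list(head_to_trunk = h2t$cells, trunk_to_head = t2h$cells,
       target_classes = target_classes)
}
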