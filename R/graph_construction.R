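## Connectome graph derivation: synapse aggregation, the <3-synapse node
## filter, largest weakly connected component, and grouping to cell types.

#' Build the cell-level connectome graph
#'
#' Derivation follows the inclusion criteria used for whole-body EM
#' connectomes: (1) every synapse gets weight one and parallel synapses
#' between the same ordered cell pair are summed into one directed edge;
#' (2) in a single pass, every node whose total incident synapse count
#' (incoming + outgoing summed weights) is below `min_synapses` is
#' removed; (3) the graph is restricted to its largest weakly connected
#' component (ties broken by larger edge count, then by lexicographically
#' smallest member name). Fragments are retained as nodes.
#'
#' @param ds A validated [larva_dataset()].
#' @param min_synapses Minimum total incident synapse count (default 3,
#'   i.e. nodes with fewer than 3 synapses are dropped).
#' @param iterative If `TRUE`, repeat the removal step until no node falls
#'   below the threshold (a k-core-like variant); default `FALSE`, a
#'   single pass.
#' @return An `igraph` directed graph. Vertices are cell names with
#'   attributes `cell_class`, `cell_type`, `segment`, `side`; edges carry
#'   `weight` (summed synapse count). Graph attributes record the filter
#'   threshold and the number of nodes removed at each step
#'   (`min_synapses`, `n_removed_filter`, `n_removed_component`,
#'   `n_synapses_total`, `n_synapses_in_graph`).
#' @export
build_connectome <- function(ds, min_synapses = 3, iterative = FALSE) {
  if (!nrow(ds$connectors)) stop("no synapses in dataset")
  sk2cell <- skeleton_to_cell(ds)
  pre <- sk2cell[as.character(ds$connectors$pre_skeleton)]
  post <- sk2cell[as.character(ds$connectors$post_skeleton)]
  agg <- aggregate(list(weight = rep(1L, length(pre))),
                   by = list(from = pre, to = post), FUN = sum)
  g <- igraph::graph_from_data_frame(
    agg, directed = TRUE,
    vertices = data.frame(name = ds$cells$cell_name,
                          cell_class = ds$cells$cell_class,
                          cell_type = ds$cells$cell_type,
                          segment = ds$cells$segment,
                          side = ds$cells$side,
                          stringsAsFactors = FALSE))
  ## cells with no synapse at all never enter the synapse graph
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, isolated)
  n_synapses_total <- sum(igraph::E(g)$weight)

  incident_count <- function(g)
    igraph::strength(g, mode = "in", loops = TRUE) +
    igraph::strength(g, mode = "out", loops = TRUE)
  n_removed_filter <- length(isolated)
  repeat {
    low <- igraph::V(g)$name[incident_count(g) < min_synapses]
    if (!length(low)) break
    g <- igraph::delete_vertices(g, low)
    n_removed_filter <- n_removed_filter + length(low)
    if (!iterative) break
  }
  if (igraph::vcount(g) == 0)
    stop(sprintf("graph empty after <%d-synapse filter (%d nodes removed)",
                 min_synapses, n_removed_filter))

  comp <- igraph::components(g, mode = "weak")
  keep <- largest_component_members(g, comp)
  n_removed_component <- igraph::vcount(g) - length(keep)
  g <- igraph::induced_subgraph(g, keep)

  g <- igraph::set_graph_attr(g, "min_synapses", min_synapses)
  g <- igraph::set_graph_attr(g, "n_removed_filter", n_removed_filter)
  g <- igraph::set_graph_attr(g, "n_removed_component", n_removed_component)
  g <- igraph::set_graph_attr(g, "n_synapses_total", n_synapses_total)
  g <- igraph::set_graph_attr(g, "n_synapses_in_graph",
                              sum(igraph::E(g)$weight))
  g
}

## largest weak component; ties -> more edges, then smallest member name
largest_component_members <- function(g, comp) {
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    ecounts <- vapply(cand, function(ci) {
      sub <- igraph::induced_subgraph(
        g, igraph::V(g)[comp$membership == ci])
      igraph::ecount(sub)
    }, numeric(1))
    cand <- cand[ecounts == max(ecounts)]
  }
  if (length(cand) > 1) {
    first_names <- vapply(cand, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    cand <- cand[first_names == min(first_names)]
  }
  igraph::V(g)$name[comp$membership == cand[1]]
}

#' Directed graph density
#'
#' `e / (n * (n - 1))` for a directed simple graph with `n` nodes and `e`
#' edges (self-loops excluded from the edge count).
#'
#' @param g An `igraph` connectome graph.
#' @return Density in \[0, 1\].
#' @seealso [directed_density()] for the closed form from counts.
#' @export
graph_density <- function(g) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g) - sum(igraph::which_loop(g))
  directed_density(n, e)
}

#' @rdname graph_density
#' @param n_nodes,n_edges Node and directed-edge counts.
#' @export
directed_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("density undefined for fewer than 2 nodes")
  n_edges / (n_nodes * (n_nodes - 1))
}

#' Collapse a connectome to the cell-type level
#'
#' Cells of the same type become one node; synapse counts are summed.
#' Untyped cells and fragments are excluded (their count is recorded in
#' the graph attribute `n_excluded_untyped`). Within-type synapses are
#' retained as self-loop edges. `display_weight = sqrt(weight)` is
#' attached for plotting only; analyses use raw summed weights.
#'
#' @param g Cell-level connectome from [build_connectome()].
#' @return An `igraph` graph over cell-type labels with edge attributes
#'   `weight` and `display_weight` and vertex attributes `cell_class`,
#'   `segment` (the member cells' values; `NA` if members disagree).
#' @export
group_by_type <- function(g) {
  type <- igraph::V(g)$cell_type
  typed <- !is.na(type) & type != ""
  if (!any(typed)) stop("no typed nodes in graph")
  sub <- igraph::induced_subgraph(g, igraph::V(g)[typed])
  el <- igraph::as_data_frame(sub, what = "edges")
  vtype <- setNames(igraph::V(sub)$cell_type, igraph::V(sub)$name)
  el$from <- vtype[el$from]
  el$to <- vtype[el$to]
  agg <- aggregate(list(weight = el$weight),
                   by = list(from = el$from, to = el$to), FUN = sum)
  vmeta <- unique(data.frame(name = igraph::V(sub)$cell_type,
                             cell_class = igraph::V(sub)$cell_class,
                             segment = igraph::V(sub)$segment,
                             stringsAsFactors = FALSE))
  ## members of a type should agree on class/segment; NA out any clash
  vmeta <- do.call(rbind, lapply(split(vmeta, vmeta$name), function(d) {
    data.frame(name = d$name[1],
               cell_class = if (length(unique(d$cell_class)) == 1)
                 d$cell_class[1] else NA_character_,
               segment = if (length(unique(d$segment)) == 1)
                 d$segment[1] else NA_character_)
  }))
  tg <- igraph::graph_from_data_frame(agg, directed = TRUE,
                                      vertices = vmeta)
  igraph::E(tg)$display_weight <- sqrt(igraph::E(tg)$weight)
  tg <- igraph::set_graph_attr(tg, "n_excluded_untyped", sum(!typed))
  tg
}

#' Induced subgraph of cells matching an annotation predicate
#'
#' @param g Connectome graph.
#' @param predicate Function taking the vertex-attribute `data.frame`
#'   (columns `name`, `cell_class`, `cell_type`, `segment`, `side`) and
#'   returning a logical vector.
#' @return The induced `igraph` subgraph; edge weights untouched, no
#'   re-filtering.
#' @export
subset_connectome <- function(g, predicate) {
  va <- igraph::as_data_frame(g, what = "vertices")
  keep <- predicate(va)
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("empty selection")
  igraph::induced_subgraph(g, igraph::V(g)[keep])
}
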