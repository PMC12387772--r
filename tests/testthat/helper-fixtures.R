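# Fixture builders and independent reference (oracle) implementations.
# Oracles are deliberately naive — plain loops over tables — and share no
# code path with the package functions they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

node_df <- function(node_id, parent_id, x, y, z, radius = 0, tags = "") {
  data.frame(node_id = node_id, parent_id = parent_id, x = x, y = y,
             z = z, radius = radius, tags = tags,
             stringsAsFactors = FALSE)
}

# unbranched skeleton along +x: n nodes, spacing step (nm), soma at root
line_skeleton <- function(n = 5, step = 1000, id = 1L,
                          name = paste0("line", id)) {
  skeleton(id, name,
           node_df(seq_len(n), c(NA, seq_len(n - 1)),
                   x = (seq_len(n) - 1) * step, y = 0, z = 0,
                   tags = c("soma", rep("", n - 1))))
}

# star: `arms` straight arms of `arm_nodes` nodes radiating from the soma
star_skeleton <- function(arms = 4, arm_nodes = 5, step = 1000, id = 1L,
                          name = "star") {
  nodes <- node_df(1L, NA_integer_, 0, 0, 0, tags = "soma")
  nid <- 1L
  for (a in seq_len(arms)) {
    ang <- 2 * pi * (a - 1) / arms
    parent <- 1L
    for (j in seq_len(arm_nodes)) {
      nid <- nid + 1L
      nodes <- rbind(nodes, node_df(nid, parent, j * step * cos(ang),
                                    j * step * sin(ang), 0))
      parent <- nid
    }
  }
  skeleton(id, name, nodes)
}

# three-cell dataset with hand-placed synapses used across modules
tiny_dataset <- function() {
  sk <- list(line_skeleton(3, id = 1L, name = "A"),
             line_skeleton(3, id = 2L, name = "B"),
             line_skeleton(3, id = 3L, name = "C"))
  cells <- data.frame(
    cell_name = c("A", "B", "C"), skeleton_id = 1:3,
    cell_class = c("sensory", "interneuron", "effector"),
    cell_type = c("tA", "tB", "tC"),
    segment = c("head", "segment_1", "segment_1"),
    side = c("left", "left", "left"), annotations = "",
    stringsAsFactors = FALSE)
  conn <- data.frame(connector_id = 1:5,
                     pre_skeleton = c(1, 1, 1, 2, 2),
                     pre_node = 2, post_skeleton = c(2, 2, 2, 3, 3),
                     post_node = 2)
  larva_dataset(sk, conn, cells)
}

# dataset whose connector table is given as cell-name pairs; every cell
# gets a 2-node skeleton so endpoints always resolve
dataset_from_edges <- function(pre, post, classes = NULL, segments = NULL,
                               sides = NULL, types = NULL,
                               all_cells = NULL) {
  cells <- sort(unique(c(pre, post, all_cells)))
  sk <- lapply(seq_along(cells), function(i)
    line_skeleton(2, id = i, name = cells[i]))
  info <- data.frame(
    cell_name = cells, skeleton_id = seq_along(cells),
    cell_class = if (is.null(classes)) "interneuron" else classes[cells],
    cell_type = if (is.null(types)) cells else types[cells],
    segment = if (is.null(segments)) "head" else segments[cells],
    side = if (is.null(sides)) "middle" else sides[cells],
    annotations = "", stringsAsFactors = FALSE)
  id_of <- setNames(seq_along(cells), cells)
  conn <- data.frame(connector_id = seq_along(pre),
                     pre_skeleton = unname(id_of[pre]), pre_node = 1L,
                     post_skeleton = unname(id_of[post]), post_node = 1L)
  larva_dataset(sk, conn, info)
}

# directed weighted igraph with the vertex attributes the analyses expect
annotated_graph <- function(edges, classes = NULL, segments = NULL,
                            sides = NULL, types = NULL, cells = NULL) {
  cells <- sort(unique(c(edges$from, edges$to, cells)))
  pick <- function(v, default) if (is.null(v)) rep(default, length(cells))
                               else unname(v[cells])
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = cells,
                          cell_class = pick(classes, "interneuron"),
                          cell_type = pick(types, NA_character_),
                          segment = pick(segments, "head"),
                          side = pick(sides, "middle"),
                          stringsAsFactors = FALSE))
}

small_simulation <- function(seed = 1, mirror_noise = 0,
                             fragment_fraction = 0.15, ...) {
  simulate_larva(
    bp = body_plan_config(
      n_types_per_class_per_segment = c(sensory = 2, interneuron = 2,
                                        motoneuron = 1, effector = 1),
      segments = c("head", "segment_1", "pygidium"),
      fragment_fraction = fragment_fraction),
    cc = connectivity_config(mirror_noise = mirror_noise, ...),
    seed = seed)
}

## ---- independent reference implementations --------------------------------

# connectome derivation without igraph: aggregate -> single-pass filter ->
# largest weak component (ties: edge count, then smallest member name)
naive_build_connectome <- function(ds, min_synapses = 3) {
  map <- setNames(as.character(ds$cells$cell_name),
                  as.character(ds$cells$skeleton_id))
  pre <- map[as.character(ds$connectors$pre_skeleton)]
  post <- map[as.character(ds$connectors$post_skeleton)]
  key <- paste(pre, post, sep = "\r")
  w <- table(key)
  edges <- data.frame(
    from = sub("\r.*", "", names(w)), to = sub(".*\r", "", names(w)),
    weight = as.integer(w), stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  incident <- sapply(nodes, function(v)
    sum(edges$weight[edges$from == v]) + sum(edges$weight[edges$to == v]))
  nodes <- nodes[incident >= min_synapses]
  edges <- edges[edges$from %in% nodes & edges$to %in% nodes, ]
  if (!length(nodes)) return(NULL)
  # weak components by repeated BFS over an undirected adjacency list
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cid
      nb <- c(edges$to[edges$from == u], edges$from[edges$to == u])
      queue <- c(queue, setdiff(nb, names(comp)[!is.na(comp)]))
    }
  }
  sizes <- table(comp)
  best <- names(sizes)[sizes == max(sizes)]
  if (length(best) > 1) {
    ec <- sapply(best, function(ci) {
      m <- names(comp)[comp == as.integer(ci)]
      sum(edges$from %in% m & edges$to %in% m)
    })
    best <- best[ec == max(ec)]
  }
  if (length(best) > 1) {
    first <- sapply(best, function(ci)
      min(names(comp)[comp == as.integer(ci)]))
    best <- best[first == min(first)]
  }
  keep <- names(comp)[comp == as.integer(best[1])]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, ]
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  list(nodes = sort(keep), edges = edges)
}

graph_as_lists <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")[, c("from", "to",
                                                     "weight")]
  el <- el[order(el$from, el$to), ]
  rownames(el) <- NULL
  el$weight <- as.integer(el$weight)
  list(nodes = sort(igraph::V(g)$name), edges = el)
}

# PageRank by plain power iteration; dangling mass teleports uniformly
naive_pagerank <- function(edges, nodes, damping = 0.85, tol = 1e-14) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges)))
    W[edges$from[i], edges$to[i]] <- W[edges$from[i], edges$to[i]] +
      edges$weight[i]
  out <- rowSums(W)
  P <- W / ifelse(out > 0, out, 1)
  dangling <- out == 0
  v <- rep(1 / n, n)
  repeat {
    v_new <- (1 - damping) / n +
      damping * (as.vector(t(P) %*% v) + sum(v[dangling]) / n)
    if (max(abs(v_new - v)) < tol) break
    v <- v_new
  }
  setNames(v_new, nodes)
}

# all-pairs unweighted shortest hop counts by Floyd-Warshall
naive_hops <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) D[edges$from[i], edges$to[i]] <- 1
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

random_skeleton <- function(n_nodes = 20, id = 1L, name = "rand") {
  parent <- c(NA_integer_, vapply(2:n_nodes, function(i)
    sample(seq_len(i - 1), 1), integer(1)))
  skeleton(id, name,
           node_df(seq_len(n_nodes), parent,
                   x = cumsum(rnorm(n_nodes, 0, 800)),
                   y = cumsum(rnorm(n_nodes, 0, 800)),
                   z = cumsum(rnorm(n_nodes, 0, 800)),
                   tags = c("soma", rep("", n_nodes - 1))))
}
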