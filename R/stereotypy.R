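## Left-right stereotypy of connectivity (side-specific synapse matrices)
## and morphology (Sholl profile similarity).

#' Pair left-right homologous cells by type
#'
#' A pair is formed only for cell types with exactly one left and one
#' right member; midline, asymmetric and odd-count types are listed
#' unpaired with a reason.
#'
#' @param cells Cell annotation `data.frame` (columns `cell_name`,
#'   `cell_type`, `side`).
#' @return List with `pairs` (`data.frame`: `cell_type`, `left`, `right`)
#'   and `unpaired` (`data.frame`: `cell_type`, `reason` in
#'   `"middle"`, `"asymmetric"`, `"unbalanced"`).
#' @export
pair_homologs <- function(cells) {
  typed <- cells[!is.na(cells$cell_type), ]
  pairs <- list(); unpaired <- list()
  for (ty in unique(typed$cell_type)) {
    m <- typed[typed$cell_type == ty, ]
    nl <- sum(m$side == "left", na.rm = TRUE)
    nr <- sum(m$side == "right", na.rm = TRUE)
    if (nl == 1 && nr == 1 && nrow(m) == 2) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        cell_type = ty, left = m$cell_name[m$side == "left"],
        right = m$cell_name[m$side == "right"], stringsAsFactors = FALSE)
    } else {
      reason <- if (all(m$side == "middle", na.rm = TRUE)) "middle"
                else if (nrow(m) == 1) "asymmetric"
                else "unbalanced"
      unpaired[[length(unpaired) + 1L]] <- data.frame(
        cell_type = ty, reason = reason, stringsAsFactors = FALSE)
    }
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(cell_type = character(), left = character(),
                    right = character()),
       unpaired = if (length(unpaired)) do.call(rbind, unpaired) else
         data.frame(cell_type = character(), reason = character()))
}

#' Side-specific type-level synapse matrices
#'
#' For every ordered pair of paired cell types (T1, T2), the left matrix
#' entry is the summed synapse count from the *left* member of T1 onto the
#' members of T2 on either side; the right matrix is defined mirror-wise.
#' Zero entries are retained. Types without exactly one member per side
#' are excluded (recorded in the `"excluded_types"` attribute).
#'
#' @param g Connectome graph.
#' @param cells Cell annotation `data.frame`.
#' @param scope Optional character vector restricting the cell types used.
#' @return A `side_matrices` object: list with `types`, `left_matrix`,
#'   `right_matrix`.
#' @export
side_matrices <- function(g, cells, scope = NULL) {
  ph <- pair_homologs(cells)
  pairs <- ph$pairs
  if (!is.null(scope)) pairs <- pairs[pairs$cell_type %in% scope, ]
  if (!nrow(pairs)) stop("no paired cell types available")
  types <- sort(pairs$cell_type)
  pairs <- pairs[match(types, pairs$cell_type), ]
  type_of <- setNames(cells$cell_type, cells$cell_name)
  left_of <- setNames(pairs$left, pairs$cell_type)
  right_of <- setNames(pairs$right, pairs$cell_type)

  el <- igraph::as_data_frame(g, what = "edges")
  el$pre_type <- unname(type_of[el$from])
  el$post_type <- unname(type_of[el$to])
  el <- el[!is.na(el$pre_type) & !is.na(el$post_type) &
             el$pre_type %in% types & el$post_type %in% types, ,
           drop = FALSE]

  n <- length(types)
  left <- matrix(0L, n, n, dimnames = list(types, types))
  right <- matrix(0L, n, n, dimnames = list(types, types))
  for (i in seq_len(nrow(el))) {
    r <- el$pre_type[i]; cc <- el$post_type[i]
    if (el$from[i] == left_of[[r]])
      left[r, cc] <- left[r, cc] + el$weight[i]
    else if (el$from[i] == right_of[[r]])
      right[r, cc] <- right[r, cc] + el$weight[i]
  }
  structure(list(types = types, left_matrix = left, right_matrix = right),
            class = "side_matrices",
            excluded_types = ph$unpaired)
}

#' @export
print.side_matrices <- function(x, ...) {
  cat(sprintf("<side_matrices> %d paired types; left total %d, right total %d\n",
              length(x$types), sum(x$left_matrix), sum(x$right_matrix)))
  invisible(x)
}

#' Left-right correlation of the side-specific synapse matrices
#'
#' Pearson correlation over the flattened paired entries, zeros included.
#' High values indicate stereotypic (mirror-symmetric) connectivity.
#'
#' @param m A [side_matrices()] object.
#' @param transform `"none"` (default, raw counts) or `"sqrt"`.
#' @return Pearson r.
#' @export
lr_correlation <- function(m, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  l <- as.numeric(m$left_matrix)
  r <- as.numeric(m$right_matrix)
  if (transform == "sqrt") { l <- sqrt(l); r <- sqrt(r) }
  if (length(unique(l)) < 2 || length(unique(r)) < 2)
    stop("undefined correlation: constant matrix")
  if (all(l == r)) return(1)  # exact mirror symmetry, no float noise
  cor(l, r, method = "pearson")
}

#' Sholl-profile similarity of two skeletons
#'
#' Sholl profiles of both skeletons are computed on a shared radius grid
#' extending to the larger of the two arbor extents, then correlated
#' (Pearson). A skeleton and its exact mirror image have similarity 1.
#'
#' @param left,right Two rooted [skeleton()] objects.
#' @param step Radius step in nm.
#' @return Pearson correlation of the two crossing profiles.
#' @export
sholl_similarity <- function(left, right, step = 1000) {
  if (nrow(left$nodes) < 2 || nrow(right$nodes) < 2)
    stop("degenerate single-node skeleton")
  max_r <- max(node_root_distances(left), node_root_distances(right))
  ## grid stays strictly inside the larger extent so the trailing
  ## all-zero radius never masks a constant profile
  n_r <- max(1, ceiling(max_r / step - 1e-9) - 1)
  pl <- sholl(left, step = step, max_radius = n_r * step)
  pr <- sholl(right, step = step, max_radius = n_r * step)
  if (length(unique(pl$crossings)) < 2 || length(unique(pr$crossings)) < 2)
    stop("undefined correlation: constant Sholl profile")
  cor(pl$crossings, pr$crossings, method = "pearson")
}
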