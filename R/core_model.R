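#' larvanet: whole-body connectome derivation and analysis
#'
#' Tools to derive a synapse-weighted directed connectome graph from
#' CATMAID-style exports (SWC skeletons, connector and annotation tables)
#' and to analyse it: module detection, centrality ranking, left-right
#' stereotypy, sensory-to-effector path classification, segmental
#' connectivity censuses and skeleton morphometrics. A synthetic
#' segmented-larva generator ([simulate_larva()]) provides datasets with
#' known ground truth for every stage.
#'
#' @section Conventions:
#' All coordinates are in nanometres, as exported by CATMAID. Chemical
#' synapses are monadic: one presynaptic (skeleton, node) endpoint and one
#' postsynaptic (skeleton, node) endpoint. Cell identity is keyed by
#' `cell_name`; `skeleton_id` is file-level plumbing. Body-region
#' membership comes from annotations, never from coordinates.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rnbinom rnorm rpois runif setNames cor aggregate
#' @importFrom utils read.delim write.table read.table packageVersion
NULL

## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies for cell annotations
#'
#' Cell classes (sensory, inter-, motoneuron, effector, other non-neuronal,
#' soma-less fragment), the six body regions of the three-day-old larva
#' (head, cryptic segment 0, chaetigerous segments 1-3, pygidium) and body
#' sides.
#'
#' @name vocabularies
#' @keywords datasets
NULL

#' @rdname vocabularies
#' @export
CELL_CLASSES <- c("sensory", "interneuron", "motoneuron", "effector",
                  "other_non_neuronal", "fragment")

#' @rdname vocabularies
#' @export
SEGMENTS <- c("head", "segment_0", "segment_1", "segment_2", "segment_3",
              "pygidium")

#' @rdname vocabularies
#' @export
SIDES <- c("left", "right", "middle")

## Constructors ---------------------------------------------------------------

#' Create a skeleton object
#'
#' A skeleton is a rooted tree of 3D nodes (in nanometres) tracing one cell
#' or fragment. Exactly one node must be the root (`parent_id` `NA`); a
#' complete cell carries the tag `"soma"` on its root, a fragment carries no
#' soma tag anywhere.
#'
#' @param skeleton_id Integer identifier.
#' @param cell_name Unique cell (or fragment) name.
#' @param nodes `data.frame` with columns `node_id`, `parent_id` (`NA` for
#'   the root), `x`, `y`, `z` (nm), `radius` (nm, 0 = unknown) and `tags`
#'   (semicolon-joined strings, `""` for none).
#' @return An object of class `larva_skeleton` with fields `skeleton_id`,
#'   `cell_name`, `nodes` and `has_soma`.
#' @export
skeleton <- function(skeleton_id, cell_name, nodes) {
  stopifnot(is.data.frame(nodes))
  required <- c("node_id", "parent_id", "x", "y", "z", "radius", "tags")
  missing <- setdiff(required, names(nodes))
  if (length(missing))
    stop("skeleton nodes missing columns: ", paste(missing, collapse = ", "))
  nodes <- nodes[, required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$tags <- as.character(nodes$tags)
  rownames(nodes) <- NULL
  structure(
    list(skeleton_id = as.integer(skeleton_id),
         cell_name = as.character(cell_name),
         nodes = nodes,
         has_soma = any(node_has_tag(nodes$tags, "soma"))),
    class = "larva_skeleton")
}

node_has_tag <- function(tags, tag) {
  vapply(strsplit(tags, ";", fixed = TRUE),
         function(tt) tag %in% tt, logical(1))
}

#' @export
print.larva_skeleton <- function(x, ...) {
  cat(sprintf("<larva_skeleton> %s (id %d): %d nodes, %s\n",
              x$cell_name, x$skeleton_id, nrow(x$nodes),
              if (x$has_soma) "soma-rooted" else "fragment (no soma)"))
  invisible(x)
}

#' Root node id of a skeleton
#' @param skel A `larva_skeleton`.
#' @return Integer node id of the root (the node with no parent).
#' @export
skeleton_root <- function(skel) {
  r <- skel$nodes$node_id[is.na(skel$nodes$parent_id)]
  if (length(r) != 1L)
    stop("skeleton ", skel$cell_name, " has ", length(r), " roots")
  r
}

#' Assemble a dataset from its parts
#'
#' @param skeletons List of [skeleton()] objects.
#' @param connectors `data.frame` of monadic synapses with columns
#'   `connector_id`, `pre_skeleton`, `pre_node`, `post_skeleton`,
#'   `post_node`.
#' @param cells Cell-annotation `data.frame` with columns `cell_name`,
#'   `skeleton_id`, `cell_class`, `cell_type` (`NA` if untyped), `segment`,
#'   `side`, `annotations` (semicolon-joined free annotations).
#' @param check If `TRUE` (default) run [validate_dataset()] and stop on
#'   referential-integrity violations.
#' @return An object of class `larva_dataset`.
#' @export
larva_dataset <- function(skeletons, connectors = empty_connectors(),
                          cells, check = TRUE) {
  if (is.null(names(skeletons)))
    names(skeletons) <- vapply(skeletons,
                               function(s) as.character(s$skeleton_id),
                               character(1))
  connectors <- as.data.frame(connectors)
  for (col in c("connector_id", "pre_skeleton", "pre_node",
                "post_skeleton", "post_node"))
    connectors[[col]] <- as.integer(connectors[[col]])
  cells <- as.data.frame(cells)
  ds <- structure(list(skeletons = skeletons, connectors = connectors,
                       cells = cells),
                  class = "larva_dataset")
  if (check) {
    if (anyDuplicated(cells$cell_name))
      stop("duplicate cell_name: ",
           paste(unique(cells$cell_name[duplicated(cells$cell_name)]),
                 collapse = ", "))
    bad <- connector_resolution_violations(ds)
    if (nrow(bad))
      stop("unresolved connector endpoint(s): connector_id ",
           paste(bad$entity, collapse = ", "), " (", bad$detail[1], ")")
  }
  ds
}

#' @export
print.larva_dataset <- function(x, ...) {
  n_soma <- sum(vapply(x$skeletons, `[[`, logical(1), "has_soma"))
  cat(sprintf(paste0("<larva_dataset> %d skeletons (%d with soma, %d ",
                     "fragments), %d connectors, %d annotated cells\n"),
              length(x$skeletons), n_soma, length(x$skeletons) - n_soma,
              nrow(x$connectors), nrow(x$cells)))
  invisible(x)
}

#' Empty connector table
#' @return Zero-row connector `data.frame` with the canonical columns.
#' @export
empty_connectors <- function() {
  data.frame(connector_id = integer(), pre_skeleton = integer(),
             pre_node = integer(), post_skeleton = integer(),
             post_node = integer())
}

#' Map skeleton ids to cell names
#' @param ds A `larva_dataset`.
#' @return Named character vector, names are skeleton ids.
#' @export
skeleton_to_cell <- function(ds) {
  setNames(as.character(ds$cells$cell_name),
           as.character(ds$cells$skeleton_id))
}

## SWC + TSV I/O --------------------------------------------------------------

parse_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(data.frame(node_id = integer(), parent_id = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric(), tags = character()))
  m <- read.table(text = lines, col.names = c("index", "type", "x", "y",
                                              "z", "radius", "parent"))
  data.frame(node_id = as.integer(m$index),
             parent_id = ifelse(m$parent == -1L, NA_integer_,
                                as.integer(m$parent)),
             x = as.numeric(m$x), y = as.numeric(m$y), z = as.numeric(m$z),
             radius = as.numeric(m$radius),
             tags = ifelse(m$type == 1L, "soma", ""))
}

#' Read a dataset from CATMAID-style export files
#'
#' Expects one SWC file per skeleton (named `<cell_name>.swc`, SWC columns
#' index/type/x/y/z/radius/parent with parent -1 for the root and
#' structure type 1 mapped to the `"soma"` tag), a connector TSV
#' (`connector_id`, `pre_skeleton`, `pre_node`, `post_skeleton`,
#' `post_node`) and an annotation table, either TSV or JSON (columns
#' `cell_name`, `skeleton_id`, `cell_class`, `cell_type`, `segment`,
#' `side`, `annotations`). An optional `tags.tsv` in `skeleton_dir`
#' (columns `skeleton_id`, `node_id`, `tag`) restores node tags beyond the
#' soma tag, which SWC cannot carry.
#'
#' @param skeleton_dir Directory of SWC files.
#' @param connectors Path to the connector TSV.
#' @param annotations Path to the annotation TSV or JSON.
#' @return A validated [larva_dataset()]. Coordinates are preserved in nm.
#' @export
read_dataset <- function(skeleton_dir, connectors, annotations) {
  stopifnot(dir.exists(skeleton_dir), file.exists(connectors),
            file.exists(annotations))
  cells <- if (grepl("\\.json$", annotations, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(annotations))
  } else {
    read.delim(annotations, stringsAsFactors = FALSE,
               na.strings = c("NA", ""))
  }
  if (!nrow(cells)) {
    cells <- data.frame(cell_name = character(), skeleton_id = integer(),
                        cell_class = character(), cell_type = character(),
                        segment = character(), side = character(),
                        annotations = character())
  }
  cells$annotations[is.na(cells$annotations)] <- ""
  if (anyDuplicated(cells$cell_name))
    stop("duplicate cell_name in annotation table: ",
         paste(unique(cells$cell_name[duplicated(cells$cell_name)]),
               collapse = ", "))

  tag_file <- file.path(skeleton_dir, "tags.tsv")
  extra_tags <- if (file.exists(tag_file))
    read.delim(tag_file, stringsAsFactors = FALSE) else NULL

  skels <- lapply(seq_len(nrow(cells)), function(i) {
    f <- file.path(skeleton_dir, paste0(cells$cell_name[i], ".swc"))
    if (!file.exists(f)) stop("missing SWC file for cell ",
                              cells$cell_name[i], ": ", f)
    nodes <- parse_swc(f)
    if (sum(is.na(nodes$parent_id)) != 1L)
      stop("skeleton ", cells$cell_name[i], " has ",
           sum(is.na(nodes$parent_id)), " roots (expected exactly 1)")
    if (!is.null(extra_tags)) {
      et <- extra_tags[extra_tags$skeleton_id == cells$skeleton_id[i], ]
      if (nrow(et)) {
        add <- vapply(nodes$node_id, function(nid)
          paste(et$tag[et$node_id == nid], collapse = ";"), character(1))
        nodes$tags <- ifelse(add == "", nodes$tags,
                             ifelse(nodes$tags == "", add,
                                    paste(nodes$tags, add, sep = ";")))
      }
    }
    skeleton(cells$skeleton_id[i], cells$cell_name[i], nodes)
  })
  names(skels) <- as.character(cells$skeleton_id)

  conn <- read.delim(connectors, stringsAsFactors = FALSE)
  if (!nrow(conn)) conn <- empty_connectors()
  larva_dataset(skels, conn, cells, check = TRUE)
}

#' Write a dataset as SWC + TSV interchange files
#'
#' Emits one `<cell_name>.swc` per skeleton, `connectors.tsv` and
#' `annotations.tsv` into `out_dir` (plus `tags.tsv` when any node carries
#' tags beyond `"soma"`). `read_dataset()` on the output reproduces the
#' dataset exactly.
#'
#' @param ds A `larva_dataset`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, `out_dir`.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  extra <- list()
  for (skel in ds$skeletons) {
    n <- skel$nodes
    soma <- node_has_tag(n$tags, "soma")
    swc <- data.frame(index = n$node_id, type = ifelse(soma, 1L, 0L),
                      x = n$x, y = n$y, z = n$z, radius = n$radius,
                      parent = ifelse(is.na(n$parent_id), -1L, n$parent_id))
    f <- file.path(out_dir, paste0(skel$cell_name, ".swc"))
    writeLines(c("# index type x y z radius parent",
                 do.call(sprintf,
                         c(list("%d %d %.17g %.17g %.17g %.17g %d"),
                           swc))), f)
    rest <- lapply(strsplit(n$tags, ";", fixed = TRUE), setdiff, "soma")
    keep <- lengths(rest) > 0
    if (any(keep))
      extra[[length(extra) + 1L]] <- data.frame(
        skeleton_id = skel$skeleton_id,
        node_id = rep(n$node_id[keep], lengths(rest[keep])),
        tag = unlist(rest[keep]))
  }
  if (length(extra))
    write.table(do.call(rbind, extra), file.path(out_dir, "tags.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$connectors, file.path(out_dir, "connectors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$cells, file.path(out_dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(out_dir)
}

## Validation -----------------------------------------------------------------

violation <- function(entity, rule, detail) {
  data.frame(entity = as.character(entity), rule = rule, detail = detail,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(entity = character(), rule = character(), detail = character(),
             stringsAsFactors = FALSE)
}

skeleton_is_acyclic <- function(nodes) {
  parent <- setNames(nodes$parent_id, as.character(nodes$node_id))
  visited_ok <- character()
  for (start in names(parent)) {
    seen <- character()
    cur <- start
    while (!is.na(parent[[cur]] %||% NA_integer_)) {
      if (cur %in% visited_ok) break
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      nxt <- as.character(parent[[cur]])
      if (!nxt %in% names(parent)) break  # dangling: caught by another rule
      cur <- nxt
    }
    visited_ok <- c(visited_ok, seen)
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

connector_resolution_violations <- function(ds) {
  out <- no_violations()
  cn <- ds$connectors
  if (!nrow(cn)) return(out)
  sk_ids <- names(ds$skeletons)
  for (i in seq_len(nrow(cn))) {
    for (end in c("pre", "post")) {
      sk <- as.character(cn[[paste0(end, "_skeleton")]][i])
      nd <- cn[[paste0(end, "_node")]][i]
      if (!sk %in% sk_ids) {
        out <- rbind(out, violation(cn$connector_id[i], "endpoint resolution",
                                    sprintf("%s skeleton %s not in dataset",
                                            end, sk)))
      } else if (!nd %in% ds$skeletons[[sk]]$nodes$node_id) {
        out <- rbind(out, violation(cn$connector_id[i], "endpoint resolution",
                                    sprintf("%s node %d not in skeleton %s",
                                            end, nd, sk)))
      }
    }
  }
  out
}

#' Validate a dataset against the structural invariants
#'
#' Checks, per skeleton: exactly one root, parent references resolve within
#' the skeleton, the parent relation is acyclic, node ids are unique, and
#' the `has_soma` flag matches the node tags. Across the dataset: connector
#' endpoints resolve to existing (skeleton, node) pairs, cell names are
#' unique, every skeleton maps to an annotated cell, and fragments carry
#' neither a cell type nor a segment. Reports violations; never throws, so
#' it can be used as a validation mode on broken inputs.
#'
#' @param ds A `larva_dataset`.
#' @return `data.frame` with columns `entity`, `rule`, `detail`; zero rows
#'   iff all invariants hold.
#' @export
validate_dataset <- function(ds) {
  out <- no_violations()
  for (skel in ds$skeletons) {
    n <- skel$nodes
    nm <- skel$cell_name
    nroot <- sum(is.na(n$parent_id))
    if (nroot != 1L)
      out <- rbind(out, violation(nm, "single root",
                                  sprintf("%d root nodes", nroot)))
    dangling <- !is.na(n$parent_id) & !(n$parent_id %in% n$node_id)
    if (any(dangling))
      out <- rbind(out, violation(nm, "parent reference",
                                  paste("parent of node",
                                        paste(n$node_id[dangling],
                                              collapse = ","), "missing")))
    if (anyDuplicated(n$node_id))
      out <- rbind(out, violation(nm, "unique node ids",
                                  paste("duplicated:",
                                        paste(unique(n$node_id[duplicated(n$node_id)]),
                                              collapse = ","))))
    if (!any(dangling) && !skeleton_is_acyclic(n))
      out <- rbind(out, violation(nm, "acyclicity", "parent relation cyclic"))
    if (skel$has_soma != any(node_has_tag(n$tags, "soma")))
      out <- rbind(out, violation(nm, "soma flag",
                                  "has_soma inconsistent with tags"))
  }
  out <- rbind(out, connector_resolution_violations(ds))
  dup <- unique(ds$cells$cell_name[duplicated(ds$cells$cell_name)])
  if (length(dup))
    out <- rbind(out, violation(paste(dup, collapse = ","),
                                "unique cell name", "duplicated cell_name"))
  unmapped <- setdiff(names(ds$skeletons), as.character(ds$cells$skeleton_id))
  if (length(unmapped))
    out <- rbind(out, violation(paste(unmapped, collapse = ","),
                                "skeleton-cell mapping",
                                "skeleton without annotated cell"))
  frag <- ds$cells$cell_class == "fragment"
  bad_frag <- frag & (!is.na(ds$cells$cell_type) |
                        !(is.na(ds$cells$segment) |
                            ds$cells$segment %in% c("none", "")))
  if (any(bad_frag))
    out <- rbind(out, violation(paste(ds$cells$cell_name[bad_frag],
                                      collapse = ","),
                                "fragment annotation",
                                "fragment with cell_type or segment"))
  rownames(out) <- NULL
  out
}
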