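## Machine-readable summary reports and graph export/import.

#' Dataset summary report
#'
#' Collects the headline statistics of a reconstruction: cell and fragment
#' counts, skeleton-node and synaptic-site totals split between
#' soma-bearing cells and fragments (with the fraction of nodes, pre- and
#' postsynaptic sites left on fragments), connectome graph size, density,
#' the per-class cell census and, when supplied, the cell-type census and
#' the fraction of neuronal types with an assigned transmitter.
#'
#' @param ds A [larva_dataset()].
#' @param g Connectome graph from [build_connectome()] (optional).
#' @param type_census Optional list with `n_neuronal_types`,
#'   `n_non_neuronal_types`, `n_types_with_transmitter`.
#' @return A `dataset_report` list; see [report_from_totals()] for the
#'   same summary computed from published totals instead of raw data.
#' @export
dataset_report <- function(ds, g = NULL, type_census = NULL) {
  is_frag <- !vapply(ds$skeletons, `[[`, logical(1), "has_soma")
  n_nodes <- vapply(ds$skeletons, function(s) nrow(s$nodes), numeric(1))
  frag_ids <- vapply(ds$skeletons[is_frag], `[[`, integer(1),
                     "skeleton_id")
  pre_on_frag <- sum(ds$connectors$pre_skeleton %in% frag_ids)
  post_on_frag <- sum(ds$connectors$post_skeleton %in% frag_ids)
  census <- table(ds$cells$cell_class)
  tc <- type_census %||% list(n_neuronal_types = NA_integer_,
                              n_non_neuronal_types = NA_integer_,
                              n_types_with_transmitter = NA_integer_)
  rep <- list(
    n_cells_with_soma = sum(!is_frag),
    n_fragments = sum(is_frag),
    n_nodes_total = sum(n_nodes),
    n_nodes_on_fragments = sum(n_nodes[is_frag]),
    n_pre_total = nrow(ds$connectors),
    n_pre_on_fragments = pre_on_frag,
    n_post_total = nrow(ds$connectors),
    n_post_on_fragments = post_on_frag,
    fraction_nodes_on_fragments = frac_or_zero(sum(n_nodes[is_frag]),
                                               sum(n_nodes)),
    fraction_pre_on_fragments = frac_or_zero(pre_on_frag,
                                             nrow(ds$connectors)),
    fraction_post_on_fragments = frac_or_zero(post_on_frag,
                                              nrow(ds$connectors)),
    cell_class_census = as.list(census),
    n_neuronal_types = tc$n_neuronal_types,
    n_non_neuronal_types = tc$n_non_neuronal_types,
    n_cell_types_total = tc$n_neuronal_types + tc$n_non_neuronal_types,
    n_types_with_transmitter = tc$n_types_with_transmitter,
    fraction_types_with_transmitter =
      if (!is.na(tc$n_types_with_transmitter) &&
          !is.na(tc$n_neuronal_types))
        tc$n_types_with_transmitter / tc$n_neuronal_types else NA_real_)
  if (!is.null(g)) {
    rep$connectome_n_nodes <- igraph::vcount(g)
    rep$connectome_n_edges <- igraph::ecount(g)
    rep$connectome_n_synapses <-
      igraph::graph_attr(g, "n_synapses_in_graph")
    rep$connectome_density <- graph_density(g)
  }
  structure(rep, class = "dataset_report")
}

frac_or_zero <- function(num, den) if (den > 0) num / den else 0

#' Dataset report from published totals
#'
#' Computes the same derived quantities as [dataset_report()] — fragment
#' fractions, graph density, type-census totals and transmitter fraction —
#' directly from printed summary counts, for comparing a reconstruction's
#' headline numbers without access to the underlying database.
#'
#' @param n_nodes_total,n_nodes_on_fragments Skeleton-node totals.
#' @param n_pre_total,n_pre_on_fragments Presynaptic-site totals.
#' @param n_post_total,n_post_on_fragments Postsynaptic-site totals.
#' @param connectome_n_nodes,connectome_n_edges Connectome graph size.
#' @param n_neuronal_types,n_non_neuronal_types,n_types_with_transmitter
#'   Cell-type census counts.
#' @return A `dataset_report` list.
#' @export
report_from_totals <- function(n_nodes_total, n_nodes_on_fragments,
                               n_pre_total, n_pre_on_fragments,
                               n_post_total, n_post_on_fragments,
                               connectome_n_nodes = NA,
                               connectome_n_edges = NA,
                               n_neuronal_types = NA,
                               n_non_neuronal_types = NA,
                               n_types_with_transmitter = NA) {
  structure(list(
    n_nodes_total = n_nodes_total,
    n_nodes_on_fragments = n_nodes_on_fragments,
    n_pre_total = n_pre_total,
    n_pre_on_fragments = n_pre_on_fragments,
    n_post_total = n_post_total,
    n_post_on_fragments = n_post_on_fragments,
    fraction_nodes_on_fragments = n_nodes_on_fragments / n_nodes_total,
    fraction_pre_on_fragments = n_pre_on_fragments / n_pre_total,
    fraction_post_on_fragments = n_post_on_fragments / n_post_total,
    connectome_n_nodes = connectome_n_nodes,
    connectome_n_edges = connectome_n_edges,
    connectome_density = if (!is.na(connectome_n_nodes))
      directed_density(connectome_n_nodes, connectome_n_edges)
      else NA_real_,
    n_neuronal_types = n_neuronal_types,
    n_non_neuronal_types = n_non_neuronal_types,
    n_cell_types_total = n_neuronal_types + n_non_neuronal_types,
    n_types_with_transmitter = n_types_with_transmitter,
    fraction_types_with_transmitter =
      n_types_with_transmitter / n_neuronal_types),
    class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat("<dataset_report>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=",
                               collapse = ", ")
    cat(sprintf("  %-32s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Write a dataset report as JSON
#'
#' Fractions are additionally serialised as percentages rounded to one
#' decimal place (`pct_*` fields); the raw doubles are retained.
#'
#' @param report A `dataset_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  for (k in grep("^fraction_", names(report), value = TRUE)) {
    v <- report[[k]]
    if (!is.na(v))
      out[[sub("^fraction_", "pct_", k)]] <- round(100 * v, 1)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Graph export / import

#' Export a connectome or type graph
#'
#' `graphml` and `gexf` are lossless for node attributes, edge weights and
#' module labels; `edge-tsv` writes the edge list to `path` and the node
#' attribute table to `<path>.nodes.tsv`.
#'
#' @param g An `igraph` graph.
#' @param path Output file.
#' @param format `"graphml"`, `"gexf"` or `"edge-tsv"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(g, path, format = c("graphml", "gexf",
                                             "edge-tsv")) {
  format <- match.arg(format)
  switch(format,
         graphml = igraph::write_graph(g, path, format = "graphml"),
         gexf = write_gexf(g, path),
         `edge-tsv` = {
           el <- igraph::as_data_frame(g, what = "edges")
           write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
           vt <- igraph::as_data_frame(g, what = "vertices")
           write.table(vt, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
         })
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "gexf",
                                          "edge-tsv")) {
  format <- match.arg(format)
  switch(format,
         graphml = igraph::read_graph(path, format = "graphml"),
         gexf = read_gexf(path),
         `edge-tsv` = {
           el <- read.delim(path, stringsAsFactors = FALSE)
           vt <- read.delim(paste0(path, ".nodes.tsv"),
                            stringsAsFactors = FALSE,
                            na.strings = c("NA"))
           igraph::graph_from_data_frame(el, directed = TRUE,
                                         vertices = vt)
         })
}

gexf_type <- function(v) {
  if (is.integer(v)) "long" else if (is.numeric(v)) "double" else "string"
}

write_gexf <- function(g, path) {
  vt <- igraph::as_data_frame(g, what = "vertices")
  el <- igraph::as_data_frame(g, what = "edges")
  vattrs <- setdiff(names(vt), "name")
  eattrs <- setdiff(names(el), c("from", "to", "weight"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
             '<graph defaultedgetype="directed">')
  if (length(vattrs)) {
    lines <- c(lines, '<attributes class="node">',
               sprintf('<attribute id="%d" title="%s" type="%s"/>',
                       seq_along(vattrs) - 1L, esc(vattrs),
                       vapply(vt[vattrs], gexf_type, character(1))),
               '</attributes>')
  }
  if (length(eattrs)) {
    lines <- c(lines, '<attributes class="edge">',
               sprintf('<attribute id="e%d" title="%s" type="%s"/>',
                       seq_along(eattrs) - 1L, esc(eattrs),
                       vapply(el[eattrs], gexf_type, character(1))),
               '</attributes>')
  }
  lines <- c(lines, '<nodes>')
  for (i in seq_len(nrow(vt))) {
    av <- if (length(vattrs)) {
      vals <- vapply(vattrs, function(a) {
        x <- vt[[a]][i]
        if (is.na(x)) "" else
          sprintf('<attvalue for="%d" value="%s"/>',
                  match(a, vattrs) - 1L,
                  esc(if (is.numeric(x)) format(x, digits = 17) else x))
      }, character(1))
      paste0("<attvalues>", paste(vals, collapse = ""), "</attvalues>")
    } else ""
    lines <- c(lines, sprintf('<node id="%s" label="%s">%s</node>',
                              esc(vt$name[i]), esc(vt$name[i]), av))
  }
  lines <- c(lines, '</nodes>', '<edges>')
  for (i in seq_len(nrow(el))) {
    av <- if (length(eattrs)) {
      vals <- vapply(eattrs, function(a) {
        x <- el[[a]][i]
        if (is.na(x)) "" else
          sprintf('<attvalue for="e%d" value="%s"/>',
                  match(a, eattrs) - 1L,
                  esc(if (is.numeric(x)) format(x, digits = 17) else x))
      }, character(1))
      paste0("<attvalues>", paste(vals, collapse = ""), "</attvalues>")
    } else ""
    w <- if ("weight" %in% names(el))
      sprintf(' weight="%s"', format(el$weight[i], digits = 17)) else ""
    lines <- c(lines,
               sprintf('<edge id="%d" source="%s" target="%s"%s>%s</edge>',
                       i - 1L, esc(el$from[i]), esc(el$to[i]), w, av))
  }
  lines <- c(lines, '</edges>', '</graph>', '</gexf>')
  writeLines(lines, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  adefs <- list(node = list(), edge = list())
  for (attrs in xml2::xml_find_all(doc, ".//attributes")) {
    klass <- xml2::xml_attr(attrs, "class")
    for (a in xml2::xml_find_all(attrs, ".//attribute"))
      adefs[[klass]][[xml2::xml_attr(a, "id")]] <-
        list(title = xml2::xml_attr(a, "title"),
             type = xml2::xml_attr(a, "type"))
  }
  cast <- function(x, type)
    switch(type, long = as.integer(x), double = as.numeric(x), x)
  read_attvalues <- function(el, klass) {
    vals <- list()
    for (av in xml2::xml_find_all(el, ".//attvalue")) {
      def <- adefs[[klass]][[xml2::xml_attr(av, "for")]]
      vals[[def$title]] <- cast(xml2::xml_attr(av, "value"), def$type)
    }
    vals
  }
  nodes <- xml2::xml_find_all(doc, ".//nodes/node")
  ndf <- do.call(rbind, lapply(nodes, function(nd) {
    base <- list(name = xml2::xml_attr(nd, "id"))
    av <- read_attvalues(nd, "node")
    for (d in adefs$node)
      base[[d$title]] <- av[[d$title]] %||% cast(NA_character_, d$type)
    as.data.frame(base, stringsAsFactors = FALSE)
  }))
  edges <- xml2::xml_find_all(doc, ".//edges/edge")
  edf <- do.call(rbind, lapply(edges, function(ed) {
    base <- list(from = xml2::xml_attr(ed, "source"),
                 to = xml2::xml_attr(ed, "target"))
    w <- xml2::xml_attr(ed, "weight")
    if (!is.na(w)) base$weight <- as.numeric(w)
    av <- read_attvalues(ed, "edge")
    for (d in adefs$edge)
      base[[d$title]] <- av[[d$title]] %||% cast(NA_character_, d$type)
    as.data.frame(base, stringsAsFactors = FALSE)
  }))
  if (is.null(edf)) edf <- data.frame(from = character(), to = character())
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = ndf)
}
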