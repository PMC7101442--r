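#' Serialize skeleton graphs to GraphML or CSV
#'
#' GraphML carries node attributes `x, y, z` (um) and `class`, and edge
#' attributes `length_um` and `n_slab_voxels`, via igraph. The CSV dialect
#' writes two files, `<stem>_nodes.csv` and `<stem>_edges.csv` (stem = the
#' given path without its extension). Slab-voxel paths are an in-memory
#' detail and are not serialized; a read-back graph has empty edge paths.
#'
#' @param graph a [skeleton_graph()].
#' @param path output path (`.graphml`, or any stem for CSV).
#' @param dialect `"graphml"` or `"csv"`.
#' @return the main path written, invisibly (`write`); a
#'   [skeleton_graph()] (`read`).
#' @export
write_graph_file <- function(graph, path, dialect = c("graphml", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(graph, "skeleton_graph"))
  if (dialect == "csv") {
    stem <- sub("\\.[A-Za-z]+$", "", path)
    write.csv(graph$nodes, paste0(stem, "_nodes.csv"), row.names = FALSE)
    write.csv(graph$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  if (nrow(graph$nodes)) {
    g <- igraph::set_vertex_attr(g, "name", value = as.character(graph$nodes$id))
    for (a in c("x", "y", "z")) g <- igraph::set_vertex_attr(g, a, value = graph$nodes[[a]])
    g <- igraph::set_vertex_attr(g, "class", value = graph$nodes$class)
  }
  if (nrow(graph$edges)) {
    ev <- rbind(match(graph$edges$from, graph$nodes$id),
                match(graph$edges$to, graph$nodes$id))
    g <- igraph::add_edges(g, as.vector(ev))
    g <- igraph::set_edge_attr(g, "length_um", value = graph$edges$length_um)
    g <- igraph::set_edge_attr(g, "n_slab_voxels", value = graph$edges$n_slab_voxels)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path, dialect = c("graphml", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    stem <- sub("\\.[A-Za-z]+$", "", path)
    nodes <- read.csv(paste0(stem, "_nodes.csv"), stringsAsFactors = FALSE)
    edges <- read.csv(paste0(stem, "_edges.csv"), stringsAsFactors = FALSE)
    return(skeleton_graph(nodes, edges))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nv <- igraph::vcount(g)
  nodes <- data.frame(
    id = as.integer(igraph::vertex_attr(g, "name") %||% seq_len(nv)),
    x = igraph::vertex_attr(g, "x") %||% numeric(nv),
    y = igraph::vertex_attr(g, "y") %||% numeric(nv),
    z = igraph::vertex_attr(g, "z") %||% numeric(nv),
    class = igraph::vertex_attr(g, "class") %||% rep("endpoint", nv),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(
    from = nodes$id[el[, 1]], to = nodes$id[el[, 2]],
    length_um = igraph::edge_attr(g, "length_um") %||% numeric(nrow(el)),
    n_slab_voxels = as.integer(igraph::edge_attr(g, "n_slab_voxels") %||%
                                 integer(nrow(el))))
  skeleton_graph(nodes, edges)
}
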