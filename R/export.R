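#' Export a co-expression network for external network tools
#'
#' `"sif"` writes one `GENE_A co_expr GENE_B` line per edge (isolated
#' nodes, if any, as bare names). `"graphml"` writes GraphML with the node
#' attribute `gene` and the signed correlation as edge attribute `rho`,
#' re-readable losslessly by [read_network()].
#'
#' @param net a [coexpression_network()] result.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"` (default from file extension).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("auto", "sif", "graphml")) {
  stopifnot(inherits(net, "coexpr_network"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sif = "sif", graphml = "graphml",
                     stop("cannot infer format from extension; pass format=",
                          call. = FALSE))
  }
  if (format == "sif") {
    edges <- igraph::as_data_frame(net$graph, what = "edges")
    lines <- if (nrow(edges) > 0L) {
      sprintf("%s co_expr %s", edges$from, edges$to)
    } else {
      character()
    }
    writeLines(lines, path)
  } else {
    g <- net$graph
    igraph::graph_attr(g, "group") <- net$group
    igraph::graph_attr(g, "method") <- net$method
    igraph::graph_attr(g, "cutoff") <- net$cutoff
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a co-expression network back from GraphML
#'
#' Inverse of [export_network()] for the GraphML format; restores the edge
#' weights and the group/method/cutoff metadata written by the exporter.
#'
#' @param path GraphML file path.
#' @return A `coexpr_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$gene)) {
    igraph::V(g)$name <- igraph::V(g)$gene
  }
  structure(
    list(graph = g,
         group = igraph::graph_attr(g, "group") %||% NA_character_,
         method = igraph::graph_attr(g, "method") %||% NA_character_,
         cutoff = igraph::graph_attr(g, "cutoff") %||% NA_real_),
    class = "coexpr_network"
  )
}
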