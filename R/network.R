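#' Normality gate for the correlation method
#'
#' Runs a Shapiro-Wilk normality test per gene per response group on the
#' normalized expression values; if any gene in any group rejects
#' normality at `alpha`, rank (Spearman) correlation is selected, otherwise
#' Pearson. A constant expression vector cannot be tested and is counted as
#' non-normal with a warning.
#'
#' @param norm a `norm_expr` from [normalize_delta_ct()].
#' @param alpha per-test significance level (default 0.05).
#' @return list with `method` (`"spearman"` or `"pearson"`) and `report`,
#'   a data frame with one row per gene x group (`gene`, `group`,
#'   `p_value`, `normal`).
#' @export
normality_gate <- function(norm, alpha = 0.05) {
  stopifnot(inherits(norm, "norm_expr"))
  rows <- list()
  for (g in GROUP_LEVELS) {
    vals <- norm$values[norm$group == g, , drop = FALSE]
    if (nrow(vals) < 3L) stop("need >= 3 samples per group", call. = FALSE)
    p <- vapply(colnames(vals), function(gene) {
      x <- vals[, gene]
      if (stats::sd(x) == 0) {
        warning(sprintf("constant expression for %s in %s; counted non-normal",
                        gene, g), call. = FALSE)
        return(NA_real_)
      }
      stats::shapiro.test(x)$p.value
    }, numeric(1))
    rows[[g]] <- data.frame(gene = colnames(vals), group = g, p_value = p,
                            normal = !is.na(p) & p >= alpha,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(method = if (all(report$normal)) "pearson" else "spearman",
       report = report)
}

#' Candidate-versus-panel correlation matrix
#'
#' Correlates each candidate gene against every gene of the panel within
#' one response group. Spearman uses average ranks for ties; because the
#' rank correlation is invariant under per-gene monotone transforms, it is
#' identical whether computed on `2^-dCt` or on delta-Ct.
#'
#' @param norm a `norm_expr`.
#' @param candidates character vector of candidate genes (rows), a subset
#'   of the panel targets.
#' @param group `"responder"` or `"non-responder"`.
#' @param method `"spearman"` (default) or `"pearson"`; typically the
#'   result of [normality_gate()].
#' @return An object of class `corr_matrix`: list with `rho` (candidates x
#'   panel matrix), `method`, `group`.
#' @export
correlation_matrix <- function(norm, candidates, group,
                               method = c("spearman", "pearson")) {
  stopifnot(inherits(norm, "norm_expr"))
  method <- match.arg(method)
  group <- match.arg(group, GROUP_LEVELS)
  absent <- setdiff(candidates, colnames(norm$values))
  if (length(absent) > 0L) {
    stop("candidate gene absent from expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  vals <- norm$values[norm$group == group, , drop = FALSE]
  if (nrow(vals) < 3L) stop("need >= 3 samples to correlate", call. = FALSE)
  rho <- stats::cor(vals[, candidates, drop = FALSE], vals, method = method)
  structure(list(rho = rho, method = method, group = group),
            class = "corr_matrix")
}

#' Threshold a correlation matrix into an edge list
#'
#' Keeps gene pairs with correlation magnitude strictly above the cutoff
#' (inclusive with `strict = FALSE`), excluding self-pairs and listing each
#' unordered pair once with its signed correlation as weight.
#'
#' @param corr a [correlation_matrix()] result.
#' @param cutoff magnitude cutoff in (0, 1) (default 0.9).
#' @param strict require `|rho| > cutoff` (default) rather than `>=`.
#' @return data frame with columns `from`, `to`, `rho`.
#' @export
threshold_edges <- function(corr, cutoff = 0.9, strict = TRUE) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0,1)", call. = FALSE)
  rho <- corr$rho
  keep <- if (strict) abs(rho) > cutoff else abs(rho) >= cutoff
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(from = character(), to = character(), rho = numeric(),
                      stringsAsFactors = FALSE))
  }
  from <- rownames(rho)[idx[, 1L]]
  to <- colnames(rho)[idx[, 2L]]
  w <- rho[idx]
  edges <- data.frame(from = pmin(from, to), to = pmax(from, to), rho = w,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Build a per-group co-expression network
#'
#' End-to-end construction for one response group: correlate the candidate
#' genes against the full panel (method chosen by the normality gate unless
#' given), threshold at the correlation cutoff, and assemble the undirected
#' graph. Nodes are all genes incident to a surviving edge; genes with no
#' strong correlation are dropped, so the graph order reflects observed
#' co-expression activity.
#'
#' @param norm a `norm_expr`.
#' @param candidates candidate gene symbols.
#' @param group `"responder"` or `"non-responder"`.
#' @param cutoff correlation magnitude cutoff (default 0.9).
#' @param method correlation method; `NULL` (default) applies
#'   [normality_gate()].
#' @param strict strict inequality at the cutoff (default TRUE).
#' @return An object of class `coexpr_network`: list with `graph` (an
#'   [igraph::graph] with vertex attribute `gene` and edge attribute
#'   `rho`), `group`, `method`, `cutoff`.
#' @export
coexpression_network <- function(norm, candidates, group, cutoff = 0.9,
                                 method = NULL, strict = TRUE) {
  if (is.null(method)) method <- normality_gate(norm)$method
  corr <- correlation_matrix(norm, candidates, group, method = method)
  edges <- threshold_edges(corr, cutoff = cutoff, strict = strict)
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(graph)$gene <- igraph::V(graph)$name
  structure(list(graph = graph, group = group, method = method,
                 cutoff = cutoff),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf(
    "Co-expression network (%s, %s, |rho| %s %.2f): %d genes, %d edges\n",
    x$group, x$method, ">", x$cutoff,
    igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Degree and betweenness centrality table
#'
#' Computes, on the unweighted thresholded graph, the integer degree
#' (number of co-expression partners; high-degree genes are hubs) and the
#' exact normalized betweenness centrality (share of shortest paths through
#' the gene, scaled by `(n-1)(n-2)/2` with `n` the graph order; high-
#' betweenness genes are bottlenecks). Graphs with fewer than three nodes
#' have all betweenness 0. Hub and bottleneck ranks are dense and
#' tie-aware.
#'
#' @param net a [coexpression_network()] (or a bare igraph graph).
#' @return A `centrality_table`: data frame with columns `gene`, `degree`,
#'   `betweenness`, `hub_rank`, `bottleneck_rank`.
#' @export
centrality_table <- function(net) {
  graph <- if (inherits(net, "coexpr_network")) net$graph else net
  n <- igraph::vcount(graph)
  if (n == 0L) {
    out <- data.frame(gene = character(), degree = integer(),
                      betweenness = numeric(), hub_rank = integer(),
                      bottleneck_rank = integer(), stringsAsFactors = FALSE)
    return(structure(out, class = c("centrality_table", "data.frame")))
  }
  dc <- igraph::degree(graph)
  bc <- if (n < 3L) {
    stats::setNames(rep(0, n), igraph::V(graph)$name)
  } else {
    igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
  }
  out <- data.frame(gene = igraph::V(graph)$name,
                    degree = as.integer(dc),
                    betweenness = as.numeric(bc),
                    stringsAsFactors = FALSE)
  out$hub_rank <- dense_rank_desc(out$degree)
  out$bottleneck_rank <- dense_rank_desc(out$betweenness)
  out <- out[order(out$hub_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("centrality_table", "data.frame"),
            group = if (inherits(net, "coexpr_network")) net$group else NA)
}

#' Top hub and bottleneck report
#'
#' Sorts genes by degree (hubs) and by betweenness (bottlenecks), breaking
#' ties alphabetically while reporting the shared dense rank, and returns
#' the top `k` of each. All genes tied at the k-th rank are included.
#'
#' @param table a [centrality_table()].
#' @param k list length (default 10).
#' @return list with data frames `hubs` and `bottlenecks`.
#' @export
rank_hubs_bottlenecks <- function(table, k = 10) {
  stopifnot(inherits(table, "centrality_table"))
  top <- function(df, rank_col) {
    df <- df[order(df[[rank_col]], df$gene), , drop = FALSE]
    kk <- min(k, nrow(df))
    if (kk == 0L) return(df[0L, , drop = FALSE])
    cut_rank <- df[[rank_col]][kk]
    out <- df[df[[rank_col]] <= cut_rank, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(hubs = top(as.data.frame(table), "hub_rank"),
       bottlenecks = top(as.data.frame(table), "bottleneck_rank"))
}

#' Compare centrality structure between response groups
#'
#' Intersections and set differences of the top-`k` hubs and bottlenecks of
#' two groups, plus per-gene degree and betweenness deltas over the union
#' of nodes (absent genes count as degree 0 / betweenness 0).
#'
#' @param a,b [centrality_table()]s from the same panel.
#' @param k top-list size (default 10).
#' @return list with `shared_hubs`, `unique_hubs_a`, `unique_hubs_b`,
#'   `shared_bottlenecks`, `unique_bottlenecks_a`,
#'   `unique_bottlenecks_b`, and `deltas` (gene, degree/betweenness in
#'   each group and their difference a - b).
#' @export
compare_groups <- function(a, b, k = 10) {
  stopifnot(inherits(a, "centrality_table"), inherits(b, "centrality_table"))
  ta <- rank_hubs_bottlenecks(a, k)
  tb <- rank_hubs_bottlenecks(b, k)
  genes <- sort(union(a$gene, b$gene))
  pull <- function(tab, col) {
    v <- stats::setNames(tab[[col]], tab$gene)[genes]
    v[is.na(v)] <- 0
    unname(v)
  }
  deltas <- data.frame(
    gene = genes,
    degree_a = pull(a, "degree"), degree_b = pull(b, "degree"),
    betweenness_a = pull(a, "betweenness"),
    betweenness_b = pull(b, "betweenness"),
    stringsAsFactors = FALSE
  )
  deltas$degree_delta <- deltas$degree_a - deltas$degree_b
  deltas$betweenness_delta <- deltas$betweenness_a - deltas$betweenness_b
  list(
    shared_hubs = intersect(ta$hubs$gene, tb$hubs$gene),
    unique_hubs_a = setdiff(ta$hubs$gene, tb$hubs$gene),
    unique_hubs_b = setdiff(tb$hubs$gene, ta$hubs$gene),
    shared_bottlenecks = intersect(ta$bottlenecks$gene, tb$bottlenecks$gene),
    unique_bottlenecks_a = setdiff(ta$bottlenecks$gene, tb$bottlenecks$gene),
    unique_bottlenecks_b = setdiff(tb$bottlenecks$gene, ta$bottlenecks$gene),
    deltas = deltas
  )
}
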