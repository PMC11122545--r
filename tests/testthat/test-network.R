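graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

test_that("normality gate selects rank correlation when any gene rejects normality", {
  panel <- default_panel()
  ct <- generate_cohort(study_cohort_spec(panel), seed = 2)
  norm <- normalize_delta_ct(ct, panel)
  gate <- normality_gate(norm)
  # 2^-dCt values are log-normal: some of 168 gene-by-group tests reject
  expect_identical(gate$method, "spearman")
  expect_identical(nrow(gate$report), 168L)

  # exactly Gaussian columns with a wide alpha margin allow Pearson
  set.seed(4)
  vals <- matrix(stats::qnorm(seq(0.05, 0.95, length.out = 12)), 12, 3)
  vals <- vals + matrix(stats::rnorm(36, 0, 0.01), 12, 3)
  dimnames(vals) <- list(paste0("S", 1:12), c("A", "B", "C"))
  gnorm <- make_norm(vals, rep(c("responder", "non-responder"), each = 6))
  expect_identical(normality_gate(gnorm, alpha = 1e-6)$method, "pearson")

  # a constant gene is counted non-normal with a warning
  vals2 <- vals
  vals2[, "B"] <- 1
  cnorm <- make_norm(vals2, rep(c("responder", "non-responder"), each = 6))
  expect_warning(gate2 <- normality_gate(cnorm, alpha = 1e-6), "constant")
  expect_identical(gate2$method, "spearman")
})

test_that("rank correlation matches its closed forms and the rank-Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  vals <- cbind(a = x, b = 2 * x + 1, c = -x, d = c(3, 1, 2, 5, 4))
  vals <- rbind(vals, vals + 10)  # second group, unused
  rownames(vals) <- paste0("S", 1:10)
  norm <- make_norm(vals, rep(c("responder", "non-responder"), each = 5))
  cm <- correlation_matrix(norm, candidates = c("a", "c"), "responder",
                           method = "spearman")
  expect_equal(cm$rho["a", "b"], 1)
  expect_equal(cm$rho["a", "c"], -1)
  expect_equal(cm$rho["a", "d"], 0.6)  # 1 - 6*8/(5*24)
  expect_equal(cm$rho["a", "a"], 1)

  # oracle agreement on tied and untied random vectors
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- stats::rnorm(n)
    y <- if (i %% 2 == 0) sample(round(stats::rnorm(n), 1)) else stats::rnorm(n)
    m <- cbind(x = x, y = y)
    rownames(m) <- paste0("S", seq_len(n))
    nm <- make_norm(rbind(m, m + 100),
                    rep(c("responder", "non-responder"), each = n))
    got <- correlation_matrix(nm, "x", "responder",
                              method = "spearman")$rho["x", "y"]
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
  }

  expect_error(correlation_matrix(norm, "nope", "responder"), "absent")
})

test_that("edge thresholding is strict, symmetric and monotone in the cutoff", {
  rho <- rbind(A = c(A = 1, B = 0.9, C = -0.95, D = 0.2),
               B = c(0.9, 1, 0.97, 0.5))
  corr <- structure(list(rho = rho, method = "spearman", group = "responder"),
                    class = "corr_matrix")
  edges <- threshold_edges(corr, cutoff = 0.9)
  expect_identical(sort(paste(edges$from, edges$to)), c("A C", "B C"))
  expect_equal(edges$rho[edges$from == "A"], -0.95)  # signed weight retained
  # inclusive mode admits the boundary pair
  edges_inc <- threshold_edges(corr, cutoff = 0.9, strict = FALSE)
  expect_true("A B" %in% paste(edges_inc$from, edges_inc$to))
  # identity-only correlation yields no edges
  corr0 <- structure(list(rho = diag(2), method = "spearman",
                          group = "responder"), class = "corr_matrix")
  dimnames(corr0$rho) <- list(c("A", "B"), c("A", "B"))
  expect_identical(nrow(threshold_edges(corr0)), 0L)
  # monotone: higher cutoff never adds edges
  set.seed(3)
  rr <- matrix(stats::runif(40, -1, 1), 4, 10,
               dimnames = list(paste0("C", 1:4), paste0("G", 1:10)))
  corr_r <- structure(list(rho = rr, method = "spearman", group = "responder"),
                      class = "corr_matrix")
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9),
                   function(ct) nrow(threshold_edges(corr_r, ct)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degree and betweenness match closed-form values on canonical graphs", {
  # star with 9 leaves: center degree 9, betweenness 1
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("HUB", paste0("L", 1:9))
  tab <- centrality_table(star)
  expect_identical(tab$degree[tab$gene == "HUB"], 9L)
  expect_equal(tab$betweenness[tab$gene == "HUB"], 1)
  expect_true(all(tab$degree[tab$gene != "HUB"] == 1L))
  expect_identical(tab$hub_rank[tab$gene == "HUB"], 1L)

  # path A-B-C: B carries the single shortest path
  path <- graph_from_adj(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
                                dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C"))))
  ptab <- centrality_table(path)
  expect_equal(ptab$betweenness[ptab$gene == "B"], 1)
  expect_equal(ptab$betweenness[ptab$gene != "B"], c(0, 0))

  # 4-cycle: every node lies on half of one opposite pair's two paths
  cyc <- igraph::make_ring(4)
  igraph::V(cyc)$name <- LETTERS[1:4]
  ctab <- centrality_table(cyc)
  expect_equal(ctab$betweenness, rep(1 / 6, 4))
  expect_identical(ctab$degree, rep(2L, 4))

  # triangle: all degree 2, betweenness 0; isolated node has degree 0
  tri <- graph_from_adj(matrix(c(0, 1, 1, 0, 1, 0, 1, 0, 1, 1, 0, 0,
                                 0, 0, 0, 0), 4, 4,
                               dimnames = list(LETTERS[1:4], LETTERS[1:4])))
  ttab <- centrality_table(tri)
  expect_identical(ttab$degree[ttab$gene == "D"], 0L)
  expect_equal(ttab$betweenness, rep(0, 4))

  # graphs below 3 nodes have all betweenness zero
  two <- graph_from_adj(matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(centrality_table(two)$betweenness, c(0, 0))
})

test_that("betweenness agrees with the brute-force shortest-path oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.2, 0.8))
    tab <- centrality_table(graph_from_adj(adj))
    want <- oracle_betweenness(adj)
    got <- stats::setNames(tab$betweenness, tab$gene)[rownames(adj)]
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("hub and bottleneck ranking is dense, tie-aware and truncates at k", {
  adj <- matrix(0L, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  # two tied hubs A and B (degree 3 each)
  adj["A", c("C", "D", "E")] <- 1L
  adj["B", c("C", "D", "E")] <- 1L
  adj <- adj | t(adj)
  tab <- centrality_table(graph_from_adj(adj * 1L))
  expect_identical(tab$hub_rank[tab$gene %in% c("A", "B")], c(1L, 1L))
  ranked <- rank_hubs_bottlenecks(tab, k = 2)
  expect_setequal(ranked$hubs$gene, c("A", "B"))
  # k larger than the node count truncates silently
  expect_identical(nrow(rank_hubs_bottlenecks(tab, k = 50)$hubs), 5L)
  # k = 1 on a star returns the center
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("HUB", paste0("L", 1:5))
  expect_identical(
    rank_hubs_bottlenecks(centrality_table(star), k = 1)$hubs$gene, "HUB")
  # empty graph -> empty report
  etab <- centrality_table(igraph::make_empty_graph(0, directed = FALSE))
  expect_identical(nrow(rank_hubs_bottlenecks(etab, k = 10)$hubs), 0L)
})

test_that("group comparison reports shared and unique central genes", {
  adj <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  adj["A", "B"] <- adj["B", "C"] <- 1L
  adj <- adj | t(adj)
  tab <- centrality_table(graph_from_adj(adj * 1L))
  same <- compare_groups(tab, tab)
  expect_length(same$unique_hubs_a, 0L)
  expect_length(same$unique_bottlenecks_b, 0L)
  expect_setequal(same$shared_hubs, c("A", "B", "C"))
  expect_true(all(same$deltas$degree_delta == 0))

  adj2 <- matrix(0L, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  adj2["X", "Y"] <- 1L
  tab2 <- centrality_table(graph_from_adj((adj2 | t(adj2)) * 1L))
  disjoint <- compare_groups(tab, tab2)
  expect_length(disjoint$shared_hubs, 0L)
  expect_setequal(disjoint$unique_hubs_a, c("A", "B", "C"))
})

test_that("group-scoped planted modules surface as group-specific hubs", {
  panel <- default_panel()
  spec <- study_cohort_spec(panel)
  ct <- generate_cohort(spec, seed = 17)
  norm <- normalize_delta_ct(ct, panel)
  cand <- select_candidates(suppressWarnings(dgea(ct, panel)),
                            force_include = "TNFSF14")
  netR <- coexpression_network(norm, cand, "responder")
  netN <- coexpression_network(norm, cand, "non-responder")
  cmp <- compare_groups(centrality_table(netR), centrality_table(netN))
  resp_mod <- spec$modules[[1]]$genes
  nonresp_mod <- spec$modules[[2]]$genes
  expect_true(all(c("BCL6", "CRP") %in% cmp$unique_hubs_a))
  expect_true(all(c("CCL11", "CCL22") %in% cmp$unique_hubs_b))
  # module genes dominate their own group's degree ranking
  tabR <- centrality_table(netR)
  expect_true(all(tabR$hub_rank[tabR$gene %in% resp_mod] <= 2))
  tabN <- centrality_table(netN)
  expect_true(all(tabN$hub_rank[tabN$gene %in% nonresp_mod] <= 2))
})

test_that("rank correlation on expression equals rank correlation on Ct input", {
  # monotone per-gene transform: Spearman is identical on 2^-dCt and dCt
  panel <- default_panel()
  ct <- generate_cohort(study_cohort_spec(panel), seed = 23)
  norm <- normalize_delta_ct(ct, panel)
  keep <- norm$group == "responder"
  dct <- -log2(norm$values[keep, c("BCL6", "CRP", "CCR1")])
  r_expr <- stats::cor(norm$values[keep, c("BCL6", "CRP", "CCR1")],
                       method = "spearman")
  r_dct <- stats::cor(dct, method = "spearman")
  expect_equal(r_expr, r_dct, tolerance = 1e-12)
})
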