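# Independent oracles used to cross-check the pipeline's computations.
# These deliberately use brute-force enumeration or textbook formulas and
# share no code with the package internals.

# Normalized betweenness by exhaustive simple-path enumeration on an
# adjacency matrix (feasible for graphs of <= ~8 nodes).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  if (n < 3L) return(bc)
  paths_between <- function(s, t) {
    res <- list()
    rec <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (nb in which(adj[last, ] == 1)) {
        if (!(nb %in% path)) rec(c(path, nb))
      }
    }
    rec(s)
    res
  }
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      ps <- paths_between(s, t)
      if (length(ps) == 0L) next
      lens <- vapply(ps, length, integer(1))
      sp <- ps[lens == min(lens)]
      sigma <- length(sp)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / sigma
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# Spearman as Pearson on average ranks, written out from the product-moment
# formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# AUC by enumerating every positive-negative pair (ties count one half).
oracle_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  wins <- 0
  for (i in pos) {
    for (j in neg) {
      wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  wins / (length(pos) * length(neg))
}

# Random undirected graph on n nodes with edge probability p, as an
# adjacency matrix with gene-like node names.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(stats::runif(sum(up)) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("G", seq_len(n)), paste0("G", seq_len(n)))
  adj
}

# Small panel for I/O and DGEA unit tests.
tiny_panel <- function() {
  gene_panel(targets = c("IL23A", "BCL6", "CXCL2"),
             housekeeping = c("ACTB", "GAPDH"),
             name = "tiny")
}

# Hand-built normalized-expression object (bypasses Ct input) for network
# and ML tests that need full control over the values.
make_norm <- function(values, group) {
  structure(list(values = values, group = stats::setNames(group, rownames(values)),
                 panel = NULL),
            class = "norm_expr")
}

# Separable cohort: only the three largest study effects planted, low noise
# (everything else null), so classifiers must find them.
separable_spec <- function(panel = default_panel()) {
  cohort_spec(panel, 22, 14,
              fold_regulation = c(IL23A = -24.3, CCR2 = -16.86,
                                  IL23R = -13.59),
              noise_sd = 0.1)
}
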