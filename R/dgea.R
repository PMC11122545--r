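#' Within-sample housekeeping normalization (2^-dCt)
#'
#' For every sample, subtracts the arithmetic mean of the housekeeping Ct
#' values from each target Ct (delta-Ct) and returns relative expression
#' `2^-dCt`. Subtracting the mean housekeeping Ct is equivalent to dividing
#' expression by the geometric mean of the housekeeping expressions, the
#' standard array-software convention. Any per-sample global Ct shift
#' cancels exactly.
#'
#' @param ct a [ct_matrix()].
#' @param panel a [gene_panel()]; all housekeeping genes must be present
#'   and unmasked in every sample.
#' @return An object of class `norm_expr`: list with `values` (samples x
#'   target genes matrix of 2^-dCt), `group`, and `panel`.
#' @export
normalize_delta_ct <- function(ct, panel) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(panel, "gene_panel"))
  missing_hk <- setdiff(panel$housekeeping, colnames(ct$ct))
  if (length(missing_hk) > 0L) {
    stop("missing housekeeping gene: ", paste(missing_hk, collapse = ", "),
         call. = FALSE)
  }
  targets <- intersect(panel$targets, colnames(ct$ct))
  if (length(targets) == 0L) stop("no panel target present", call. = FALSE)
  hk_mask <- ct$undetermined[, panel$housekeeping, drop = FALSE]
  if (any(hk_mask)) {
    idx <- which(hk_mask, arr.ind = TRUE)[1L, ]
    stop(sprintf("undetermined housekeeping well: sample %s, gene %s",
                 rownames(hk_mask)[idx[1L]], panel$housekeeping[idx[2L]]),
         call. = FALSE)
  }
  hk_mean <- rowMeans(ct$ct[, panel$housekeeping, drop = FALSE])
  dct <- ct$ct[, targets, drop = FALSE] - hk_mean
  structure(
    list(values = 2^(-dct), group = ct$group, panel = panel),
    class = "norm_expr"
  )
}

#' @export
print.norm_expr <- function(x, ...) {
  cat(sprintf("Normalized expression (2^-dCt): %d samples x %d target genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Fold-regulation display transform
#'
#' Converts a fold change (a positive ratio) to the signed reporting
#' convention of qPCR array software: the fold change itself when >= 1,
#' otherwise the negative reciprocal (so 0.5 becomes -2). Satisfies
#' `fold_regulation(1/x) == -fold_regulation(x)` for `x > 1`.
#'
#' @param fc positive numeric vector of fold changes.
#' @return signed fold regulations with `abs(.) >= 1`.
#' @export
fold_regulation <- function(fc) {
  if (any(!is.finite(fc) | fc <= 0)) {
    stop("fold change must be positive and finite", call. = FALSE)
  }
  ifelse(fc >= 1, fc, -1 / fc)
}

# Vectorized two-sample t-tests on the columns of `values` (samples x
# genes), non-responders vs responders. Pooled-variance Student's test by
# default, Welch optional. Degenerate zero-variance columns: p = 1 when the
# means agree, smallest positive double (with a warning) when they differ.
group_t_tests <- function(values, group, var_equal = TRUE) {
  a <- values[group == NON_RESPONDER, , drop = FALSE]
  b <- values[group == RESPONDER, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group", call. = FALSE)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2L, stats::var); v2 <- apply(b, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
  degen <- se == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    p[eq] <- 1
    if (any(degen & !eq)) {
      warning("zero pooled variance with unequal means; reporting smallest positive p",
              call. = FALSE)
      p[degen & !eq] <- .Machine$double.xmin
    }
  }
  list(p_value = p, mean_non_responder = m1, mean_responder = m2)
}

#' Differential expression by the delta-delta-Ct method
#'
#' Per target gene: the fold change is the ratio of group-mean relative
#' expression (non-responders over responders, responders being the control
#' group), reported as the signed fold regulation; statistical significance
#' comes from a two-sided pooled-variance Student's t-test on the per-sample
#' `2^-dCt` values. Genes are flagged `significant` at nominal p < `alpha`
#' and `dysregulated` at `|fold regulation| >= fr_cutoff`. No
#' multiple-testing correction is applied by default, matching the nominal
#' per-gene reporting convention of array analysis software; set
#' `p_adjust = "BH"` for Benjamini-Hochberg adjusted flags.
#'
#' @param ct a [ct_matrix()] (or a precomputed `norm_expr`).
#' @param panel a [gene_panel()].
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @param fr_cutoff fold-regulation magnitude for the `dysregulated` flag
#'   (default 2).
#' @param var_equal pooled-variance Student's t (default TRUE); FALSE gives
#'   Welch.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A `dgea` object: data frame with columns `gene`, `fold_change`,
#'   `fold_regulation`, `p_value`, `significant`, `dysregulated`, in panel
#'   order.
#' @export
dgea <- function(ct, panel, alpha = 0.05, fr_cutoff = 2, var_equal = TRUE,
                 p_adjust = "none") {
  norm <- if (inherits(ct, "norm_expr")) ct else normalize_delta_ct(ct, panel)
  tt <- group_t_tests(norm$values, norm$group, var_equal = var_equal)
  fc <- tt$mean_non_responder / tt$mean_responder
  p <- tt$p_value
  if (!identical(p_adjust, "none")) p <- stats::p.adjust(p, method = p_adjust)
  out <- data.frame(
    gene = colnames(norm$values),
    fold_change = unname(fc),
    fold_regulation = unname(fold_regulation(fc)),
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_value < alpha
  out$dysregulated <- abs(out$fold_regulation) >= fr_cutoff
  structure(out, class = c("dgea", "data.frame"),
            alpha = alpha, fr_cutoff = fr_cutoff,
            test = if (var_equal) "pooled t" else "Welch t",
            p_adjust = p_adjust)
}

#' Candidate gene selection
#'
#' Genes passing the fold-regulation magnitude filter, plus any forced
#' inclusions (the study design adds the significant-but-modest TNFSF14),
#' returned in stable table (panel) order.
#'
#' @param table a [dgea()] result.
#' @param force_include genes added regardless of fold regulation; must be
#'   present in the table.
#' @param fr_cutoff magnitude threshold (default 2).
#' @return character vector of candidate gene symbols.
#' @export
select_candidates <- function(table, force_include = character(),
                              fr_cutoff = 2) {
  stopifnot(inherits(table, "dgea"))
  absent <- setdiff(force_include, table$gene)
  if (length(absent) > 0L) {
    stop("force_include gene absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- abs(table$fold_regulation) >= fr_cutoff | table$gene %in% force_include
  table$gene[keep]
}

#' @export
print.dgea <- function(x, ...) {
  cat(sprintf(
    "Differential expression (delta-delta-Ct, %s): %d genes, %d significant (p < %.2g), %d beyond +/-%g-fold\n",
    attr(x, "test"), nrow(x), sum(x$significant), attr(x, "alpha"),
    sum(x$dysregulated), attr(x, "fr_cutoff")))
  utils::head(as.data.frame(x)[order(x$p_value), ], 10L) |> print()
  invisible(x)
}

#' @export
summary.dgea <- function(object, ...) {
  up <- object$dysregulated & object$fold_regulation > 0
  down <- object$dysregulated & object$fold_regulation < 0
  structure(
    list(n_genes = nrow(object), n_significant = sum(object$significant),
         n_up = sum(up), n_down = sum(down),
         up = object$gene[up][order(-object$fold_regulation[up])],
         down = object$gene[down][order(object$fold_regulation[down])]),
    class = "summary.dgea"
  )
}

#' @export
print.summary.dgea <- function(x, ...) {
  cat(sprintf("%d genes tested; %d significant; %d up- and %d down-regulated beyond the fold cutoff\n",
              x$n_genes, x$n_significant, x$n_up, x$n_down))
  if (x$n_up) cat("up:  ", paste(x$up, collapse = ", "), "\n")
  if (x$n_down) cat("down:", paste(x$down, collapse = ", "), "\n")
  invisible(x)
}

#' Fold-regulation plot
#'
#' Horizontal bar chart of fold regulations for genes beyond the
#' dysregulation cutoff. `transform = "log2_inv_dct"` applies the literal
#' `log2(1/dCt)` display transform some array reports use for expression
#' plots; it affects plotting only, never the analysis.
#'
#' @param x a [dgea()] result.
#' @param transform `"fold_regulation"` (default) or `"log2_inv_dct"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dgea <- function(x, transform = c("fold_regulation", "log2_inv_dct"),
                      ...) {
  transform <- match.arg(transform)
  sel <- x[x$dysregulated, ]
  if (nrow(sel) == 0L) {
    warning("no dysregulated gene to plot", call. = FALSE)
    return(invisible(NULL))
  }
  height <- if (transform == "fold_regulation") {
    sel$fold_regulation
  } else {
    # literal log2(1/dCt) of the implied group delta-delta-Ct display value
    log2(1 / abs(log2(sel$fold_change)))
  }
  ord <- order(height)
  graphics::barplot(height[ord], names.arg = sel$gene[ord], horiz = TRUE,
                    las = 1, xlab = transform, ...)
  invisible(x)
}
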