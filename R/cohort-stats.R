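#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (the convention under
#' which the baseline-table p-values of small two-group cohorts reproduce
#' from their printed counts), `df = (r-1)(c-1)`, upper-tail p. A table
#' with proportional rows gives statistic 0 and p = 1. Expected counts
#' below 1 are flagged in the result.
#'
#' @param counts matrix of non-negative integer counts, at least 2x2.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list of class `uskit_test`: `statistic`, `df`, `p_value`,
#'   `method`, `low_expected` flag.
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column total: expected counts undefined", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(
    list(statistic = unname(res$statistic), df = as.integer(res$parameter),
         p_value = max(unname(res$p.value), .Machine$double.xmin),
         method = if (correct) "chi-square (Yates)" else "chi-square",
         low_expected = any(expected < 1)),
    class = "uskit_test"
  )
}

#' Two-sample t-test from mean/SD summaries
#'
#' Two-sided equal-variance (pooled) Student's t-test computed from group
#' summaries alone: `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' `t = (m1-m2) / (sp sqrt(1/n1 + 1/n2))`, `df = n1+n2-2`. Equals a direct
#' two-sample t-test on the raw vectors with the same summaries. `welch =
#' TRUE` gives the unequal-variance test with Welch-Satterthwaite df.
#'
#' @param n1,mean1,sd1 first group size, mean and standard deviation.
#' @param n2,mean2,sd2 second group summaries.
#' @param welch use the unequal-variance test (default FALSE).
#' @return list of class `uskit_test`.
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                  welch = FALSE) {
  if (n1 < 2L || n2 < 2L || sd1 < 0 || sd2 < 0) {
    stop("need n >= 2 and sd >= 0 in both groups", call. = FALSE)
  }
  if (welch) {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) {
    if (mean1 == mean2) {
      p <- 1; stat <- 0
    } else {
      warning("zero pooled variance with unequal means", call. = FALSE)
      p <- .Machine$double.xmin; stat <- Inf * sign(mean1 - mean2)
    }
  } else {
    stat <- (mean1 - mean2) / se
    p <- 2 * stats::pt(-abs(stat), df)
  }
  structure(
    list(statistic = stat, df = df, p_value = p,
         method = if (welch) "Welch t (from summaries)" else "pooled t (from summaries)"),
    class = "uskit_test"
  )
}

#' @export
print.uskit_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Synthetic per-sample clinical baseline cohort
#'
#' A 36-sample clinical data frame (22 responders, 14 non-responders)
#' reconstructed from group-level summaries: categorical variables (sex,
#' Montreal extent, smoking status, prior anti-TNF exposure) match the
#' published group counts exactly; continuous variables (age, WBC, CRP,
#' platelets, hemoglobin) are moment-matched synthetic vectors with the
#' exact group mean and SD (so summary-based and raw-data tests agree);
#' Mayo scores are integers/half-integers matching the group medians. The
#' individual values are synthetic, not patient data.
#'
#' @return data frame with one row per sample.
#' @export
baseline_cohort <- function() {
  # deterministic moment-matched vector: exact mean and sample sd
  mm <- function(n, mean, sd) {
    b <- seq_len(n)
    b <- (b - mean(b)) / stats::sd(b)
    mean + sd * b
  }
  fill <- function(counts, levels) rep(levels, counts)
  resp <- data.frame(
    group = RESPONDER,
    sex = fill(c(16, 6), c("male", "female")),
    montreal = fill(c(1, 9, 12), c("E1", "E2", "E3")),
    smoking = fill(c(8, 4, 10), c("never", "former", "active")),
    anti_tnf = fill(c(9, 13), c("yes", "no")),
    age = mm(22, 48.43, 15.37),
    mayo = rep(c(7, 8), c(11, 11)),           # median 7.5
    wbc = mm(22, 8389.58, 3082.1),
    crp = mm(22, 0.97, 1.11),
    platelets = mm(22, 352680, 118288),
    hemoglobin = mm(22, 12.31, 1.71),
    stringsAsFactors = FALSE
  )
  nonresp <- data.frame(
    group = NON_RESPONDER,
    sex = fill(c(10, 4), c("male", "female")),
    montreal = fill(c(0, 6, 8), c("E1", "E2", "E3")),
    smoking = fill(c(3, 1, 10), c("never", "former", "active")),
    anti_tnf = fill(c(5, 9), c("yes", "no")),
    age = mm(14, 55.86, 19.37),
    mayo = rep(c(6, 7, 8), c(4, 6, 4)),       # median 7
    wbc = mm(14, 7951.67, 1917.6),
    crp = mm(14, 1.95, 2.94),
    platelets = mm(14, 274727.3, 103577),
    hemoglobin = mm(14, 13.45, 2.10),
    stringsAsFactors = FALSE
  )
  out <- rbind(resp, nonresp)
  out$sample_id <- sprintf("%s_%02d",
                           ifelse(out$group == RESPONDER, "R", "NR"),
                           c(seq_len(22), seq_len(14)))
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}

#' Clinical baseline comparison table
#'
#' Per-variable two-group summaries with the appropriate univariate test:
#' chi-square (no continuity correction) on the group-by-category counts
#' for categorical variables, pooled two-sample t for continuous
#' variables, and group medians without a test for ordinal scores (a
#' Wilcoxon rank-sum p can be added as a clearly labelled extension).
#'
#' @param records per-sample data frame.
#' @param group_col name of the response-group column (default `"group"`).
#' @param categorical,continuous,ordinal character vectors naming the
#'   variables of each kind.
#' @param ordinal_test add a Wilcoxon rank-sum test for ordinal variables
#'   (default FALSE).
#' @return A `baseline_table`: data frame with columns `variable`, `kind`,
#'   `summary_responder`, `summary_non_responder`, `test`, `p_value`.
#' @export
build_baseline_table <- function(records, group_col = "group",
                                 categorical = character(),
                                 continuous = character(),
                                 ordinal = character(),
                                 ordinal_test = FALSE) {
  grp <- records[[group_col]]
  if (length(unique(grp)) < 2L) {
    stop("need both response groups in the records", call. = FALSE)
  }
  grp <- factor(grp, levels = GROUP_LEVELS)
  rows <- list()
  add <- function(variable, kind, s1, s2, test, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, kind = kind, summary_responder = s1,
      summary_non_responder = s2, test = test, p_value = p,
      stringsAsFactors = FALSE)
  }
  cat_summary <- function(x) {
    tab <- table(x)
    paste(sprintf("%s %d", names(tab), tab), collapse = "; ")
  }
  for (v in categorical) {
    x <- records[[v]]
    ok <- !is.na(x)
    if (!any(ok)) { warning("all-missing variable skipped: ", v); next }
    counts <- table(grp[ok], x[ok])
    res <- chi_square_test(unclass(counts))
    add(v, "categorical",
        cat_summary(x[ok & grp == RESPONDER]),
        cat_summary(x[ok & grp == NON_RESPONDER]),
        res$method, res$p_value)
  }
  for (v in continuous) {
    x <- records[[v]]
    ok <- !is.na(x)
    if (!any(ok)) { warning("all-missing variable skipped: ", v); next }
    a <- x[ok & grp == RESPONDER]; b <- x[ok & grp == NON_RESPONDER]
    res <- pooled_t_from_summary(length(a), mean(a), stats::sd(a),
                                 length(b), mean(b), stats::sd(b))
    add(v, "continuous",
        sprintf("%.2f (%.2f)", mean(a), stats::sd(a)),
        sprintf("%.2f (%.2f)", mean(b), stats::sd(b)),
        res$method, res$p_value)
  }
  for (v in ordinal) {
    x <- records[[v]]
    ok <- !is.na(x)
    if (!any(ok)) { warning("all-missing variable skipped: ", v); next }
    a <- x[ok & grp == RESPONDER]; b <- x[ok & grp == NON_RESPONDER]
    p <- if (ordinal_test) {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    } else {
      NA_real_
    }
    add(v, "ordinal",
        sprintf("median %.3g", stats::median(a)),
        sprintf("median %.3g", stats::median(b)),
        if (ordinal_test) "Wilcoxon rank-sum (extension)" else "none", p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("baseline_table", "data.frame"))
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("Baseline characteristics by response group\n")
  df <- as.data.frame(x)
  df$p_value <- ifelse(is.na(df$p_value), "-", sprintf("%.3f", df$p_value))
  print(df, right = FALSE)
  invisible(x)
}
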