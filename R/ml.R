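#' Stratified train/test split with cross-validation folds
#'
#' Splits the cohort into training and held-out test sets, stratified by
#' response class with the training share rounded up within each class (so
#' a 36-sample 22/14 cohort at fraction 0.6 yields 23 training and 13 test
#' samples), and assigns stratified cross-validation folds over the
#' training ids. Deterministic for a fixed seed.
#'
#' @param norm a `norm_expr` from [normalize_delta_ct()].
#' @param fraction training share in (0, 1) (default 0.6).
#' @param seed integer seed.
#' @param n_folds number of cross-validation folds (default 5).
#' @return An object of class `split_spec`: list with `train_ids`,
#'   `test_ids`, `folds` (named integer vector over training ids) and
#'   `seed`.
#' @export
split_cohort <- function(norm, fraction = 0.6, seed, n_folds = 5) {
  stopifnot(inherits(norm, "norm_expr"))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0,1): both sides of the split must be non-empty",
         call. = FALSE)
  }
  ids <- rownames(norm$values)
  grp <- norm$group[ids]
  if (any(table(factor(grp, levels = GROUP_LEVELS)) < 5L)) {
    stop("need >= 5 samples per class to split and fold", call. = FALSE)
  }
  with_local_seed(substream_seed(seed, "split"), {
    train_ids <- unlist(lapply(GROUP_LEVELS, function(g) {
      g_ids <- ids[grp == g]
      sample(g_ids, ceiling(fraction * length(g_ids)))
    }), use.names = FALSE)
    test_ids <- setdiff(ids, train_ids)
    # stratified folds: within each class, deal shuffled ids round-robin
    folds <- integer(0)
    for (g in GROUP_LEVELS) {
      g_train <- sample(intersect(train_ids, ids[grp == g]))
      f <- rep_len(seq_len(n_folds), length(g_train))
      folds <- c(folds, stats::setNames(f, g_train))
    }
    folds <- folds[train_ids]
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   folds = folds, seed = seed),
              class = "split_spec")
  })
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Split: %d training / %d test samples, %d CV folds (seed %d)\n",
              length(x$train_ids), length(x$test_ids),
              length(unique(x$folds)), x$seed))
  invisible(x)
}

#' Rank-based AUC
#'
#' Probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one, with ties counting one half (the Mann-Whitney
#' statistic scaled to \[0, 1\]).
#'
#' @param scores numeric prediction scores.
#' @param labels per-sample class labels.
#' @param positive label of the positive class (default `"non-responder"`,
#'   the event being predicted).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels, positive = NON_RESPONDER) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# -- learner registry ---------------------------------------------------
# Each learner: fit(x, y01, params, seed) -> model; predict -> positive-class
# score; importance -> non-negative named vector over features; grid -> list
# of candidate hyperparameter sets tuned by CV AUC.

xgb_fit <- function(x, y01, params, seed) {
  xgboost::xgboost(
    x = x, y = factor(y01, levels = c(0, 1)),
    nrounds = params$nrounds, max_depth = params$max_depth,
    learning_rate = params$eta, subsample = params$subsample,
    nthreads = 1, seed = abs(seed) %% .Machine$integer.max, verbosity = 0
  )
}

xgb_importance <- function(model, features) {
  imp <- stats::setNames(rep(0, length(features)), features)
  tab <- xgboost::xgb.importance(model = model)
  imp[tab$Feature] <- tab$Gain
  imp
}

learner_registry <- function() {
  list(
    xgboost = list(
      grid = lapply(c(30L, 60L), function(nr)
        list(nrounds = nr, max_depth = 3, eta = 0.3, subsample = 1)),
      fit = xgb_fit,
      predict = function(model, x) stats::predict(model, x),
      importance = xgb_importance
    ),
    # classic stochastic gradient-boosting profile: shallow trees, slow
    # learning rate, row subsampling
    gbm = list(
      grid = lapply(c(100L, 200L), function(nr)
        list(nrounds = nr, max_depth = 2, eta = 0.1, subsample = 0.8)),
      fit = xgb_fit,
      predict = function(model, x) stats::predict(model, x),
      importance = xgb_importance
    ),
    drf = list(
      grid = lapply(c(-1, 0), function(d)
        list(mtry_f = if (d < 0) function(p) floor(sqrt(p)) else function(p) max(1L, floor(p / 3)))),
      fit = function(x, y01, params, seed) {
        with_local_seed(seed, randomForest::randomForest(
          x = as.data.frame(x), y = factor(y01, levels = c(0, 1)),
          ntree = 500, mtry = params$mtry_f(ncol(x)), importance = FALSE))
      },
      predict = function(model, x)
        stats::predict(model, as.data.frame(x), type = "prob")[, "1"],
      importance = function(model, features) {
        imp <- stats::setNames(rep(0, length(features)), features)
        gi <- randomForest::importance(model, type = 2)[, 1L]
        imp[names(gi)] <- pmax(gi, 0)
        imp
      }
    ),
    xrt = list(
      grid = lapply(c(-1, 0), function(d)
        list(mtry_f = if (d < 0) function(p) floor(sqrt(p)) else function(p) max(1L, floor(p / 3)))),
      fit = function(x, y01, params, seed) {
        df <- as.data.frame(x)
        df$.y <- factor(y01, levels = c(0, 1))
        ranger::ranger(
          dependent.variable.name = ".y", data = df, num.trees = 500,
          mtry = params$mtry_f(ncol(x)), splitrule = "extratrees",
          num.random.splits = 1, probability = TRUE,
          importance = "impurity", seed = seed, num.threads = 1)
      },
      predict = function(model, x)
        stats::predict(model, data = as.data.frame(x),
                       num.threads = 1)$predictions[, "1"],
      importance = function(model, features) {
        imp <- stats::setNames(rep(0, length(features)), features)
        gi <- ranger::importance(model)
        imp[names(gi)] <- pmax(gi, 0)
        imp
      }
    ),
    glm = list(
      grid = list(list(alpha = 0.5)),
      fit = function(x, y01, params, seed) {
        with_local_seed(seed, glmnet::glmnet(
          x, y01, family = "binomial", alpha = params$alpha))
      },
      predict = NULL,  # handled specially (lambda path)
      importance = NULL
    )
  )
}

fit_one_algorithm <- function(algo, x_train, y_train, x_test, folds, seed) {
  reg <- learner_registry()[[algo]]
  features <- colnames(x_train)
  fold_ids <- sort(unique(folds))

  if (algo == "glm") {
    # elastic-net path: lambda picked by cross-validated deviance over the
    # split's own folds (folds this small cannot support per-fold AUC
    # curves); the reported cv_auc is then recomputed fold by fold at the
    # selected lambda. Small-class fold warnings are expected at this
    # cohort size and muffled.
    quiet_smalln <- function(expr) {
      withCallingHandlers(expr, warning = function(w) {
        if (grepl("fewer than 8|Too few", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    }
    cv <- quiet_smalln(with_local_seed(seed, glmnet::cv.glmnet(
      x_train, y_train, family = "binomial", alpha = 0.5,
      foldid = as.integer(factor(folds)), type.measure = "deviance")))
    lam <- cv$lambda.min
    fold_aucs <- vapply(fold_ids, function(f) {
      tr <- folds != f
      if (length(unique(y_train[!tr])) < 2L) return(NA_real_)
      fit_f <- quiet_smalln(glmnet::glmnet(
        x_train[tr, , drop = FALSE], y_train[tr], family = "binomial",
        alpha = 0.5))
      s <- as.numeric(stats::predict(fit_f, x_train[!tr, , drop = FALSE],
                                     s = lam, type = "response"))
      compute_auc(s, y_train[!tr], positive = 1)
    }, numeric(1))
    fit <- cv$glmnet.fit
    score_test <- as.numeric(stats::predict(fit, x_test, s = lam,
                                            type = "response"))
    cf <- abs(as.numeric(stats::coef(fit, s = lam))[-1L])
    imp <- stats::setNames(cf, features)
    return(list(score = score_test, importance = imp,
                cv_auc = mean(fold_aucs, na.rm = TRUE)))
  }

  # grid tuning by mean CV AUC over the provided folds
  cv_scores <- vapply(reg$grid, function(params) {
    aucs <- vapply(fold_ids, function(f) {
      tr <- folds != f
      if (length(unique(y_train[!tr])) < 2L) return(NA_real_)
      m <- reg$fit(x_train[tr, , drop = FALSE], y_train[tr], params,
                   seed = seed + f)
      s <- reg$predict(m, x_train[!tr, , drop = FALSE])
      compute_auc(s, y_train[!tr], positive = 1)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- reg$grid[[which.max(cv_scores)]]
  model <- reg$fit(x_train, y_train, best, seed = seed)
  list(score = reg$predict(model, x_test),
       importance = reg$importance(model, features),
       cv_auc = max(cv_scores))
}

#' Train the response classifiers
#'
#' Fits the configured algorithms on the training side of the split (each
#' tuned by cross-validation AUC over the split's folds), scores each once
#' on the held-out test set, and reports per-algorithm test AUC, CV AUC
#' and the top-10 feature importances (normalized to sum one over the full
#' feature set). All target-gene expressions are supplied as features; the
#' positive class is non-response. Deterministic for a fixed seed.
#'
#' Algorithms: `"xgboost"` and `"gbm"` (two gradient-boosted tree
#' profiles), `"drf"` (random forest), `"xrt"` (extremely randomized
#' trees), `"glm"` (elastic-net logistic regression).
#'
#' @param norm a `norm_expr`.
#' @param split a [split_cohort()] result.
#' @param algorithms subset of the five learners (default all).
#' @param seed integer seed (default: the split's seed).
#' @return An object of class `ml_report`: per-algorithm list with `auc`,
#'   `cv_auc` and `importance` (top-10 named numeric vector).
#' @export
train_models <- function(norm, split,
                         algorithms = c("xgboost", "gbm", "xrt", "drf", "glm"),
                         seed = split$seed) {
  stopifnot(inherits(norm, "norm_expr"), inherits(split, "split_spec"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  x <- norm$values
  y01 <- as.integer(norm$group == NON_RESPONDER)
  names(y01) <- rownames(x)
  x_train <- x[split$train_ids, , drop = FALSE]
  x_test <- x[split$test_ids, , drop = FALSE]
  y_train <- y01[split$train_ids]
  y_test <- y01[split$test_ids]
  if (length(unique(y_train)) < 2L || length(unique(y_test)) < 2L) {
    stop("both classes must be present in train and test sets", call. = FALSE)
  }
  base_seed <- substream_seed(seed, "model")
  out <- list()
  for (i in seq_along(algorithms)) {
    algo <- algorithms[[i]]
    res <- fit_one_algorithm(algo, x_train, y_train, x_test, split$folds,
                             seed = base_seed + 1000L * i)
    total <- sum(res$importance)
    imp <- if (total > 0) res$importance / total else res$importance
    imp <- sort(imp, decreasing = TRUE)
    out[[algo]] <- list(
      auc = compute_auc(res$score, y_test, positive = 1),
      cv_auc = res$cv_auc,
      importance = utils::head(imp, 10L)
    )
  }
  structure(out, class = "ml_report", seed = seed)
}

#' @export
print.ml_report <- function(x, ...) {
  cat("Response classification report (positive class: non-responder)\n")
  for (algo in names(x)) {
    top <- names(x[[algo]]$importance)[seq_len(min(3L, length(x[[algo]]$importance)))]
    cat(sprintf("  %-8s test AUC %.3f  (CV AUC %.3f)  top: %s\n",
                algo, x[[algo]]$auc, x[[algo]]$cv_auc,
                paste(top, collapse = ", ")))
  }
  invisible(x)
}

#' Consensus feature ranking across algorithms
#'
#' Averages the normalized importances of each gene across the reports'
#' algorithms (genes absent from an algorithm's top list contribute zero)
#' and returns the `k` genes with the highest mean importance.
#'
#' @param reports an `ml_report` or list of them.
#' @param k number of consensus genes (default 10).
#' @return data frame with columns `gene`, `mean_importance`, and one
#'   importance column per algorithm.
#' @export
consensus_features <- function(reports, k = 10) {
  if (inherits(reports, "ml_report")) reports <- list(reports)
  algos <- unlist(lapply(reports, names), use.names = FALSE)
  if (length(algos) < 2L) {
    stop("need importances from at least two algorithms", call. = FALSE)
  }
  imps <- list()
  for (rep_i in reports) {
    for (algo in names(rep_i)) imps[[algo]] <- rep_i[[algo]]$importance
  }
  genes <- sort(unique(unlist(lapply(imps, names), use.names = FALSE)))
  mat <- vapply(imps, function(v) {
    out <- stats::setNames(rep(0, length(genes)), genes)
    out[names(v)] <- v
    out
  }, numeric(length(genes)))
  mean_imp <- rowMeans(mat)
  ord <- order(-mean_imp, genes)
  out <- data.frame(gene = genes[ord], mean_importance = mean_imp[ord],
                    mat[ord, , drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(out, k)
}
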