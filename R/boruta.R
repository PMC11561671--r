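#' Configuration for shadow-feature random-forest selection
#'
#' @param n_trees trees per forest.
#' @param max_runs maximum shadow-comparison runs within one selection run.
#' @param alpha significance level of the binomial decision test.
#' @param multiple_testing apply a Bonferroni correction over the number of
#'   still-undecided attributes.
#' @param mode `"numeric"` (regression target) or `"categorical"`
#'   (classification target).
#' @param n_iterations number of independent selection runs aggregated into
#'   an ensemble.
#' @param min_nonrejected_iterations a feature enters the ensemble hit set
#'   when it is nonrejected (confirmed or tentative) in at least this many
#'   iterations.
#' @param importance `"permutation"` (Z-like scaled permutation importance,
#'   the default) or `"impurity"` (fast fallback).
#' @param mtry_fraction fraction of the (augmented) feature columns tried at
#'   each split; `NULL` uses the forest default (p/3 for regression, sqrt(p)
#'   for classification). Raising it helps the forest expose pure
#'   interaction effects that have no marginal signal.
#' @param seed integer seed.
#' @return Object of class `boruta_config`.
#' @export
boruta_config <- function(n_trees = 500, max_runs = 100, alpha = 0.01,
                          multiple_testing = TRUE,
                          mode = c("numeric", "categorical"),
                          n_iterations = 30, min_nonrejected_iterations = 1,
                          importance = c("permutation", "impurity"),
                          mtry_fraction = NULL,
                          seed = 1L) {
  mode <- match.arg(mode)
  importance <- match.arg(importance)
  if (max_runs < 5) stop("`max_runs` must be at least 5", call. = FALSE)
  if (n_iterations < 1) stop("`n_iterations` must be at least 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), max_runs = as.integer(max_runs),
                 alpha = alpha, multiple_testing = isTRUE(multiple_testing),
                 mode = mode, n_iterations = as.integer(n_iterations),
                 min_nonrejected_iterations = as.integer(min_nonrejected_iterations),
                 importance = importance, mtry_fraction = mtry_fraction,
                 seed = as.integer(seed)),
            class = "boruta_config")
}

#' Augment a feature table with permuted shadow copies
#'
#' Every original feature is duplicated with independently permuted sample
#' order, providing an in-model importance null reference.
#'
#' @param X numeric matrix or data.frame (samples x features).
#' @param seed integer seed for the permutations.
#' @return Matrix with original columns followed by `shadow_<name>` columns;
#'   attribute `"shadow"` is a logical vector marking the shadow columns.
#' @export
shadow_augment <- function(X, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 1 || nrow(X) < 2) stop("need at least one feature and two samples", call. = FALSE)
  with_seed(seed, {
    shadows <- apply(X, 2, sample)
  })
  colnames(shadows) <- paste0("shadow_", colnames(X))
  out <- cbind(X, shadows)
  attr(out, "shadow") <- c(rep(FALSE, ncol(X)), rep(TRUE, ncol(X)))
  out
}

#' Binomial hit-count decision
#'
#' Two-sided binomial test of the hit count against chance (p = 0.5): a
#' feature is confirmed when its upper-tail probability falls below
#' `alpha / m` and rejected when its lower-tail probability does, otherwise
#' it stays tentative.
#'
#' @param hits number of runs in which the feature beat the best shadow.
#' @param runs number of runs the feature took part in.
#' @param alpha significance level.
#' @param m Bonferroni divisor (number of undecided attributes; use 1 for no
#'   correction).
#' @return `"confirmed"`, `"rejected"` or `"tentative"`.
#' @export
boruta_decide <- function(hits, runs, alpha = 0.01, m = 1) {
  stopifnot(hits >= 0, hits <= runs)
  if (runs == 0) return("tentative")
  upper <- stats::pbinom(hits - 1, runs, 0.5, lower.tail = FALSE)
  lower <- stats::pbinom(hits, runs, 0.5)
  if (upper < alpha / m) "confirmed"
  else if (lower < alpha / m) "rejected"
  else "tentative"
}

fit_forest <- function(X, y, config, seed) {
  df <- as.data.frame(X)
  mtry <- if (!is.null(config$mtry_fraction)) max(1L, floor(config$mtry_fraction * ncol(df)))
  ranger::ranger(
    x = df, y = y,
    num.trees = config$n_trees,
    importance = config$importance,
    scale.permutation.importance = config$importance == "permutation",
    mtry = mtry,
    num.threads = 1,
    seed = seed
  )
}

#' One shadow-feature selection run
#'
#' Repeats up to `max_runs` times: augment the still-active features with
#' permuted shadows, fit a random forest, score a hit for every feature whose
#' importance exceeds the best shadow importance, and classify undecided
#' features by the binomial decision rule. Rejected features leave the model;
#' confirmed features remain (they keep shaping multivariate importance).
#'
#' @param X numeric matrix or data.frame (samples x features), all finite.
#' @param y numeric response (`mode = "numeric"`) or factor
#'   (`mode = "categorical"`).
#' @param config a [boruta_config()].
#' @return Object of class `boruta_run`: data.frame `features` with columns
#'   `feature`, `decision`, `meanImp`, `normHits`, `runs_present`, plus the
#'   number of comparison runs performed.
#' @export
boruta_run <- function(X, y, config = boruta_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  bad <- colnames(X)[!apply(is.finite(X), 2, all)]
  if (length(bad)) stop(sprintf("non-finite values in feature column(s): %s",
                                paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  if (any(!is.finite(as.numeric(if (is.factor(y)) seq_along(levels(y))[y] else y)))) {
    stop("non-finite values in the response", call. = FALSE)
  }
  if (config$mode == "categorical" && !is.factor(y)) y <- factor(y)
  if (config$mode == "numeric" && is.factor(y)) stop("numeric mode requires a numeric response", call. = FALSE)

  features <- colnames(X)
  p <- length(features)
  state <- stats::setNames(rep("undecided", p), features)
  hits <- stats::setNames(integer(p), features)
  runs_present <- stats::setNames(integer(p), features)
  imp_sum <- stats::setNames(numeric(p), features)
  runs_done <- 0

  for (run in seq_len(config$max_runs)) {
    active <- features[state != "rejected"]
    if (!any(state == "undecided")) break
    run_seed <- derive_seed(config$seed, paste0("run", run))
    aug <- shadow_augment(X[, active, drop = FALSE], seed = run_seed)
    # keep at least 5 shadows so the max-shadow reference stays stable
    if (length(active) < 5) {
      extra <- with_seed(derive_seed(run_seed, "pad"), {
        cols <- sample(active, 5 - length(active), replace = TRUE)
        pad <- sapply(cols, function(cl) sample(X[, cl]))
        pad <- matrix(pad, nrow = nrow(X))
        colnames(pad) <- paste0("shadow_pad", seq_len(ncol(pad)))
        pad
      })
      shadow_flag <- c(attr(aug, "shadow"), rep(TRUE, ncol(extra)))
      aug <- cbind(aug, extra)
      attr(aug, "shadow") <- shadow_flag
    }
    fit <- fit_forest(aug, y, config, seed = run_seed)
    imp <- fit$variable.importance
    shadow_max <- max(imp[attr(aug, "shadow")])
    act_imp <- imp[active]
    hit <- act_imp > shadow_max
    hits[active] <- hits[active] + hit
    runs_present[active] <- runs_present[active] + 1L
    imp_sum[active] <- imp_sum[active] + act_imp
    runs_done <- run

    und <- features[state == "undecided"]
    m <- if (config$multiple_testing) length(und) else 1
    for (f in und) {
      state[f] <- switch(boruta_decide(hits[f], runs_present[f], config$alpha, m),
                         confirmed = "confirmed", rejected = "rejected",
                         tentative = "undecided")
    }
  }
  state[state == "undecided"] <- "tentative"
  res <- data.frame(
    feature = features,
    decision = unname(state),
    meanImp = unname(ifelse(runs_present > 0, imp_sum / runs_present, NA_real_)),
    normHits = unname(ifelse(runs_present > 0, hits / runs_present, 0)),
    runs_present = unname(runs_present),
    stringsAsFactors = FALSE
  )
  structure(list(features = res, runs = runs_done, config = config), class = "boruta_run")
}

#' @export
print.boruta_run <- function(x, ...) {
  tab <- table(factor(x$features$decision, c("confirmed", "tentative", "rejected")))
  cat(sprintf("boruta_run (%s mode, %d comparison runs): %d confirmed, %d tentative, %d rejected\n",
              x$config$mode, x$runs, tab["confirmed"], tab["tentative"], tab["rejected"]))
  invisible(x)
}

#' Iterated selection ensemble
#'
#' Repeats [boruta_run()] `n_iterations` times with independently derived
#' seeds and aggregates per feature: the count of iterations in which the
#' feature was nonrejected (confirmed or tentative), and the iteration means
#' of `meanImp` and `normHits`. The ensemble hit set contains every feature
#' nonrejected in at least `min_nonrejected_iterations` iterations.
#'
#' @inheritParams boruta_run
#' @return Object of class `boruta_ensemble` with a per-feature data.frame
#'   (`feature`, `n_nonrejected`, `n_confirmed`, `meanImp`, `normHits`,
#'   `in_hit_set`), the `hit_set`, the per-iteration decision matrix and the
#'   configuration.
#' @export
boruta_ensemble <- function(X, y, config = boruta_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  features <- colnames(X)
  n_it <- config$n_iterations
  decisions <- matrix(NA_character_, length(features), n_it,
                      dimnames = list(features, NULL))
  imp <- matrix(NA_real_, length(features), n_it, dimnames = list(features, NULL))
  nh <- matrix(NA_real_, length(features), n_it, dimnames = list(features, NULL))
  for (i in seq_len(n_it)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, paste0("iteration", i))
    run <- boruta_run(X, y, cfg_i)
    decisions[run$features$feature, i] <- run$features$decision
    imp[run$features$feature, i] <- run$features$meanImp
    nh[run$features$feature, i] <- run$features$normHits
  }
  nonrej <- decisions != "rejected"
  res <- data.frame(
    feature = features,
    n_nonrejected = rowSums(nonrej),
    n_confirmed = rowSums(decisions == "confirmed"),
    meanImp = rowMeans(imp, na.rm = TRUE),
    normHits = rowMeans(nh, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  res$in_hit_set <- res$n_nonrejected >= config$min_nonrejected_iterations
  structure(list(features = res, hit_set = res$feature[res$in_hit_set],
                 decisions = decisions, config = config),
            class = "boruta_ensemble")
}

#' @export
print.boruta_ensemble <- function(x, ...) {
  cat(sprintf("boruta_ensemble (%s mode, %d iterations): %d of %d features in hit set\n",
              x$config$mode, x$config$n_iterations, length(x$hit_set), nrow(x$features)))
  invisible(x)
}

#' Cohen's kappa from a confusion matrix
#'
#' @param confusion square contingency matrix (rows = truth, columns =
#'   prediction, or vice versa).
#' @return Kappa in \[-1, 1\].
#' @export
kappa_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

stratified_folds <- function(strata, folds, seed) {
  strata <- as.factor(strata)
  fold <- integer(length(strata))
  with_seed(seed, {
    for (lev in levels(strata)) {
      idx <- sample(which(strata == lev))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated predictive accuracy of a feature subset
#'
#' Random-forest cross-validation of the response from a feature subset. In
#' numeric mode the regression predictions are snapped to the nearest design
#' age level before scoring, so accuracy and Cohen's kappa are defined in
#' both modes. Folds are stratified by class (by age level in numeric mode).
#'
#' @param X numeric matrix (samples x features).
#' @param y response: numeric ages (numeric mode) or factor (categorical).
#' @param feature_subset columns of `X` to use.
#' @param mode `"numeric"` or `"categorical"`.
#' @param folds number of cross-validation folds.
#' @param seed integer seed (folding and forests).
#' @param n_trees trees per fold forest.
#' @return Object of class `prediction_eval`: `accuracy`, `kappa`, `folds`,
#'   `mode`, `confusion`.
#' @export
evaluate_prediction <- function(X, y, feature_subset = colnames(X),
                                mode = c("numeric", "categorical"),
                                folds = 10, seed = 1L, n_trees = 500) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  missing <- setdiff(feature_subset, colnames(X))
  if (length(missing)) stop(sprintf("feature subset not in X: %s",
                                    paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  if (length(feature_subset) == 0) stop("empty feature subset", call. = FALSE)
  Xs <- X[, feature_subset, drop = FALSE]
  if (mode == "numeric") {
    levels_num <- sort(unique(y))
    classes <- factor(y, levels = levels_num)
  } else {
    classes <- as.factor(y)
  }
  if (nlevels(classes) < 2) stop("response must have at least two classes", call. = FALSE)
  folds <- min(folds, min(table(classes)))
  if (folds < 2) stop("not enough samples per class for stratified folding", call. = FALSE)
  fold <- stratified_folds(classes, folds, seed)
  pred_class <- factor(rep(NA_character_, length(y)), levels = levels(classes))
  for (k in seq_len(folds)) {
    train <- fold != k
    fit <- ranger::ranger(x = as.data.frame(Xs[train, , drop = FALSE]),
                          y = if (mode == "numeric") y[train] else classes[train],
                          num.trees = n_trees, num.threads = 1,
                          seed = derive_seed(seed, paste0("fold", k)))
    pr <- stats::predict(fit, data = as.data.frame(Xs[!train, , drop = FALSE]))$predictions
    if (mode == "numeric") {
      snapped <- levels_num[apply(abs(outer(pr, levels_num, "-")), 1, which.min)]
      pred_class[!train] <- factor(snapped, levels = levels_num)
    } else {
      pred_class[!train] <- pr
    }
  }
  confusion <- table(truth = classes, prediction = pred_class)
  structure(list(accuracy = mean(pred_class == classes),
                 kappa = kappa_from_confusion(confusion),
                 folds = folds, mode = mode, confusion = confusion),
            class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s mode): accuracy %.3f, kappa %.3f\n",
              x$folds, x$mode, x$accuracy, x$kappa))
  invisible(x)
}
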