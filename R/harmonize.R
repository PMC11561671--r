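#' Z-score genes within sample groups
#'
#' Within each group of samples, every gene is centered to mean 0 and scaled
#' to unit population variance; genes that are constant within a group map to
#' zero there (never NaN).
#'
#' @param matrix numeric genes x samples matrix.
#' @param groups vector/factor of length `ncol(matrix)` giving the group of
#'   each sample. Every group must contain at least two samples.
#' @return Matrix of the same shape.
#' @export
zscore_within <- function(matrix, groups) {
  assert_expression_matrix(matrix)
  groups <- as.factor(groups)
  if (length(groups) != ncol(matrix)) stop("`groups` must have one entry per sample", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop(sprintf("singleton group(s) cannot be z-scored: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")), call. = FALSE)
  }
  out <- matrix
  for (g in levels(groups)) {
    idx <- which(groups == g)
    out[, idx] <- standardize_rows(matrix[, idx, drop = FALSE])
  }
  out
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Parametric empirical-Bayes location/scale batch correction of the
#' expression matrix, with per-batch effects shrunk toward common priors.
#' The adjustment is delegated to \code{sva::ComBat} (parametric priors, no
#' covariate preservation). Genes with essentially no within-batch variance
#' are passed through unchanged rather than producing NaNs.
#'
#' @param matrix numeric genes x samples matrix.
#' @param batch vector/factor of batch labels, one per sample; every batch
#'   must contain at least two samples.
#' @return Adjusted matrix of identical shape.
#' @export
combat_eb <- function(matrix, batch) {
  assert_expression_matrix(matrix)
  batch <- as.factor(batch)
  if (length(batch) != ncol(matrix)) stop("`batch` must have one entry per sample", call. = FALSE)
  if (nlevels(batch) < 2) {
    warning("single batch: returning input unchanged")
    return(matrix)
  }
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop(sprintf("batch(es) with fewer than 2 samples: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")), call. = FALSE)
  }
  # within-batch residual variance per gene; degenerate genes bypass the EB fit
  bm <- matrix(0, nrow(matrix), ncol(matrix))
  for (b in levels(batch)) {
    idx <- which(batch == b)
    bm[, idx] <- rowMeans(matrix[, idx, drop = FALSE])
  }
  v <- rowMeans((matrix - bm)^2)
  ok <- v > 1e-12
  out <- matrix
  if (any(ok)) {
    adj <- suppressMessages(sva::ComBat(dat = matrix[ok, , drop = FALSE], batch = batch,
                                        mod = NULL, par.prior = TRUE, prior.plots = FALSE))
    out[ok, ] <- adj
  }
  out
}

#' Define a consecutive correction plan
#'
#' A plan is an ordered list of correction steps, each removing one nuisance
#' covariate by z-scoring or empirical-Bayes adjustment. With `nesting = TRUE`
#' (the default), step *k* is fitted separately within every stratum defined
#' by the covariates already corrected in steps 1..k-1 ("consecutively fitted
#' subgroups").
#'
#' @param steps named character vector: names are covariates (in application
#'   order), values are methods (`"zscore"` or `"combat"`).
#' @param nesting logical; fit each step within strata of previously corrected
#'   covariates.
#' @return Object of class `correction_plan`.
#' @export
correction_plan <- function(steps = character(), nesting = TRUE) {
  if (length(steps)) {
    if (is.null(names(steps)) || any(!nzchar(names(steps)))) {
      stop("`steps` must be a named character vector (covariate = method)", call. = FALSE)
    }
    if (anyDuplicated(names(steps))) stop("no covariate may be corrected twice", call. = FALSE)
    bad <- setdiff(steps, c("zscore", "combat"))
    if (length(bad)) stop(sprintf("unknown correction method(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
    if ("age" %in% names(steps)) stop("the age variable is the signal of interest and is never corrected", call. = FALSE)
  }
  structure(list(steps = steps, nesting = isTRUE(nesting)), class = "correction_plan")
}

#' @export
print.correction_plan <- function(x, ...) {
  if (!length(x$steps)) {
    cat("correction_plan: <identity>\n")
  } else {
    cat(sprintf("correction_plan (%s): %s\n", if (x$nesting) "nested" else "flat",
                paste(sprintf("%s(%s)", x$steps, names(x$steps)), collapse = " -> ")))
  }
  invisible(x)
}

plan_string <- function(plan) {
  if (!length(plan$steps)) return("<identity>")
  paste(sprintf("%s(%s)", plan$steps, names(plan$steps)), collapse = "->")
}

#' Apply a correction plan
#'
#' @param matrix numeric genes x samples matrix.
#' @param samples data.frame with one row per sample containing the plan's
#'   covariates.
#' @param plan a [correction_plan()].
#' @return Corrected matrix; the applied plan is attached as attribute
#'   `"plan"`.
#' @export
apply_plan <- function(matrix, samples, plan) {
  stopifnot(inherits(plan, "correction_plan"))
  assert_expression_matrix(matrix)
  if (nrow(samples) != ncol(matrix)) stop("`samples` must have one row per sample column", call. = FALSE)
  missing <- setdiff(names(plan$steps), names(samples))
  if (length(missing)) stop(sprintf("covariate(s) absent from sample table: %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  out <- matrix
  covs <- names(plan$steps)
  for (k in seq_along(plan$steps)) {
    cov <- covs[k]
    method <- plan$steps[[k]]
    if (plan$nesting && k > 1) {
      strata <- interaction(samples[covs[seq_len(k - 1)]], drop = TRUE)
    } else {
      strata <- factor(rep("all", nrow(samples)))
    }
    for (s in levels(strata)) {
      idx <- which(strata == s)
      grp <- samples[[cov]][idx]
      sizes <- table(grp)
      if (any(sizes < 2)) {
        stop(sprintf("stratum '%s' has level(s) of '%s' with fewer than 2 samples: %s",
                     s, cov, paste(names(sizes)[sizes < 2], collapse = ", ")), call. = FALSE)
      }
      sub <- out[, idx, drop = FALSE]
      out[, idx] <- switch(method,
        zscore = zscore_within(sub, grp),
        combat = combat_eb(sub, grp)
      )
    }
  }
  attr(out, "plan") <- plan
  out
}

# Balanced sequential ANOVA fallback for one PC score vector: per-factor
# between-level SS as a share of the total SS.
anova_fractions <- function(score, samples, factors) {
  ctr <- score - mean(score)
  ss_total <- sum(ctr^2)
  ss <- stats::setNames(numeric(length(factors)), factors)
  for (f in factors) {
    g <- as.factor(samples[[f]])
    mg <- tapply(ctr, g, mean)
    ss[f] <- sum(table(g) * mg^2)
  }
  resid <- max(0, ss_total - sum(ss))
  c(ss, residual = resid) / (sum(ss) + resid)
}

#' Principal variance component analysis
#'
#' Principal components of the gene-standardized matrix are retained up to a
#' cumulative-variance threshold (at least two). For every retained PC a
#' random-intercept model with one random effect per design factor (main
#' effects only) is fitted; per-PC variance-component proportions are then
#' averaged with eigenvalue weights and normalized to sum to one.
#'
#' @param matrix numeric genes x samples matrix.
#' @param samples sample table containing `factors`.
#' @param factors character vector of design factors to model.
#' @param cum_var_threshold retain PCs up to this cumulative variance share.
#' @return Object of class `pvca_result` with elements `fractions` (named,
#'   includes `residual`, sums to 1), `pcs_used`, `cum_var_threshold`,
#'   `eigenvalues`.
#' @export
pvca <- function(matrix, samples, factors, cum_var_threshold = 0.6) {
  assert_expression_matrix(matrix)
  stopifnot(cum_var_threshold > 0, cum_var_threshold <= 1)
  missing <- setdiff(factors, names(samples))
  if (length(missing)) stop(sprintf("factor(s) absent from sample table: %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  usable <- factors[vapply(factors, function(f) nlevels(as.factor(samples[[f]])) >= 2, logical(1))]
  dropped <- setdiff(factors, usable)
  if (length(dropped)) {
    warning(sprintf("factor(s) with a single level get fraction 0: %s", paste(dropped, collapse = ", ")))
  }
  Z <- standardize_rows(matrix)
  Z <- Z[rowSums(Z != 0) > 0, , drop = FALSE]
  sv <- svd(t(Z), nu = min(ncol(Z), nrow(Z), 200), nv = 0)
  ev <- sv$d^2
  ev_share <- ev / sum(ev)
  m <- max(2, which(cumsum(ev_share) >= cum_var_threshold)[1])
  m <- min(m, ncol(sv$u))
  scores <- sv$u[, seq_len(m), drop = FALSE] %*% diag(sv$d[seq_len(m)], m)

  fac_df <- as.data.frame(lapply(samples[usable], as.factor))
  per_pc <- matrix(0, m, length(usable) + 1,
                   dimnames = list(NULL, c(usable, "residual")))
  if (length(usable)) {
    form <- stats::as.formula(paste("score ~", paste(sprintf("(1|%s)", usable), collapse = " + ")))
    for (j in seq_len(m)) {
      dat <- cbind(score = scores[, j], fac_df)
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(form, data = dat,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore"))
        )),
        error = function(e) NULL
      )
      comp <- NULL
      if (!is.null(fit)) {
        vc <- as.data.frame(lme4::VarCorr(fit))
        comp <- stats::setNames(vc$vcov, vc$grp)
        # a (near-)zero residual makes the mixed-model likelihood degenerate
        # and the component split arbitrary; the balanced ANOVA is exact there
        if (comp[["Residual"]] <= 1e-8 * sum(comp)) comp <- NULL
      }
      if (is.null(comp)) {
        per_pc[j, ] <- anova_fractions(scores[, j], samples, usable)
      } else {
        vals <- c(pmax(comp[usable], 0), residual = max(0, unname(comp["Residual"])))
        per_pc[j, ] <- vals / sum(vals)
      }
    }
  } else {
    per_pc[, "residual"] <- 1
  }
  w <- ev[seq_len(m)] / sum(ev[seq_len(m)])
  fr <- pmax(colSums(per_pc * w), 0)  # pmax(x, 0): keep names
  fr <- fr / sum(fr)
  fractions <- stats::setNames(numeric(length(factors) + 1), c(factors, "residual"))
  fractions[names(fr)] <- fr
  structure(list(fractions = fractions, pcs_used = m,
                 cum_var_threshold = cum_var_threshold,
                 eigenvalues = ev[seq_len(m)]),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA over %d PCs (cum. var threshold %.2f):\n", x$pcs_used, x$cum_var_threshold))
  print(round(x$fractions, 4))
  invisible(x)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Exhaustive correction-order search
#'
#' Enumerates every permutation of the covariates crossed with every per-step
#' method assignment, applies each plan, and ranks plans by the PVCA age
#' variance fraction of the corrected matrix (descending). Ties are broken by
#' fewer ComBat steps, then lexicographically by plan string.
#'
#' @param matrix numeric genes x samples matrix.
#' @param samples sample table.
#' @param covariates covariates to correct (at most 4; exhaustive search).
#' @param methods correction methods to consider per step.
#' @param age_factor name of the age column used as the selection criterion.
#' @param cum_var_threshold passed to [pvca()].
#' @param nesting passed to [correction_plan()].
#' @return Object of class `order_search`: a ranking data.frame plus the
#'   evaluated plans and their PVCA results, best first.
#' @export
search_order <- function(matrix, samples, covariates,
                         methods = c("combat", "zscore"),
                         age_factor = "age", cum_var_threshold = 0.6,
                         nesting = TRUE) {
  if (length(covariates) > 4) stop("exhaustive search supports at most 4 covariates", call. = FALSE)
  methods <- match.arg(methods, c("combat", "zscore"), several.ok = TRUE)
  plans <- list()
  for (perm in all_permutations(covariates)) {
    grid <- expand.grid(rep(list(methods), length(perm)), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      steps <- stats::setNames(as.character(grid[i, ]), perm)
      plans[[length(plans) + 1]] <- correction_plan(steps, nesting = nesting)
    }
  }
  pvca_factors <- unique(c(covariates, age_factor))
  results <- vector("list", length(plans))
  age_frac <- numeric(length(plans))
  n_combat <- integer(length(plans))
  labels <- character(length(plans))
  for (i in seq_along(plans)) {
    corrected <- apply_plan(matrix, samples, plans[[i]])
    res <- suppressWarnings(pvca(corrected, samples, pvca_factors, cum_var_threshold))
    results[[i]] <- res
    age_frac[i] <- res$fractions[[age_factor]]
    n_combat[i] <- sum(plans[[i]]$steps == "combat")
    labels[i] <- plan_string(plans[[i]])
  }
  ord <- order(-age_frac, n_combat, labels)
  ranking <- data.frame(plan = labels[ord], age_fraction = age_frac[ord],
                        n_combat = n_combat[ord], stringsAsFactors = FALSE)
  structure(list(ranking = ranking, plans = plans[ord], pvca = results[ord]),
            class = "order_search")
}

#' @export
print.order_search <- function(x, ...) {
  cat(sprintf("correction-order search: %d plans evaluated\n", nrow(x$ranking)))
  print(utils::head(x$ranking, 10))
  invisible(x)
}
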