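#' Scale-free topology fit index
#'
#' Bins the connectivity distribution into equal-width bins and regresses
#' log10 bin frequency on log10 mean bin connectivity; the fit index is the
#' regression R-squared signed by minus the slope sign, so a decaying
#' power-law degree distribution scores close to +1.
#'
#' @param connectivities per-node connectivity values.
#' @param n_bins number of equal-width bins.
#' @return Signed R-squared in \[-1, 1\].
#' @export
scale_free_fit <- function(connectivities, n_bins = 10) {
  k <- connectivities[is.finite(connectivities)]
  if (length(unique(k)) < 2) stop("all connectivities equal: fit index undefined", call. = FALSE)
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length)
  keep <- !is.na(mean_k) & mean_k > 0 & !is.na(freq)
  if (sum(keep) < 2) stop("fewer than two usable connectivity bins", call. = FALSE)
  lx <- log10(mean_k[keep])
  ly <- log10(freq[keep] / length(k))
  fit <- stats::lm(ly ~ lx)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  slope <- stats::coef(fit)[["lx"]]
  r2 * (-sign(slope))
}

#' Choose the soft-threshold power from candidate fits
#'
#' The chosen power is the smallest whose fit exceeds the threshold; when
#' none does, the power with the maximal fit is returned and flagged.
#'
#' @param powers candidate powers.
#' @param fits scale-free fit indices, one per power.
#' @param threshold required fit index.
#' @return List with `power` and logical `reached_threshold`.
#' @export
select_power <- function(powers, fits, threshold = 0.94) {
  stopifnot(length(powers) == length(fits))
  ok <- which(!is.na(fits) & fits > threshold)
  if (length(ok)) list(power = powers[min(ok)], reached_threshold = TRUE)
  else list(power = powers[which.max(fits)], reached_threshold = FALSE)
}

#' Soft-threshold power scan for an unsigned co-expression network
#'
#' For each candidate power beta the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` is built and the per-node connectivity
#' `k_i = sum_j a_ij` scored for scale-free topology.
#'
#' @param X genes x samples matrix.
#' @param powers candidate integer powers.
#' @param threshold scale-free fit index required.
#' @param n_bins passed to [scale_free_fit()].
#' @return Object of class `soft_power_scan`: per-power fit and mean
#'   connectivity, the chosen power and whether the threshold was reached.
#' @export
pick_power <- function(X, powers = 1:12, threshold = 0.94, n_bins = 10) {
  assert_expression_matrix(X)
  keep <- apply(X, 1, stats::sd) > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d constant gene row(s)", sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X) < 30) warning("fewer than 30 genes: the scale-free fit is unstable")
  ac <- abs(stats::cor(t(X)))
  diag(ac) <- 0
  fits <- numeric(length(powers))
  mean_k <- numeric(length(powers))
  for (i in seq_along(powers)) {
    k <- rowSums(ac^powers[i])
    mean_k[i] <- mean(k)
    fits[i] <- tryCatch(scale_free_fit(k, n_bins), error = function(e) NA_real_)
  }
  sel <- select_power(powers, fits, threshold)
  structure(list(powers = powers, fit_index = fits, mean_connectivity = mean_k,
                 chosen_power = sel$power, reached_threshold = sel$reached_threshold,
                 fit_threshold = threshold),
            class = "soft_power_scan")
}

#' @export
print.soft_power_scan <- function(x, ...) {
  cat(sprintf("soft-power scan: chosen beta = %d (fit > %.2f: %s)\n",
              x$chosen_power, x$fit_threshold, x$reached_threshold))
  print(data.frame(power = x$powers, fit = round(x$fit_index, 3),
                   mean_k = round(x$mean_connectivity, 2)))
  invisible(x)
}

# Unsigned topological overlap matrix from an adjacency matrix (zero diagonal).
tom_similarity <- function(adj) {
  L <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

# First principal component of the row-standardized module submatrix, scaled
# to unit variance, with the sign aligned to the module's mean profile.
module_eigengene <- function(Xm) {
  Z <- standardize_rows(Xm)
  sv <- svd(Z, nu = 0, nv = 1)
  me <- sv$v[, 1]
  me <- me / stats::sd(me)
  if (stats::cor(me, colMeans(Z)) < 0) me <- -me
  var_share <- sv$d[1]^2 / sum(sv$d^2)
  list(me = me, var_share = var_share)
}

#' Detect unsigned co-expression modules
#'
#' Builds the unsigned adjacency at the given power, converts it to a
#' topological-overlap dissimilarity, clusters genes by average-linkage
#' hierarchical clustering and cuts the tree at a fixed height. Clusters
#' smaller than `min_module_size` are pooled into `"grey"`. Each module is
#' summarized by its eigengene (first principal component of the module's
#' standardized expression, unit variance, sign aligned with the module mean
#' profile) and its mean signed intra-module pairwise correlation.
#'
#' @param X genes x samples matrix.
#' @param beta soft-threshold power (see [pick_power()]).
#' @param min_module_size smallest cluster kept as a module.
#' @param cut_height static tree-cut height; when `NULL`, heights are scanned
#'   downward from 0.99 of the maximal merge height until at least two
#'   modules emerge.
#' @return Object of class `module_set`: `membership` (gene -> module label),
#'   `eigengenes` (samples x modules matrix), `sizes`, `intra_cor`,
#'   `me_var_share`, `cut_height`, `beta`.
#' @export
detect_modules <- function(X, beta, min_module_size = 10, cut_height = NULL) {
  assert_expression_matrix(X)
  genes <- rownames(X)
  if (nrow(X) < min_module_size) {
    warning("fewer genes than `min_module_size`: all genes assigned to grey")
    membership <- stats::setNames(rep("grey", nrow(X)), genes)
    return(structure(list(membership = membership, eigengenes = NULL,
                          sizes = c(grey = nrow(X)), intra_cor = NULL,
                          me_var_share = NULL, cut_height = NA_real_, beta = beta),
                     class = "module_set"))
  }
  C <- stats::cor(t(X))
  C[is.na(C)] <- 0
  adj <- abs(C)^beta
  diag(adj) <- 0
  diss <- 1 - tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  assign_at <- function(h) {
    cl <- stats::cutree(hc, h = h)
    tab <- table(cl)
    keep <- names(tab)[tab >= min_module_size]
    lab <- rep("grey", length(cl))
    if (length(keep)) {
      ord <- keep[order(-tab[keep])]
      for (i in seq_along(ord)) lab[cl == ord[i]] <- paste0("M", i)
    }
    stats::setNames(lab, genes)
  }
  max_h <- max(hc$height)
  if (is.null(cut_height)) {
    # scan from just under the top merge through the gaps between successive
    # merge heights until at least two sufficiently large modules emerge;
    # co-expression trees are often nearly flat, so fixed height fractions
    # would miss the split
    hs <- sort(unique(hc$height), decreasing = TRUE)
    candidates <- unique(c(0.99 * max_h,
                           (utils::head(hs, -1) + utils::tail(hs, -1)) / 2))
    membership <- NULL
    for (h in candidates) {
      cand <- assign_at(h)
      if (is.null(membership)) { membership <- cand; cut_height <- h }
      if (length(setdiff(unique(cand), "grey")) >= 2) {
        membership <- cand
        cut_height <- h
        break
      }
    }
  } else {
    membership <- assign_at(cut_height)
  }
  mods <- setdiff(unique(membership), "grey")
  mods <- mods[order(as.integer(sub("M", "", mods)))]
  all_mods <- c(mods, if ("grey" %in% membership) "grey")
  eig <- matrix(NA_real_, ncol(X), length(all_mods),
                dimnames = list(colnames(X), all_mods))
  var_share <- stats::setNames(rep(NA_real_, length(all_mods)), all_mods)
  intra <- stats::setNames(rep(NA_real_, length(all_mods)), all_mods)
  for (mname in all_mods) {
    members <- names(membership)[membership == mname]
    if (length(members) >= 2) {
      em <- module_eigengene(X[members, , drop = FALSE])
      eig[, mname] <- em$me
      var_share[mname] <- em$var_share
      cm <- C[members, members]
      intra[mname] <- mean(cm[upper.tri(cm)])
    }
  }
  structure(list(membership = membership, eigengenes = eig,
                 sizes = table(membership), intra_cor = intra,
                 me_var_share = var_share, cut_height = cut_height, beta = beta),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (beta = %s, cut height %.3f)\n",
              length(setdiff(names(x$sizes), "grey")), format(x$beta), x$cut_height))
  print(x$sizes)
  invisible(x)
}

#' Median age-profile summaries
#'
#' Per age level, the median value across all samples of that age (organs,
#' strains and sexes pooled). Values are expected on the harmonized z-scale.
#' In group mode, member genes' summaries are averaged.
#'
#' @param X genes x samples matrix (z-scale).
#' @param ages numeric age per sample.
#' @param groups optional gene -> group labels; when given, per-group mean
#'   summaries are returned.
#' @return Matrix with one row per gene (or group) and one column per age
#'   level (increasing).
#' @export
profile_summary <- function(X, ages, groups = NULL) {
  assert_expression_matrix(X)
  stopifnot(length(ages) == ncol(X))
  levels_num <- sort(unique(ages))
  out <- sapply(levels_num, function(a) {
    apply(X[, ages == a, drop = FALSE], 1, stats::median)
  })
  out <- matrix(out, nrow = nrow(X), dimnames = list(rownames(X), levels_num))
  if (is.null(groups)) return(out)
  stopifnot(!is.null(names(groups)))
  glev <- unique(groups)
  gsum <- t(sapply(glev, function(g) colMeans(out[names(groups)[groups == g], , drop = FALSE])))
  rownames(gsum) <- glev
  gsum
}

#' Split a module into antiparallel subgroups
#'
#' Genes of one module are clustered by average-linkage hierarchical
#' clustering on the correlation distance of their age-profile summaries
#' (1 - Pearson correlation of per-age medians) and the dendrogram is cut at
#' a fixed distance threshold. The first and second most frequent subgroups
#' are summarized and flagged antiparallel when their mean profiles are
#' strongly anticorrelated.
#'
#' @param X_module genes x samples matrix of module members (z-scale).
#' @param ages numeric age per sample.
#' @param distance_threshold tree-cut height on the correlation distance.
#' @param antiparallel_cor flag threshold: subgroup profile correlation below
#'   this marks the module antiparallel.
#' @return Object of class `subgroup_split`: `subgroups` (gene -> label),
#'   `profiles` (the two largest subgroups' mean age profiles), their
#'   `sizes`, `profile_cor`, logical `antiparallel` and logical `split`.
#' @export
split_antiparallel <- function(X_module, ages, distance_threshold = 0.22,
                               antiparallel_cor = -0.5) {
  assert_expression_matrix(X_module)
  if (nrow(X_module) < 4) stop("module must contain at least 4 genes", call. = FALSE)
  prof <- profile_summary(X_module, ages)
  pc <- suppressWarnings(stats::cor(t(prof)))
  pc[is.na(pc)] <- 0
  d <- 1 - pc
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = distance_threshold)
  tab <- sort(table(cl), decreasing = TRUE)
  subgroups <- stats::setNames(paste0("S", match(cl, names(tab))), rownames(X_module))
  if (length(tab) < 2) {
    return(structure(list(subgroups = subgroups,
                          profiles = list(S1 = colMeans(prof)),
                          sizes = c(S1 = unname(tab[1])),
                          profile_cor = NA_real_, antiparallel = FALSE,
                          split = FALSE, distance_threshold = distance_threshold),
                     class = "subgroup_split"))
  }
  g1 <- rownames(X_module)[cl == names(tab)[1]]
  g2 <- rownames(X_module)[cl == names(tab)[2]]
  p1 <- colMeans(prof[g1, , drop = FALSE])
  p2 <- colMeans(prof[g2, , drop = FALSE])
  pcor <- suppressWarnings(stats::cor(p1, p2))
  structure(list(subgroups = subgroups, profiles = list(S1 = p1, S2 = p2),
                 sizes = c(S1 = length(g1), S2 = length(g2)),
                 profile_cor = pcor,
                 antiparallel = is.finite(pcor) && pcor < antiparallel_cor,
                 split = TRUE, distance_threshold = distance_threshold),
            class = "subgroup_split")
}

#' @export
print.subgroup_split <- function(x, ...) {
  if (!x$split) {
    cat("subgroup_split: single subgroup (no split at threshold)\n")
  } else {
    cat(sprintf("subgroup_split: sizes %d/%d, profile correlation %.3f, antiparallel: %s\n",
                x$sizes[1], x$sizes[2], x$profile_cor, x$antiparallel))
  }
  invisible(x)
}
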