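#' Describe a factorial aging-cohort design
#'
#' The default mirrors a multi-organ mouse aging cohort: seven organs, two
#' strains, both sexes, five sampling ages across the lifespan and five
#' biological replicates per design cell (700 samples in total).
#'
#' @param organs character vector of organ labels.
#' @param strains character vector of strain labels.
#' @param sexes character vector of sex labels.
#' @param ages strictly increasing numeric vector of sampling ages in months.
#' @param replicates_per_cell positive integer, replicates per design cell.
#' @param seed integer master seed for cohort generation.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(organs = c("brain", "heart", "liver", "kidney", "colon", "muscle", "aorta"),
                          strains = c("B6", "D2"),
                          sexes = c("F", "M"),
                          ages = c(3, 6, 12, 18, 24),
                          replicates_per_cell = 5,
                          seed = 1L) {
  stopifnot(length(organs) >= 1, length(strains) >= 1, length(sexes) >= 1)
  if (length(ages) < 2 || any(diff(ages) <= 0)) {
    stop("`ages` must be a strictly increasing vector with at least two values", call. = FALSE)
  }
  if (replicates_per_cell < 1) stop("`replicates_per_cell` must be a positive integer", call. = FALSE)
  structure(
    list(organs = organs, strains = strains, sexes = sexes, ages = ages,
         replicates_per_cell = as.integer(replicates_per_cell), seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  n <- length(x$organs) * length(x$strains) * length(x$sexes) * length(x$ages) * x$replicates_per_cell
  cat(sprintf("cohort_design: %d organs x %d strains x %d sexes x %d ages x %d replicates = %d samples\n",
              length(x$organs), length(x$strains), length(x$sexes), length(x$ages),
              x$replicates_per_cell, n))
  invisible(x)
}

n_samples <- function(design) {
  length(design$organs) * length(design$strains) * length(design$sexes) *
    length(design$ages) * design$replicates_per_cell
}

ARCHETYPES <- c("up", "down", "inflect6", "peak_adolescent", "null")

#' Canonical age-profile archetypes
#'
#' Deterministic zero-mean, unit-max-abs age trajectories used to plant age
#' signal in synthetic cohorts. The archetypes summarize the dominant
#' trajectory shapes of collective organ aging: monotone increase or decrease,
#' a turn-around after the second sampling age (around the sixth month of
#' life, when maturation is presumed complete), and a sharp adolescent peak
#' followed by a decline that has largely run its course by midlife.
#'
#' @param archetype one of `"up"`, `"down"`, `"inflect6"`, `"peak_adolescent"`,
#'   `"null"`.
#' @param ages strictly increasing numeric vector of at least two ages.
#' @return Numeric vector, one value per age; zero mean; maximum absolute
#'   value 1 (except `"null"`, which is all zeros).
#' @export
archetype_profile <- function(archetype, ages) {
  if (length(ages) < 2 || any(diff(ages) <= 0)) {
    stop("`ages` must be strictly increasing with at least two values", call. = FALSE)
  }
  if (length(archetype) != 1 || !archetype %in% ARCHETYPES) {
    stop(sprintf("unknown archetype label '%s'; known: %s",
                 as.character(archetype)[1], paste(ARCHETYPES, collapse = ", ")),
         call. = FALSE)
  }
  k <- length(ages)
  raw <- switch(archetype,
    "null" = return(rep(0, k)),
    "up" = ages - mean(ages),
    "down" = -(ages - mean(ages)),
    # V-shape: decline to the second age, then rise -- the slope changes sign
    # after the second sampling age.
    "inflect6" = {
      v <- numeric(k)
      v[1:2] <- c(1, -1)
      if (k > 2) v[3:k] <- -1 + 2 * seq_len(k - 2) / (k - 2)
      v
    },
    # Sharp peak at the second age, steep primary decline to the third age,
    # then a shallow late-life drift.
    "peak_adolescent" = {
      v <- numeric(k)
      v[1] <- 0.2
      v[2] <- 1
      if (k > 2) v[3:k] <- -0.5 - 0.1 * (seq_len(k - 2) - 1) / max(1, k - 3)
      v
    }
  )
  raw <- raw - mean(raw)
  raw / max(abs(raw))
}

#' Declare the planted statistical structure of a synthetic cohort
#'
#' @param n_genes number of genes to simulate.
#' @param variance_fractions named nonnegative vector of target variance
#'   fractions for design factors (any of `organ`, `strain`, `sex`, `age`);
#'   must sum to at most 1. The remainder is residual (noise) variance. The
#'   default reproduces the dominance hierarchy typical of a multi-organ
#'   cohort: organ by far the largest, then residual, strain, sex, with age
#'   the smallest contributor.
#' @param archetype_assignments named character vector mapping gene ids to
#'   archetype labels (see [archetype_profile()]); genes not named are "null".
#' @param antiparallel_pairs list of `list(A = <gene ids>, B = <gene ids>)`;
#'   genes in `B` receive the sign-flipped age profile of their archetype.
#' @param regulators list of `list(regulator = <gene>, targets = <genes>,
#'   effect = <size>)`; each target receives a nonlinear (linear-plus-
#'   threshold) function of its regulator's realized values, so the planted
#'   dependence is recoverable by forest importance but asymmetric: the
#'   regulator itself is driven only by design factors and noise.
#' @param noise_sd residual noise standard deviation; defaults to
#'   `sqrt(1 - sum(variance_fractions))` so realized fractions match targets.
#' @param archetype_amplitude amplitude of the planted age trajectories on
#'   the z-scale.
#' @param gene_prefix prefix for generated gene identifiers.
#' @return Object of class `planted_structure`.
#' @export
planted_structure <- function(n_genes,
                              variance_fractions = c(organ = 0.873, strain = 0.0274, sex = 0.0031),
                              archetype_assignments = character(),
                              antiparallel_pairs = list(),
                              regulators = list(),
                              noise_sd = NULL,
                              archetype_amplitude = 0.2,
                              gene_prefix = "g") {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1) stop("`n_genes` must be positive", call. = FALSE)
  if (length(variance_fractions)) {
    if (is.null(names(variance_fractions)) || any(!nzchar(names(variance_fractions)))) {
      stop("`variance_fractions` must be a named vector", call. = FALSE)
    }
    if (any(variance_fractions < 0)) stop("variance fractions must be nonnegative", call. = FALSE)
    if (sum(variance_fractions) > 1 + 1e-12) {
      stop("variance fractions sum to more than 1; no residual variance left", call. = FALSE)
    }
  }
  genes <- sprintf("%s%04d", gene_prefix, seq_len(n_genes))
  if (length(archetype_assignments)) {
    bad <- setdiff(names(archetype_assignments), genes)
    if (length(bad)) stop(sprintf("archetype assignment for unknown gene(s): %s",
                                  paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    unknown <- setdiff(unique(archetype_assignments), ARCHETYPES)
    if (length(unknown)) stop(sprintf("unknown archetype label(s): %s",
                                      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (p in antiparallel_pairs) {
    stopifnot(is.list(p), all(c("A", "B") %in% names(p)))
    if (length(setdiff(c(p$A, p$B), genes))) stop("antiparallel pair names unknown genes", call. = FALSE)
  }
  for (r in regulators) {
    stopifnot(is.list(r), all(c("regulator", "targets", "effect") %in% names(r)))
    if (r$regulator %in% r$targets) stop("a regulator may not target itself", call. = FALSE)
    if (length(setdiff(c(r$regulator, r$targets), genes))) stop("regulator entry names unknown genes", call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- sqrt(max(0, 1 - sum(variance_fractions)))
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  structure(
    list(n_genes = n_genes, genes = genes,
         variance_fractions = variance_fractions,
         archetype_assignments = archetype_assignments,
         antiparallel_pairs = antiparallel_pairs,
         regulators = regulators,
         noise_sd = noise_sd,
         archetype_amplitude = archetype_amplitude),
    class = "planted_structure"
  )
}

#' Default planted structure for pipeline exercises
#'
#' Assigns roughly a quarter of genes to the four informative age archetypes
#' (with one antiparallel twin pair inside the turn-around archetype), plants
#' two fan-out regulators among the null genes, and uses the organ-dominant
#' variance hierarchy.
#'
#' @inheritParams planted_structure
#' @param ... passed on to [planted_structure()].
#' @export
default_planted_structure <- function(n_genes = 300, ...) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_arch <- max(4, floor(n_genes * 0.08))
  n_turn <- max(4, floor(n_genes * 0.04))
  idx <- 0
  take <- function(k) { out <- genes[idx + seq_len(k)]; idx <<- idx + k; out }
  up <- take(n_arch); down <- take(n_arch)
  inflect <- take(n_turn); peak <- take(n_turn)
  assign <- c(stats::setNames(rep("up", n_arch), up),
              stats::setNames(rep("down", n_arch), down),
              stats::setNames(rep("inflect6", n_turn), inflect),
              stats::setNames(rep("peak_adolescent", n_turn), peak))
  half <- floor(n_turn / 2)
  pairs <- list(list(A = inflect[seq_len(half)], B = inflect[(half + 1):n_turn]))
  nulls <- genes[(idx + 1):n_genes]
  regulators <- list(
    list(regulator = nulls[1], targets = nulls[2:9], effect = 0.8),
    list(regulator = nulls[10], targets = nulls[11:18], effect = 0.8)
  )
  planted_structure(n_genes, archetype_assignments = assign,
                    antiparallel_pairs = pairs, regulators = regulators, ...)
}

# Sign (+1/-1) of each gene's age profile: -1 for members of a pair's B set.
profile_signs <- function(structure) {
  s <- stats::setNames(rep(1, structure$n_genes), structure$genes)
  for (p in structure$antiparallel_pairs) s[p$B] <- -1
  s
}

#' Generate a synthetic cohort
#'
#' Gene values are the sum of (i) per-gene random intercepts for each design
#' factor, drawn once per gene-by-level with scale `sqrt(target fraction)` so
#' realized variance fractions approach their targets as the gene count
#' grows; (ii) the gene's planted age archetype (sign-flipped for antiparallel
#' twins); (iii) for regulator targets, a linear-plus-threshold function of
#' the regulator's realized values; and (iv) Gaussian noise. Values live on
#' the z-like generative scale; `scale = "fpkm"` exponentiates to a
#' nonnegative FPKM-like scale (recorded in the result).
#'
#' @param design a [cohort_design()].
#' @param structure a [planted_structure()].
#' @param scale `"z"` (default) or `"fpkm"`.
#' @return Object of class `synthetic_cohort`: list with `expression`
#'   (genes x samples matrix), `samples` (data.frame of factors) and `truth`
#'   (the planted structure plus per-sample regulator inputs).
#' @export
generate_cohort <- function(design, structure, scale = c("z", "fpkm")) {
  stopifnot(inherits(design, "cohort_design"), inherits(structure, "planted_structure"))
  scale <- match.arg(scale)
  samples <- expand.grid(
    replicate = seq_len(design$replicates_per_cell),
    age = design$ages,
    sex = design$sexes,
    strain = design$strains,
    organ = design$organs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("organ", "strain", "sex", "age", "replicate")]
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  samples <- samples[, c("sample_id", "organ", "strain", "sex", "age", "replicate")]
  n <- nrow(samples)
  G <- structure$n_genes
  genes <- structure$genes

  factor_levels <- list(organ = design$organs, strain = design$strains,
                        sex = design$sexes, age = as.character(design$ages))
  sample_factors <- list(organ = samples$organ, strain = samples$strain,
                         sex = samples$sex, age = as.character(samples$age))

  with_seed(design$seed, {
    E <- matrix(0, G, n, dimnames = list(genes, samples$sample_id))
    for (f in names(structure$variance_fractions)) {
      frac <- structure$variance_fractions[[f]]
      if (frac <= 0) next
      if (!f %in% names(factor_levels)) {
        stop(sprintf("variance fraction declared for unknown factor '%s'", f), call. = FALSE)
      }
      levs <- factor_levels[[f]]
      eff <- matrix(stats::rnorm(G * length(levs), sd = sqrt(frac)), G, length(levs))
      E <- E + eff[, match(sample_factors[[f]], levs), drop = FALSE]
    }
    signs <- profile_signs(structure)
    if (length(structure$archetype_assignments)) {
      age_idx <- match(samples$age, design$ages)
      for (arch in setdiff(unique(structure$archetype_assignments), "null")) {
        gs <- names(structure$archetype_assignments)[structure$archetype_assignments == arch]
        prof <- archetype_profile(arch, design$ages)
        E[gs, ] <- E[gs, , drop = FALSE] +
          structure$archetype_amplitude * outer(signs[gs], prof[age_idx])
      }
    }
    if (structure$noise_sd > 0) {
      E <- E + matrix(stats::rnorm(G * n, sd = structure$noise_sd), G, n)
    }
    # Regulator contributions come last: the regulator row itself is already
    # final (factors + noise only), so the planted dependence is one-way.
    regulator_inputs <- list()
    for (r in structure$regulators) {
      rv <- E[r$regulator, ]
      z <- (rv - mean(rv)) / stats::sd(rv)
      contrib <- r$effect * (0.6 * z + pmax(z - 0.5, 0))
      E[r$targets, ] <- E[r$targets, , drop = FALSE] +
        matrix(contrib, length(r$targets), n, byrow = TRUE)
      regulator_inputs[[r$regulator]] <- contrib
    }
    if (scale == "fpkm") E <- 2^(E + 4)
    structure(
      list(expression = E, samples = samples,
           truth = structure, scale = scale, seed = design$seed, design = design,
           regulator_inputs = regulator_inputs),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (%s scale, seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$scale, x$seed))
  invisible(x)
}

#' Audit realized per-factor variance fractions of a cohort
#'
#' Direct balanced-design decomposition: per gene, the between-level sum of
#' squares of each factor; fractions are pooled across genes. In the full
#' factorial design the factors are orthogonal, so these are the realized
#' analogues of the planted target fractions.
#'
#' @param cohort a `synthetic_cohort` (or any genes-x-samples matrix plus
#'   sample table via `expression`/`samples`).
#' @param factors design factors to decompose.
#' @return Named vector of fractions (factors plus `residual`) summing to 1.
#' @export
audit_variance_fractions <- function(cohort, factors = c("organ", "strain", "sex", "age")) {
  E <- cohort$expression
  samples <- cohort$samples
  factors <- intersect(factors, names(samples))
  ctr <- E - rowMeans(E)
  ss_total <- sum(ctr^2)
  ss <- stats::setNames(numeric(length(factors)), factors)
  for (f in factors) {
    g <- as.factor(samples[[f]])
    if (nlevels(g) < 2) next
    # per-gene between-level SS, summed over genes
    counts <- as.vector(table(g))
    means <- ctr %*% stats::model.matrix(~ g - 1) %*% diag(1 / counts, nlevels(g))
    ss[f] <- sum(sweep(means^2, 2, counts, "*"))
  }
  resid <- max(0, ss_total - sum(ss))
  out <- c(ss, residual = resid) / (sum(ss) + resid)
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `expression.tsv` (first column `gene_id`), `samples.tsv` and
#' `truth.json` into `dir`.
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  write_expression_tsv(cohort$expression, expr_path)
  samp_path <- file.path(dir, "samples.tsv")
  utils::write.table(cohort$samples, samp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- cohort$truth
  jsonlite::write_json(
    list(n_genes = truth$n_genes,
         variance_fractions = as.list(truth$variance_fractions),
         archetype_assignments = as.list(truth$archetype_assignments),
         antiparallel_pairs = truth$antiparallel_pairs,
         regulators = truth$regulators,
         noise_sd = truth$noise_sd,
         archetype_amplitude = truth$archetype_amplitude,
         scale = cohort$scale, seed = cohort$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(expr_path, samp_path, truth_path))
}
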