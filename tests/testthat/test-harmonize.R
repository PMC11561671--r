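test_that("zscore_within standardizes per group with the population-sd convention", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  z <- zscore_within(m, rep("all", 3))
  expect_equal(unname(z["gA", ]), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # constant gene maps to zero, not NaN
  expect_identical(unname(z["gB", ]), c(0, 0, 0))
  # two groups with different means: per-group means all zero afterwards
  m2 <- noise_expression(5, 8, seed = 2) + 3
  groups <- rep(c("a", "b"), each = 4)
  z2 <- zscore_within(m2, groups)
  expect_equal(max(abs(rowMeans(z2[, groups == "a"]))), 0, tolerance = 1e-12)
  expect_equal(max(abs(rowMeans(z2[, groups == "b"]))), 0, tolerance = 1e-12)
  expect_error(zscore_within(m2, c(rep("a", 7), "lonely")), "lonely")
})

test_that("combat_eb removes planted batch offsets and respects edge cases", {
  m <- noise_expression(40, 30, seed = 3)
  batch <- rep(c("b1", "b2"), c(15, 15))
  # single batch: identity with a warning
  expect_warning(out1 <- combat_eb(m, rep("b1", 30)), "single batch")
  expect_identical(out1, m)
  expect_error(combat_eb(m, c(rep("b1", 29), "b2")), "fewer than 2")
  # identical distributions: adjustment is small
  adj <- combat_eb(m, batch)
  expect_identical(dim(adj), dim(m))
  expect_lt(mean(abs(adj - m)), 0.35)
  # planted offset delta = 2: between-batch mean gap shrinks by > 10x
  delta <- 2
  m_off <- m
  m_off[, batch == "b2"] <- m_off[, batch == "b2"] + delta
  corr <- combat_eb(m_off, batch)
  gap_before <- mean(rowMeans(m_off[, batch == "b2"]) - rowMeans(m_off[, batch == "b1"]))
  gap_after <- mean(abs(rowMeans(corr[, batch == "b2"]) - rowMeans(corr[, batch == "b1"])))
  expect_equal(gap_before, delta, tolerance = 0.3)
  expect_lt(gap_after, 0.1 * delta)
})

test_that("combat_eb and zscore_within are idempotent up to tolerance", {
  m <- noise_expression(30, 24, seed = 6)
  batch <- rep(c("b1", "b2", "b3"), each = 8)
  once <- combat_eb(m, batch)
  twice <- combat_eb(once, batch)
  expect_lt(mean(abs(twice - once)), 0.1)
  z1 <- zscore_within(m, batch)
  expect_equal(zscore_within(z1, batch), z1, tolerance = 1e-9)
})

test_that("correction plans validate and apply in order", {
  expect_error(correction_plan(c(organ = "combat", organ = "zscore")), "twice")
  expect_error(correction_plan(c(organ = "magic")), "unknown correction method")
  expect_error(correction_plan(c(age = "zscore")), "never corrected")

  d <- cohort_design(organs = c("O1", "O2"), strains = c("A", "B"), sexes = "F",
                     ages = c(3, 12, 24), replicates_per_cell = 3, seed = 12)
  co <- generate_cohort(d, planted_structure(30, variance_fractions = c(organ = 0.6, strain = 0.2)))
  # empty plan is the identity
  expect_identical(apply_plan(co$expression, co$samples, correction_plan())[, ],
                   co$expression)
  # a single zscore step equals zscore_within on the covariate grouping
  p1 <- apply_plan(co$expression, co$samples, correction_plan(c(organ = "zscore")))
  expect_equal(p1[, ], zscore_within(co$expression, co$samples$organ), tolerance = 1e-12)
  # nested second step: strata of the first covariate crossed with the second
  p2 <- apply_plan(co$expression, co$samples,
                   correction_plan(c(organ = "zscore", strain = "zscore")))
  cell <- interaction(co$samples$organ, co$samples$strain)
  expect_equal(p2[, ], zscore_within(co$expression, cell), tolerance = 1e-12)
})

test_that("pvca attributes saturated and null variance correctly", {
  # genes that are exact functions of organ level
  d <- cohort_design(organs = paste0("O", 1:4), strains = "A", sexes = "F",
                     ages = c(3, 24), replicates_per_cell = 3, seed = 2)
  st <- planted_structure(60, variance_fractions = c(organ = 1), noise_sd = 0)
  co <- generate_cohort(d, st)
  pv <- suppressWarnings(pvca(co$expression, co$samples, c("organ", "age")))
  expect_gte(pv$fractions[["organ"]], 0.99)
  # pure iid noise: residual dominates
  m <- noise_expression(200, 200, seed = 4)
  samples <- data.frame(sample_id = colnames(m),
                        organ = rep(paste0("O", 1:4), each = 50),
                        age = rep(c(3, 6, 12, 18, 24), 40))
  pv0 <- pvca(m, samples, c("organ", "age"))
  expect_gte(pv0$fractions[["residual"]], 0.9)
  # fractions are a distribution and invariant to sample permutation
  expect_equal(sum(pv0$fractions), 1, tolerance = 1e-9)
  expect_true(all(pv0$fractions >= 0))
  perm <- crossage:::with_seed(5, sample(ncol(m)))
  pv_perm <- pvca(m[, perm], samples[perm, ], c("organ", "age"))
  expect_equal(pv_perm$fractions, pv0$fractions, tolerance = 1e-6)
  # single-level factor: fraction 0 with a warning, not an error
  expect_warning(pv1 <- pvca(m, cbind(samples, sex = "F"), c("organ", "sex")),
                 "single level")
  expect_identical(unname(pv1$fractions[["sex"]]), 0)
})

test_that("correcting a factor does not increase its own PVCA fraction", {
  d <- cohort_design(organs = paste0("O", 1:3), strains = c("A", "B"), sexes = "F",
                     ages = c(3, 12, 24), replicates_per_cell = 3, seed = 17)
  co <- generate_cohort(d, planted_structure(
    120, variance_fractions = c(organ = 0.6, strain = 0.15), archetype_amplitude = 0))
  before <- suppressWarnings(pvca(co$expression, co$samples, c("organ", "strain", "age")))
  after_m <- apply_plan(co$expression, co$samples, correction_plan(c(organ = "combat")))
  after <- suppressWarnings(pvca(after_m, co$samples, c("organ", "strain", "age")))
  expect_lte(after$fractions[["organ"]], before$fractions[["organ"]] + 0.02)
})

test_that("the corrected matrix carries a larger age fraction than the raw one", {
  d <- cohort_design(organs = paste0("O", 1:3), strains = c("A", "B"), sexes = c("F", "M"),
                     ages = c(3, 6, 12, 18, 24), replicates_per_cell = 2, seed = 23)
  genes <- sprintf("g%04d", 1:120)
  st <- planted_structure(
    120, variance_fractions = c(organ = 0.8, strain = 0.08, sex = 0.02),
    archetype_assignments = stats::setNames(rep(c("up", "down"), 15), genes[1:30]),
    archetype_amplitude = 0.5)
  co <- generate_cohort(d, st)
  plan <- correction_plan(c(organ = "combat", strain = "combat", sex = "zscore"))
  corrected <- apply_plan(co$expression, co$samples, plan)
  factors <- c("organ", "strain", "sex", "age")
  raw_age <- suppressWarnings(pvca(co$expression, co$samples, factors))$fractions[["age"]]
  cor_age <- suppressWarnings(pvca(corrected, co$samples, factors))$fractions[["age"]]
  expect_gt(cor_age, raw_age)
})

test_that("search_order enumerates permutations x methods and ranks by age fraction", {
  d <- cohort_design(organs = c("O1", "O2"), strains = c("A", "B"), sexes = c("F", "M"),
                     ages = c(3, 12, 24), replicates_per_cell = 3, seed = 37)
  genes <- sprintf("g%04d", 1:40)
  st <- planted_structure(
    40, variance_fractions = c(organ = 0.5, strain = 0.1, sex = 0.05),
    archetype_assignments = stats::setNames(rep("up", 10), genes[1:10]),
    archetype_amplitude = 0.5)
  co <- generate_cohort(d, st)
  # one covariate, one method: a single plan
  s1 <- search_order(co$expression, co$samples, "organ", methods = "zscore")
  expect_identical(nrow(s1$ranking), 1L)
  # 3 covariates x 2 methods = 3! * 2^3 = 48 plans
  s48 <- search_order(co$expression, co$samples, c("organ", "strain", "sex"))
  expect_identical(nrow(s48$ranking), 48L)
  expect_false(is.unsorted(rev(s48$ranking$age_fraction)))
  expect_error(search_order(co$expression, co$samples,
                            c("a", "b", "c", "d", "e")), "at most 4")
})
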