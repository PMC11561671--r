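toy_table <- function() {
  edge_table(data.frame(
    target  = c("A", "A", "B", "C"),
    feature = c("B", "C", "A", "D"),
    meanImp = c(2, 1.5, 3, 0.5),
    normHits = c(0.9, 0.5, 1, 0.3),
    decision = c("confirmed", "tentative", "confirmed", "tentative"),
    stringsAsFactors = FALSE), universe = c("A", "B", "C", "D"))
}

test_that("edge tables validate their invariants", {
  expect_error(edge_table(data.frame(target = "A", feature = "A", meanImp = 1,
                                     normHits = 1, decision = "confirmed")),
               "self-edges")
  expect_error(edge_table(data.frame(target = c("A", "A"), feature = c("B", "B"),
                                     meanImp = 1, normHits = 1,
                                     decision = "confirmed")), "duplicate")
  expect_error(edge_table(data.frame(target = "A", feature = "B", meanImp = 1,
                                     normHits = 1, decision = "rejected")),
               "rejected")
})

test_that("restriction keeps only edges inside the hit set and retains isolated hits", {
  tab <- toy_table()
  expect_error(restrict_to_hits(tab, character()), "nonempty")
  net <- restrict_to_hits(tab, c("A", "B"))
  expect_setequal(paste(net$edges$target, net$edges$feature),
                  c("A B", "B A"))
  # full universe: identity filter
  net_all <- restrict_to_hits(tab, tab$universe)
  expect_identical(nrow(net_all$edges), 4L)
  # isolated hit kept as node with zero closeness and undefined AAS
  net_iso <- restrict_to_hits(tab, c("A", "B", "Z"))
  expect_true("Z" %in% net_iso$nodes$gene)
  z <- net_iso$nodes[net_iso$nodes$gene == "Z", ]
  expect_identical(z$closeness, 0)
  expect_true(is.na(z$aas_log2))
})

test_that("AAS equals brute-force in/out sums, with documented sentinels", {
  tab <- toy_table()
  net <- restrict_to_hits(tab, tab$universe)
  # inset scenario: in-edges {2, 2, 2}, out-edges {2} -> ratio 3, log2 ~ 1.585
  inset <- edge_table(data.frame(
    target = c("A", "B", "C", "D"), feature = c("X", "X", "X", "X"),
    meanImp = 2, normHits = 1, decision = "confirmed"), universe = LETTERS[1:4])
  inset$edges <- rbind(inset$edges[1:3, ],
                       data.frame(target = "X", feature = "D", meanImp = 2,
                                  normHits = 1, decision = "confirmed"))
  net_inset <- restrict_to_hits(inset, c("A", "B", "C", "D", "X"))
  x <- net_inset$nodes[net_inset$nodes$gene == "X", ]
  expect_equal(x$aas_ratio, 3)
  expect_equal(x$aas_log2, log2(3), tolerance = 1e-12)
  # never-a-target node: "no value" sentinel
  d <- net_inset$nodes[net_inset$nodes$gene == "D", ]
  expect_true(is.na(d$aas_ratio))
  # exhaustive agreement with the brute-force oracle on random toy graphs
  for (s in 1:30) {
    nodes <- LETTERS[1:sample(3:6, 1)]
    e <- random_edge_table(nodes, seed = 900 + s)
    if (is.null(e)) next
    net_s <- restrict_to_hits(edge_table(e, universe = nodes), nodes)
    for (v in nodes) {
      oracle <- brute_aas(e, v)
      got <- aas(net_s, v)
      expect_identical(is.na(got$ratio), is.na(oracle$ratio))
      if (!is.na(oracle$ratio)) {
        expect_equal(got$ratio, oracle$ratio, tolerance = 1e-12)
        expect_equal(got$log2, oracle$log2, tolerance = 1e-12)
      }
    }
  }
  expect_error(aas(net, "nope"), "not in network")
})

test_that("hub scores count in-edges under the decision filter", {
  tab <- edge_table(data.frame(
    target = c("A", "B", "C", "D", "E", "F", "G"),
    feature = c(rep("X", 7)),
    meanImp = 1, normHits = 1,
    decision = c("confirmed", "confirmed", rep("tentative", 5))),
    universe = c(LETTERS[1:7], "X"))
  expect_identical(hub_score(tab, "X"), 7L)
  expect_identical(hub_score(tab, "X", "confirmed"), 2L)
  expect_identical(hub_score(tab, "A"), 0L)
  # sum of unfiltered hub scores equals the edge count
  toy <- toy_table()
  total <- sum(vapply(toy$universe, function(g) hub_score(toy, g), integer(1)))
  expect_identical(total, nrow(toy$edges))
})

test_that("closeness matches closed forms and the brute-force BFS oracle", {
  path <- edge_table(data.frame(target = c("A", "B"), feature = c("B", "C"),
                                meanImp = 1, normHits = 1, decision = "confirmed"),
                     universe = c("A", "B", "C"))
  net <- restrict_to_hits(path, c("A", "B", "C"))
  cl <- closeness_centrality(net)
  expect_equal(unname(cl[c("A", "B", "C")]), c(2 / 3, 1, 2 / 3), tolerance = 1e-12)
  # complete graph: all ones
  nodes <- LETTERS[1:4]
  cmb <- t(combn(nodes, 2))
  complete <- edge_table(data.frame(target = cmb[, 1], feature = cmb[, 2],
                                    meanImp = 1, normHits = 1, decision = "confirmed"),
                         universe = nodes)
  expect_equal(unname(closeness_centrality(restrict_to_hits(complete, nodes))),
               rep(1, 4), tolerance = 1e-12)
  # random graphs up to 50 nodes, permutation-invariant, equal to BFS
  for (s in 1:5) {
    nn <- crossage:::with_seed(700 + s, sample(10:50, 1))
    nodes <- sprintf("n%02d", seq_len(nn))
    e <- random_edge_table(nodes, seed = 800 + s, p_edge = 0.05)
    if (is.null(e)) next
    net_s <- restrict_to_hits(edge_table(e, universe = nodes), nodes)
    got <- closeness_centrality(net_s)
    oracle <- brute_closeness(e, nodes)
    expect_equal(got[nodes], oracle[nodes], tolerance = 1e-12)
    perm <- crossage:::with_seed(s, sample(nodes))
    net_p <- restrict_to_hits(edge_table(e, universe = nodes), perm)
    expect_equal(closeness_centrality(net_p)[nodes], oracle[nodes], tolerance = 1e-12)
  }
})

test_that("quantile thresholds use the linear-interpolation convention", {
  expect_equal(quantile_threshold(0:10, 0.9), 9)
  expect_equal(quantile_threshold(rep(4.2, 10), 0.9), 4.2)
  v <- crossage:::with_seed(1, runif(21))
  expect_equal(quantile_threshold(v, 0.5), median(v))
  expect_error(quantile_threshold(numeric()), "no finite")
})

test_that("feature-hierarchy queries enumerate targets sharing a feature", {
  tab <- edge_table(data.frame(
    target = c("A", "C", "C"), feature = c("B", "B", "D"),
    meanImp = 1, normHits = 1, decision = "tentative"),
    universe = LETTERS[1:4])
  q <- feature_hierarchy_query(tab, "B")
  expect_setequal(q$targets, c("A", "C"))
  expect_identical(q$n_targets, 2L)
  expect_identical(q$n_edges, 2L)
  # disjoint set: empty result
  q0 <- feature_hierarchy_query(tab, "Z")
  expect_identical(q0$n_targets, 0L)
  expect_identical(q0$n_edges, 0L)
  # enlarging the set never decreases the target count
  q2 <- feature_hierarchy_query(tab, c("B", "D"))
  expect_gte(q2$n_targets, q$n_targets)
  expect_error(feature_hierarchy_query(tab, character()), "nonempty")
})

test_that("networks round-trip losslessly through GraphML and TSV", {
  tab <- toy_table()
  net <- restrict_to_hits(tab, tab$universe,
                          origin = c(A = "NVA", B = "both", C = "CVA", D = "NVA"),
                          modules = c(A = "M1", B = "M1", C = "M2", D = "grey"))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- read_network_graphml(f)
  ord <- order(back$nodes$gene)
  expect_equal(back$nodes[ord, ], net$nodes[order(net$nodes$gene), ],
               ignore_attr = TRUE)
  eord <- function(e) e[order(e$target, e$feature), ]
  expect_equal(eord(back$edges), eord(net$edges), ignore_attr = TRUE)
  # TSV edge list is bit-exact
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, ftsv, "tsv")
  back_tab <- read_edges_tsv(ftsv)
  expect_identical(eord(back_tab$edges), eord(net$edges))
  # empty-edge network still exports all nodes
  net_iso <- restrict_to_hits(tab, c("Z1", "Z2"))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net_iso, f2, "graphml")
  expect_setequal(read_network_graphml(f2)$nodes$gene, c("Z1", "Z2"))
})

test_that("crossboruta emits order-invariant edges that conserve strength", {
  co <- regulator_cohort(seed = 91, n_genes = 12, reps = 8)
  Xz <- zscore_within(co$expression, co$samples$organ)
  cfg <- boruta_config(n_trees = 60, max_runs = 12, n_iterations = 1, seed = 14)
  et <- crossboruta(Xz, config = cfg)
  expect_s3_class(et, "edge_table")
  expect_true(all(et$edges$target != et$edges$feature))
  expect_true(all(et$edges$decision %in% c("confirmed", "tentative")))
  # reversed target order: identical table
  et_rev <- crossboruta(Xz, targets = rev(rownames(Xz)), config = cfg)
  key <- function(e) { e <- e[order(e$target, e$feature), ]; rownames(e) <- NULL; e }
  expect_identical(key(et_rev$edges), key(et$edges))
  # conservation: total in-strength = total out-strength = total edge weight
  net <- restrict_to_hits(et, rownames(Xz))
  in_strength <- sum(vapply(net$nodes$gene,
                            function(g) sum(net$edges$meanImp[net$edges$feature == g]),
                            numeric(1)))
  out_strength <- sum(vapply(net$nodes$gene,
                             function(g) sum(net$edges$meanImp[net$edges$target == g]),
                             numeric(1)))
  expect_equal(in_strength, sum(net$edges$meanImp), tolerance = 1e-9)
  expect_equal(out_strength, sum(net$edges$meanImp), tolerance = 1e-9)
  # a constant target is skipped with a log entry
  Xc <- Xz
  Xc["g0012", ] <- 0
  expect_message(et_c <- crossboruta(Xc, targets = c("g0001", "g0012"), config = cfg),
                 "skipped")
  expect_identical(et_c$skipped, "g0012")
})
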