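# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, BFS) so it stays independent of the package implementation.

seeded_matrix <- function(n, p, seed, prefix = "f") {
  m <- crossage:::with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(m) <- sprintf("%s%03d", prefix, seq_len(p))
  m
}

# genes x samples noise matrix with gene rownames
noise_expression <- function(genes, samples, seed) {
  m <- crossage:::with_seed(seed, matrix(rnorm(genes * samples), genes, samples))
  rownames(m) <- sprintf("g%04d", seq_len(genes))
  colnames(m) <- sprintf("S%04d", seq_len(samples))
  m
}

# Brute-force all-pairs shortest paths by breadth-first search on an
# undirected simple graph given as a directed edge data.frame.
brute_closeness <- function(edges, nodes) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges$target[i]; b <- edges$feature[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[v] <- 0
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
    }
    reach <- names(dist)[is.finite(dist) & names(dist) != v]
    out[v] <- if (!length(reach)) 0 else length(reach) / sum(dist[reach])
  }
  out
}

# Brute-force AAS by explicit summation over the edge rows.
brute_aas <- function(edges, node) {
  in_sum <- 0; out_sum <- 0
  for (i in seq_len(nrow(edges))) {
    if (edges$feature[i] == node) in_sum <- in_sum + edges$meanImp[i]
    if (edges$target[i] == node) out_sum <- out_sum + edges$meanImp[i]
  }
  if (out_sum == 0) return(list(ratio = NA_real_, log2 = NA_real_))
  list(ratio = in_sum / out_sum,
       log2 = if (in_sum > 0) log2(in_sum / out_sum) else -Inf)
}

# Random small directed weighted edge table over the given node names.
random_edge_table <- function(nodes, seed, p_edge = 0.4) {
  crossage:::with_seed(seed, {
    rows <- list()
    for (a in nodes) for (b in nodes) {
      if (a != b && runif(1) < p_edge) {
        rows[[length(rows) + 1]] <- data.frame(
          target = a, feature = b, meanImp = round(runif(1, 0.5, 5), 3),
          normHits = round(runif(1), 3),
          decision = sample(c("confirmed", "tentative"), 1),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Cohort with one antiparallel twin pair on the turn-around archetype.
antiparallel_cohort <- function(seed, noise_sd, n_genes = 20, reps = 6) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  half <- n_genes / 2
  st <- planted_structure(
    n_genes, variance_fractions = c(organ = 0),
    archetype_assignments = stats::setNames(rep("inflect6", n_genes), genes),
    antiparallel_pairs = list(list(A = genes[1:half], B = genes[(half + 1):n_genes])),
    noise_sd = noise_sd, archetype_amplitude = 1)
  d <- cohort_design(organs = c("O1", "O2"), strains = "A", sexes = "F",
                     ages = c(3, 6, 12, 18, 24), replicates_per_cell = reps,
                     seed = seed)
  generate_cohort(d, st)
}

# Cohort with one fan-out regulator driving nine targets among noise genes.
regulator_cohort <- function(seed, n_genes = 24, reps = 12) {
  st <- planted_structure(
    n_genes, variance_fractions = c(organ = 0.2),
    regulators = list(list(regulator = "g0001",
                           targets = sprintf("g%04d", 2:10), effect = 1)))
  d <- cohort_design(organs = c("O1", "O2"), strains = "A", sexes = "F",
                     ages = c(3, 6, 12, 18, 24), replicates_per_cell = reps,
                     seed = seed)
  generate_cohort(d, st)
}
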