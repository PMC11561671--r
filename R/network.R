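#' All-versus-all feature selection (CrossBoruta)
#'
#' Runs the iterated shadow-feature selection once per target gene, with the
#' target's expression as the response and all other genes as predictors.
#' Every nonrejected feature becomes one directed edge target -> feature
#' carrying the iteration-averaged `meanImp` and `normHits`; the edge is
#' `confirmed` when the feature was confirmed in a majority of its
#' nonrejected iterations, otherwise `tentative`. Each target draws its seed
#' from the master seed and its own name, so results are identical whatever
#' the execution order.
#'
#' @param X harmonized genes x samples matrix.
#' @param targets genes to analyze as target variables (default: all).
#' @param config a [boruta_config()] with `mode = "numeric"`.
#' @param covariates optional data.frame of extra predictor columns (e.g.
#'   organ/strain/sex) added to every target's frame; excluded by default so
#'   the edges keep pure gene-gene semantics.
#' @return Object of class `edge_table`: data.frame with columns `target`,
#'   `feature`, `meanImp`, `normHits`, `decision`, plus provenance
#'   (`seed`, `universe`, `skipped`).
#' @export
crossboruta <- function(X, targets = rownames(X), config = boruta_config(),
                        covariates = NULL) {
  assert_expression_matrix(X)
  if (config$mode != "numeric") stop("crossboruta requires a numeric-mode configuration", call. = FALSE)
  missing <- setdiff(targets, rownames(X))
  if (length(missing)) stop(sprintf("target(s) not in matrix: %s",
                                    paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  edges <- list()
  skipped <- character()
  for (t in targets) {
    y <- X[t, ]
    if (stats::sd(y) == 0) {
      message(sprintf("target '%s' constant after harmonization: skipped", t))
      skipped <- c(skipped, t)
      next
    }
    predictors <- t(X[setdiff(rownames(X), t), , drop = FALSE])
    if (!is.null(covariates)) {
      cov_num <- as.data.frame(lapply(covariates, function(v) as.numeric(as.factor(v))))
      predictors <- cbind(predictors, as.matrix(cov_num))
    }
    cfg_t <- config
    cfg_t$seed <- derive_seed(config$seed, paste0("target:", t))
    ens <- boruta_ensemble(predictors, y, cfg_t)
    hit <- ens$features[ens$features$in_hit_set & ens$features$feature %in% rownames(X), , drop = FALSE]
    if (nrow(hit)) {
      edges[[t]] <- data.frame(
        target = t,
        feature = hit$feature,
        meanImp = hit$meanImp,
        normHits = hit$normHits,
        decision = ifelse(hit$n_confirmed > hit$n_nonrejected / 2, "confirmed", "tentative"),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- if (length(edges)) do.call(rbind, edges) else
    data.frame(target = character(), feature = character(), meanImp = numeric(),
               normHits = numeric(), decision = character(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(edges = tab, seed = config$seed, universe = rownames(X),
                 skipped = skipped),
            class = "edge_table")
}

#' Construct an edge table from a data.frame
#'
#' @param edges data.frame with columns `target`, `feature`, `meanImp`,
#'   `normHits`, `decision`.
#' @param universe gene universe the table refers to.
#' @param seed provenance seed (optional).
#' @export
edge_table <- function(edges, universe = unique(c(edges$target, edges$feature)), seed = NA_integer_) {
  need <- c("target", "feature", "meanImp", "normHits", "decision")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop(sprintf("edge table lacks column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (any(edges$target == edges$feature)) stop("self-edges (target == feature) are not allowed", call. = FALSE)
  if (anyDuplicated(edges[c("target", "feature")])) stop("duplicate (target, feature) pairs", call. = FALSE)
  if (any(!edges$decision %in% c("confirmed", "tentative"))) {
    stop("edge decisions must be 'confirmed' or 'tentative' (rejected pairs are absent)", call. = FALSE)
  }
  structure(list(edges = edges[need], seed = seed, universe = universe, skipped = character()),
            class = "edge_table")
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf("edge_table: %d directed edges over %d targets (universe %d genes)\n",
              nrow(x$edges), length(unique(x$edges$target)), length(x$universe)))
  invisible(x)
}

#' Restrict an edge table to a hit set and compute node metrics
#'
#' Keeps only edges with both endpoints in `hits`; nodes are all hits
#' (isolated ones retained). Per node, the asymmetric association strength,
#' the hub score (nonrejected in-edges) and the unweighted closeness
#' centrality are computed.
#'
#' @param table an `edge_table`.
#' @param hits nonempty character vector of hit genes.
#' @param origin optional named vector (gene -> `"NVA"`/`"CVA"`/`"both"`).
#' @param modules optional named vector (gene -> module label).
#' @return Object of class `aging_network` with `nodes` (data.frame: `gene`,
#'   `origin`, `aas_ratio`, `aas_log2`, `hub_score`, `closeness`, `module`)
#'   and `edges`.
#' @export
restrict_to_hits <- function(table, hits, origin = NULL, modules = NULL) {
  stopifnot(inherits(table, "edge_table"))
  if (length(hits) == 0) stop("`hits` must be nonempty", call. = FALSE)
  hits <- unique(hits)
  e <- table$edges
  e <- e[e$target %in% hits & e$feature %in% hits, , drop = FALSE]
  rownames(e) <- NULL
  nodes <- data.frame(gene = hits, stringsAsFactors = FALSE)
  nodes$origin <- if (!is.null(origin)) unname(origin[hits]) else NA_character_
  a <- aas_all(e, hits)
  nodes$aas_ratio <- a$ratio
  nodes$aas_log2 <- a$log2
  nodes$hub_score <- vapply(hits, function(g) sum(e$feature == g), integer(1))
  nodes$closeness <- node_closeness_values(e, hits)
  nodes$module <- if (!is.null(modules)) unname(modules[hits]) else NA_character_
  structure(list(nodes = nodes, edges = e), class = "aging_network")
}

#' @export
print.aging_network <- function(x, ...) {
  cat(sprintf("aging_network: %d nodes, %d directed edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

aas_all <- function(edges, nodes) {
  in_sum <- vapply(nodes, function(g) sum(edges$meanImp[edges$feature == g]), numeric(1))
  out_sum <- vapply(nodes, function(g) sum(edges$meanImp[edges$target == g]), numeric(1))
  ratio <- rep(NA_real_, length(nodes))
  l2 <- rep(NA_real_, length(nodes))
  defined <- out_sum > 0
  ratio[defined] <- in_sum[defined] / out_sum[defined]
  l2[defined & in_sum > 0] <- log2(ratio[defined & in_sum > 0])
  l2[defined & in_sum == 0] <- -Inf
  list(ratio = ratio, log2 = l2)
}

#' Asymmetric association strength of one node
#'
#' The sum of association weights (`meanImp`) over the node's in-edges (the
#' node acting as a selected feature of other targets) divided by the sum
#' over its out-edges (the node acting as a target). A ratio above 1
#' (positive log2) marks a transcript that others depend on more than it
#' depends on them -- a putative hierarchically superior actor. A node that
#' is never a target has no defined AAS (`NA`, the "no value" sentinel); a
#' node with targets but no in-edges has ratio 0 and `log2 = -Inf`.
#'
#' @param network an `aging_network` (or `edge_table`).
#' @param node gene identifier.
#' @return List with `ratio` and `log2`.
#' @export
aas <- function(network, node) {
  edges <- network$edges
  known <- if (inherits(network, "aging_network")) network$nodes$gene else network$universe
  if (!node %in% known) stop(sprintf("node '%s' not in network", node), call. = FALSE)
  a <- aas_all(edges, node)
  list(ratio = a$ratio, log2 = a$log2)
}

#' Hub score of a node
#'
#' The number of distinct target variables that selected the node as a
#' feature, optionally restricted by edge decision.
#'
#' @param network an `aging_network` or `edge_table`.
#' @param node gene identifier.
#' @param decision_filter edge decisions to count.
#' @return Integer count.
#' @export
hub_score <- function(network, node, decision_filter = c("confirmed", "tentative")) {
  e <- network$edges
  e <- e[e$decision %in% decision_filter, , drop = FALSE]
  length(unique(e$target[e$feature == node]))
}

node_closeness_values <- function(edges, nodes, weighted = FALSE) {
  g <- igraph::graph_from_data_frame(
    edges[, c("target", "feature", "meanImp")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  # parallel target->feature / feature->target edges collapse; keep the
  # strongest association as the link weight
  g <- igraph::simplify(g, edge.attr.comb = list(meanImp = "max"))
  d <- igraph::distances(g, weights = if (weighted) 1 / igraph::E(g)$meanImp else NA)
  comp <- igraph::components(g)$membership
  out <- stats::setNames(numeric(length(nodes)), nodes)
  vn <- igraph::V(g)$name
  for (i in seq_along(vn)) {
    members <- vn[comp == comp[i]]
    if (length(members) < 2) { out[vn[i]] <- 0; next }
    out[vn[i]] <- (length(members) - 1) / sum(d[i, members])
  }
  out
}

#' Closeness centrality of network nodes
#'
#' Per connected component, `c(i) = (n_comp - 1) / sum_j d(i, j)`; isolated
#' nodes score 0. By default the network is treated as unweighted and
#' undirected; the weighted mode uses edge length `1 / meanImp` (the layout
#' convention of association networks).
#'
#' @param network an `aging_network`.
#' @param weighted use inverse-`meanImp` edge lengths.
#' @return Named vector of closeness values in \[0, 1\] (unweighted mode).
#' @export
closeness_centrality <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "aging_network"))
  if (nrow(network$nodes) == 0) stop("network has no nodes", call. = FALSE)
  node_closeness_values(network$edges, network$nodes$gene, weighted = weighted)
}

#' Empirical quantile threshold
#'
#' Linear-interpolation empirical quantile (type 7), the convention used to
#' cut the closeness distribution at its 90% quantile.
#'
#' @param values numeric values.
#' @param q quantile in \[0, 1\].
#' @return The threshold value.
#' @export
quantile_threshold <- function(values, q = 0.90) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values", call. = FALSE)
  unname(stats::quantile(values, q, type = 7))
}

#' Feature-hierarchy query
#'
#' Finds the target variables that selected any member of `gene_set` as a
#' feature (under the decision filter), i.e. transcripts sharing a selected
#' feature with the query set.
#'
#' @param full_table an `edge_table` (typically over the full transcriptome).
#' @param gene_set nonempty character vector of feature genes.
#' @param decision_filter edge decisions admitted.
#' @return List with `targets` (character), `n_targets` and `n_edges`.
#' @export
feature_hierarchy_query <- function(full_table, gene_set,
                                    decision_filter = c("confirmed", "tentative")) {
  stopifnot(inherits(full_table, "edge_table"))
  if (length(gene_set) == 0) stop("`gene_set` must be nonempty", call. = FALSE)
  e <- full_table$edges
  e <- e[e$decision %in% decision_filter & e$feature %in% gene_set, , drop = FALSE]
  list(targets = sort(unique(e$target)), n_targets = length(unique(e$target)),
       n_edges = nrow(e))
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Export / import an aging network
#'
#' `export_network` writes GraphML (node attributes: origin, AAS, hub score,
#' closeness, module; edge attributes: meanImp, normHits, decision) or a TSV
#' edge list; `read_network_graphml` restores the network losslessly.
#' The undefined-AAS sentinel is encoded as the string `"no value"`.
#'
#' @param network an `aging_network`.
#' @param path output file.
#' @param format `"graphml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(network, "aging_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(
      data.frame(target = network$edges$target, feature = network$edges$feature,
                 meanImp = fmt_num(network$edges$meanImp),
                 normHits = fmt_num(network$edges$normHits),
                 decision = network$edges$decision, stringsAsFactors = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  nodes <- network$nodes
  enc <- function(x) ifelse(is.na(x), "no value", fmt_num(x))
  vertices <- data.frame(
    name = nodes$gene,
    origin = ifelse(is.na(nodes$origin), "NA", nodes$origin),
    aas_ratio = enc(nodes$aas_ratio),
    aas_log2 = enc(nodes$aas_log2),
    hub_score = nodes$hub_score,
    closeness = fmt_num(nodes$closeness),
    module = ifelse(is.na(nodes$module), "NA", nodes$module),
    stringsAsFactors = FALSE
  )
  # numeric attributes travel as 17-digit strings so the file round-trips
  # bit-exactly through the companion reader
  edges <- data.frame(target = network$edges$target, feature = network$edges$feature,
                      meanImp = fmt_num(network$edges$meanImp),
                      normHits = fmt_num(network$edges$normHits),
                      decision = network$edges$decision, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_network
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  dec <- function(x) suppressWarnings(ifelse(x == "no value", NA_real_, as.numeric(x)))
  nodes <- data.frame(
    gene = igraph::V(g)$name,
    origin = ifelse(igraph::V(g)$origin == "NA", NA_character_, igraph::V(g)$origin),
    aas_ratio = dec(igraph::V(g)$aas_ratio),
    aas_log2 = dec(igraph::V(g)$aas_log2),
    hub_score = as.integer(igraph::V(g)$hub_score),
    closeness = as.numeric(igraph::V(g)$closeness),
    module = ifelse(igraph::V(g)$module == "NA", NA_character_, igraph::V(g)$module),
    stringsAsFactors = FALSE
  )
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(target = el$from, feature = el$to,
                      meanImp = as.numeric(el$meanImp),
                      normHits = as.numeric(el$normHits),
                      decision = el$decision, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    edges <- data.frame(target = character(), feature = character(), meanImp = numeric(),
                        normHits = numeric(), decision = character(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "aging_network")
}

#' @rdname export_network
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$meanImp <- as.numeric(df$meanImp)
  df$normHits <- as.numeric(df$normHits)
  edge_table(df)
}
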