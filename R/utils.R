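#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed derived from a master seed and a string label.
# Used to give every Boruta iteration / CrossBoruta target its own stream so
# results do not depend on execution order.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Population-style standardization of the rows of a matrix: mean 0 and, when
# the row varies, population sd 1; constant rows map to all-zero.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  ctr <- x - mu
  sd_pop <- sqrt(rowMeans(ctr^2))
  out <- ctr / ifelse(sd_pop > 0, sd_pop, 1)
  out[sd_pop == 0, ] <- 0
  out
}

assert_expression_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  }
  if (is.null(rownames(x))) stop(sprintf("`%s` must have gene identifiers as rownames", arg), call. = FALSE)
  if (anyDuplicated(rownames(x))) stop(sprintf("`%s` has duplicated gene identifiers", arg), call. = FALSE)
  invisible(x)
}
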