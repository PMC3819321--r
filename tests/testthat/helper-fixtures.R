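# Small in-code fixtures shared across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# gene x sample tibble from a matrix-like spec
toy_expression <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}

# random strictly positive expression tibble
random_expression <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    toy_expression(matrix(2^stats::rnorm(n_genes * n_samples, 4, 2),
                          n_genes, n_samples))
  })
}

expr_mat <- function(data) {
  m <- as.matrix(data[, -1, drop = FALSE])
  rownames(m) <- data[[1]]
  m
}

factors_of <- function(x) {
  if (inherits(x, "tx_norm")) x <- x$factors
  stats::setNames(x$factor, x$sample)
}

# brute-force average-tie ranks: rank_i = #(x < x_i) + (#(x == x_i) + 1) / 2
brute_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Spearman correlation from first principles: Pearson on brute-force ranks
brute_spearman <- function(x, y) {
  rx <- brute_ranks(x); ry <- brute_ranks(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# dense linear-solve PageRank oracle on an undirected weighted graph:
# solves (I - d T) pr = (1 - d) / G, where T spreads a node's score over
# its neighbours proportionally to edge weight (uniformly for dangling).
solve_pagerank <- function(w, damping = 0.85) {
  g <- nrow(w)
  s <- colSums(w)
  t_mat <- matrix(0, g, g)
  for (j in seq_len(g)) {
    t_mat[, j] <- if (s[j] > 0) w[, j] / s[j] else 1 / g
  }
  as.vector(solve(diag(g) - damping * t_mat, rep((1 - damping) / g, g)))
}

# maximum relative error between two aligned positive factor vectors
max_rel_error <- function(est, truth) {
  est <- est[names(truth)]
  max(abs(est - truth) / truth)
}
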