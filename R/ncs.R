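#' Ratio dispersal between two genes
#'
#' For genes `i` and `j` with strictly positive expression across the same
#' samples, the per-sample expression ratios `R_k = y_i[k] / y_j[k]` are
#' formed and the dispersal is `D = log2(max_k R_k) - log2(min_k R_k)`.
#' `D` is symmetric in the gene order, non-negative, zero exactly for
#' perfectly proportional genes, and invariant under per-sample rescaling
#' (scaling factors cancel in the ratio).
#'
#' @param values_i,values_j Numeric vectors of per-sample expression,
#'   strictly positive, same length >= 2.
#' @return A one-row tibble with columns `max_ratio`, `min_ratio`, and
#'   `dispersal`.
#' @export
#' @examples
#' pair_dispersal(c(2, 4, 8), c(1, 2, 4))  # proportional: dispersal 0
pair_dispersal <- function(values_i, values_j) {
  if (length(values_i) != length(values_j) || length(values_i) < 2L) {
    abort("both vectors must share the same length >= 2.")
  }
  if (any(values_i <= 0) || any(values_j <= 0)) {
    abort("dispersal is defined for strictly positive values only.")
  }
  r <- values_i / values_j
  tibble(
    max_ratio = max(r), min_ratio = min(r),
    dispersal = log2(max(r)) - log2(min(r))
  )
}

# dense G x G dispersal matrix over the pool rows of a positive matrix
dispersal_matrix <- function(m) {
  l <- log2(m)
  g <- nrow(l)
  mx <- matrix(-Inf, g, g)
  mn <- matrix(Inf, g, g)
  for (k in seq_len(ncol(l))) {
    d <- outer(l[, k], l[, k], `-`)
    mx <- pmax(mx, d)
    mn <- pmin(mn, d)
  }
  out <- mx - mn
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Build the gene similarity network
#'
#' All gene pairs in the pool are compared by ratio dispersal; pairs with
#' `D <= d_cutoff` (default 1, i.e. the largest per-sample expression ratio
#' at most twice the smallest) become edges of a weighted undirected
#' network with similarity weight `sim = 1/(1 + D)`. Weights therefore lie
#' in `(1/(1 + d_cutoff), 1]`, reaching 1 only for perfectly proportional
#' pairs. Genes with no admissible pair remain as isolated nodes.
#'
#' @param data An expression tibble.
#' @param pool Character vector or tibble (`gene` column) of pool genes
#'   (>= 2), strictly positive in all samples (ubiquitous genes are).
#' @param d_cutoff Maximum admitted dispersal (default 1).
#' @return A `tx_network`: list with `nodes` (character), `edges` (tibble
#'   `from`, `to`, `dispersal`, `sim`), and `d_cutoff`.
#' @export
build_similarity_network <- function(data, pool, d_cutoff = 1) {
  data <- check_expression(data)
  if (is.data.frame(pool)) pool <- pool$gene
  if (length(pool) < 2L) abort("the network pool needs at least 2 genes.")
  if (d_cutoff <= 0) abort("`d_cutoff` must be positive.")
  m <- expr_matrix(data)
  missing <- setdiff(pool, rownames(m))
  if (length(missing)) abort(paste0("pool gene not in matrix: ", missing[1L]))
  m <- m[pool, , drop = FALSE]
  if (any(m <= 0)) abort("network pool genes must be strictly positive in all samples.")
  d <- dispersal_matrix(m)
  idx <- which(upper.tri(d) & d <= d_cutoff, arr.ind = TRUE)
  edges <- tibble(
    from = pool[idx[, 1L]],
    to = pool[idx[, 2L]],
    dispersal = d[idx],
    sim = 1 / (1 + d[idx])
  )
  structure(list(nodes = pool, edges = edges, d_cutoff = d_cutoff),
            class = "tx_network")
}

#' @export
print.tx_network <- function(x, ...) {
  cat("<tx_network>", length(x$nodes), "genes,", nrow(x$edges),
      "edges (dispersal cutoff", x$d_cutoff, ")\n")
  invisible(x)
}

# weighted PageRank by power iteration on an undirected network.
# Each undirected edge acts as two directed edges; a node passes its score
# to neighbours proportionally to edge weight. Nodes without edges are
# dangling: their score is redistributed uniformly.
power_iteration_pagerank <- function(nodes, edges, damping = 0.85,
                                     tol = 1e-9, max_iter = 1000L) {
  g <- length(nodes)
  w <- matrix(0, g, g, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    i <- match(edges$from, nodes)
    j <- match(edges$to, nodes)
    w[cbind(i, j)] <- edges$sim
    w[cbind(j, i)] <- edges$sim
  }
  strength <- colSums(w)
  dangling <- strength == 0
  v <- rep(1 / g, g)
  for (iter in seq_len(max_iter)) {
    share <- ifelse(dangling, 0, v / pmax(strength, .Machine$double.xmin))
    v_new <- (1 - damping) / g + damping * (as.vector(w %*% share) + sum(v[dangling]) / g)
    delta <- sum(abs(v_new - v))
    v <- v_new
    if (delta < tol) {
      return(setNames(v, nodes))
    }
  }
  abort(paste0("PageRank did not converge after ", max_iter,
               " iterations (L1 residual ", format(delta), ")."))
}

#' Centrality weights from the similarity network
#'
#' Runs weighted PageRank on the similarity network (power iteration,
#' stopping when the L1 change drops below `tol`) and converts the
#' PageRank of each of the `G` nodes into a guide weight
#' `W = PageRank * G - 1`: nodes more central than the uniform baseline
#' `1/G` get positive weight, the rest are set to zero and discarded.
#'
#' @param network A `tx_network` from [build_similarity_network()].
#' @param damping PageRank damping factor (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return A tibble with columns `gene`, `pagerank`, `weight`, restricted to
#'   genes with positive weight and ordered by decreasing weight. The full
#'   (unclamped) table over all nodes is stored in attribute `all`.
#' @export
centrality_weights <- function(network, damping = 0.85, tol = 1e-9,
                               max_iter = 1000L) {
  if (!inherits(network, "tx_network")) abort("`network` must be a tx_network.")
  if (!length(network$nodes)) abort("empty network.")
  pr <- power_iteration_pagerank(network$nodes, network$edges,
                                 damping = damping, tol = tol,
                                 max_iter = max_iter)
  g <- length(pr)
  all <- tibble(gene = names(pr), pagerank = unname(pr),
                weight = unname(pr) * g - 1)
  out <- all |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$gene)
  attr(out, "all") <- all
  attr(out, "damping") <- damping
  out
}

#' Scaling factors from centrality-weighted guide genes
#'
#' Combines the per-gene factor suggestions using the centrality weights:
#' factors are proportional to the reciprocal of the weight-weighted
#' geometric mean of the guide genes in each sample, product-1 adjusted, so
#' that after scaling the weighted geometric mean of the guides is constant
#' across samples. Multiplying all weights by a constant leaves the factors
#' unchanged.
#'
#' @param data An expression tibble.
#' @param weights A tibble with `gene` and `weight` columns (from
#'   [centrality_weights()]); at least one positive weight.
#' @return An adjusted factor tibble.
#' @export
ncs_factors <- function(data, weights) {
  data <- check_expression(data)
  weights <- dplyr::filter(as_tibble(weights), .data$weight > 0)
  if (!nrow(weights)) abort("all centrality weights are zero; no guide genes available.")
  g <- guide_geomeans(expr_matrix(data), weights$gene, weights$weight)
  adjust_factors(scaling_factors(1 / g))
}

#' Network Centrality Scaling (NCS)
#'
#' The five-stage pipeline: (1) build the wide-trim (0.05, 0.95) ubiquitous
#' pool, capped at the `pool_cap` most highly expressed genes; (2) compute
#' all pairwise ratio dispersals; (3) build the similarity network
#' (`sim = 1/(1+D)`, pairs with `D > d_cutoff` discarded) and run weighted
#' PageRank to obtain centrality weights; (4) derive product-1-adjusted
#' scaling factors from the weighted geometric mean of the positive-weight
#' guide genes; (5) scale every gene of the matrix. If the strict
#' ubiquitous intersection is empty the pool is rebuilt with 80% membership
#' (with a message); an empty pool after that is an error.
#'
#' @param data An expression tibble.
#' @param d_cutoff Maximum admitted dispersal (default 1).
#' @param pool_cap Maximum pool size fed to the quadratic pairwise stage
#'   (default 2000).
#' @param damping,tol,max_iter PageRank parameters.
#' @param lower_cut,upper_cut Trim profile of stage 1.
#' @return A `tx_norm` result; `details` records the pool, the network size,
#'   and the guide weights.
#' @export
normalize_ncs <- function(data, d_cutoff = 1, pool_cap = 2000L,
                          damping = 0.85, tol = 1e-9, max_iter = 1000L,
                          lower_cut = 0.05, upper_cut = 0.95) {
  data <- check_expression(data)
  pool <- ubiquitous_genes(data, lower_cut, upper_cut)
  if (!nrow(pool)) {
    inform("strict ubiquitous set is empty; relaxing membership to 80% of samples.")
    pool <- ubiquitous_genes(data, lower_cut, upper_cut, min_membership = 0.8)
  }
  if (nrow(pool) < 2L) {
    abort("ubiquitous pool has fewer than 2 genes even after relaxation; widen the trim cutoffs.")
  }
  capped <- top_expressed_subset(data, pool, n_max = pool_cap)
  network <- build_similarity_network(data, capped$gene, d_cutoff = d_cutoff)
  weights <- centrality_weights(network, damping = damping, tol = tol,
                                max_iter = max_iter)
  if (!nrow(weights)) {
    # perfectly symmetric network (e.g. noise-free proportional pool): no
    # gene exceeds uniform centrality, so all pool genes are equally good
    # guides -- fall back to equal weights.
    inform("no gene exceeds uniform centrality; using equal weights over the pool.")
    weights <- tibble(gene = network$nodes, weight = 1)
  }
  factors <- ncs_factors(data, weights)
  new_tx_norm(
    "ncs", apply_factors(data, factors), factors,
    details = list(
      guides = weights$gene, weights = weights$weight,
      centrality = weights, pool = capped$gene,
      n_edges = nrow(network$edges), d_cutoff = d_cutoff,
      damping = damping
    )
  )
}
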