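#' Coefficient of variation of a gene's expression
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. The CoV
#' is scale-free: rescaling the whole vector leaves it unchanged, which is
#' why the uniform-gene count is invariant under global matrix rescaling.
#'
#' @param values Numeric per-sample expression values with positive mean.
#' @return A single number.
#' @export
#' @examples
#' gene_cov(c(1, 2, 3))  # 0.5
gene_cov <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) abort("CoV is undefined for a non-positive mean.")
  sd(values) / m
}

# closure for fast repeated uniform counting under candidate factor vectors
# (used by the Evolution Strategy): two matrix-vector products per call.
uniform_counter <- function(m, cov_cutoff = 0.25) {
  n <- ncol(m)
  m2 <- m^2
  function(f) {
    s1 <- as.vector(m %*% f)
    s2 <- as.vector(m2 %*% (f^2))
    mu <- s1 / n
    v <- (s2 - n * mu^2) / (n - 1)
    v[v < 0] <- 0
    sum(mu > 0 & sqrt(v) < cov_cutoff * mu)
  }
}

#' Count uniformly expressed genes
#'
#' A gene is "uniform" when the CoV of its (normalized) expression across
#' samples is below `cov_cutoff` (default 0.25). The count of uniform genes
#' is the package's first metric of normalization success: better scaling
#' renders more genes consistent across samples. Genes with zero mean are
#' never uniform.
#'
#' @param data An expression tibble (typically already normalized).
#' @param cov_cutoff CoV cutoff (default 0.25; 0.15-0.5 are sensible
#'   alternatives, stricter cutoffs separate methods less).
#' @return A tibble of the uniform genes with columns `gene`, `mean`, `cov`;
#'   the count is `nrow()` of the result.
#' @export
count_uniform <- function(data, cov_cutoff = 0.25) {
  data <- check_expression(data)
  if (!(cov_cutoff > 0)) abort("`cov_cutoff` must be positive.")
  m <- expr_matrix(data)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  ok <- mu > 0 & s / mu < cov_cutoff
  tibble(gene = rownames(m)[ok], mean = mu[ok], cov = (s / mu)[ok])
}

# decode the k-th unordered pair (i < j) over p items, column-major upper triangle
decode_pairs <- function(k, p) {
  # j is the smallest column with k <= choose(j, 2)... solve quadratically
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  # guard against floating-point overshoot at exact triangular numbers
  over <- k <= (j - 1) * (j - 2) / 2
  j[over] <- j[over] - 1
  i <- k - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Decorrelation of sample rankings across gene pairs
#'
#' Each gene, through its expression values, induces a ranking of the
#' samples. For a large sample of gene pairs (all pairs when cheaper) the
#' Spearman correlation between the two induced rankings is computed; a
#' successfully normalized matrix shows a symmetric correlation
#' distribution centered near zero, while distorted scalings push most
#' pairs to agree on the same sample ranking and inflate the mean. Genes
#' constant across samples induce no ranking; pairs containing them are
#' resampled (or dropped under exhaustive enumeration) and reported.
#'
#' @param data An expression tibble.
#' @param pool Character vector or tibble (`gene` column) of genes to
#'   compare; defaults to the wide-trim (0.05, 0.95) ubiquitous set.
#' @param n_pairs Number of gene pairs to sample (default 100000); all
#'   pairs are enumerated when there are fewer than `n_pairs`.
#' @param seed Integer seed for pair sampling.
#' @return A `tx_decorrelation` object: list with `correlations` (numeric
#'   vector), `mean`, `median`, `n_pairs`, `exhaustive`, `n_unrankable`
#'   (genes without two distinct values), and `seed`. `tidy()` returns the
#'   correlations as a tibble, `glance()` the summary row, `autoplot()` the
#'   density curve.
#' @export
ranking_decorrelation <- function(data, pool = NULL, n_pairs = 1e5, seed = 1L) {
  data <- check_expression(data)
  if (is.null(pool)) pool <- ubiquitous_genes(data, 0.05, 0.95)
  if (is.data.frame(pool)) pool <- pool$gene
  if (length(pool) < 2L) abort("the decorrelation pool needs at least 2 genes.")
  m <- expr_matrix(data)
  missing <- setdiff(pool, rownames(m))
  if (length(missing)) abort(paste0("pool gene not in matrix: ", missing[1L]))
  m <- m[pool, , drop = FALSE]

  # per-gene sample rankings (average ties), centered and normalized so the
  # Spearman correlation of a pair is a plain dot product
  r <- t(apply(m, 1L, rank))
  r <- r - rowMeans(r)
  norms <- sqrt(rowSums(r^2))
  rankable <- norms > 0
  n_unrankable <- sum(!rankable)
  if (n_unrankable > 0) {
    inform(paste0(n_unrankable, " pool gene(s) are constant across samples and were dropped."))
  }
  z <- r[rankable, , drop = FALSE] / norms[rankable]
  p <- nrow(z)
  if (p < 2L) abort("fewer than 2 rankable genes in the pool.")
  total <- p * (p - 1) / 2
  exhaustive <- total <= n_pairs
  ks <- if (exhaustive) seq_len(total) else withr::with_seed(seed, sample(total, n_pairs))
  ij <- decode_pairs(ks, p)
  rho <- unname(rowSums(z[ij[, "i"], , drop = FALSE] * z[ij[, "j"], , drop = FALSE]))
  structure(
    list(
      correlations = rho, mean = mean(rho), median = median(rho),
      n_pairs = length(rho), exhaustive = exhaustive,
      n_unrankable = n_unrankable, seed = seed
    ),
    class = "tx_decorrelation"
  )
}

#' @export
print.tx_decorrelation <- function(x, ...) {
  cat("<tx_decorrelation>", x$n_pairs, "gene pairs",
      if (x$exhaustive) "(exhaustive)" else "(sampled)", "\n")
  cat("  mean Spearman:", format(x$mean, digits = 4),
      " median:", format(x$median, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.tx_decorrelation <- function(x, ...) tibble(rho = x$correlations)

#' @export
glance.tx_decorrelation <- function(x, ...) {
  tibble(
    mean_rho = x$mean, median_rho = x$median, n_pairs = x$n_pairs,
    exhaustive = x$exhaustive, n_unrankable = x$n_unrankable
  )
}

#' @export
autoplot.tx_decorrelation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Spearman correlation of sample rankings",
      y = "density",
      title = "Gene-pair ranking decorrelation"
    ) +
    ggplot2::theme_minimal()
}

#' Pairwise correlation between scaling-factor solutions
#'
#' Pearson correlation of the log2 factor vectors for every pair of
#' methods, over a shared sample set. Methods approaching the same optimal
#' scaling show correlations near 1; a method against its own rescaled
#' factors gives exactly 1 (log2 turns a common scale into an additive
#' shift).
#'
#' @param factor_sets Named list of factor tibbles (see
#'   [scaling_factors()]) or named numeric vectors over identical samples.
#' @return A `tx_factor_comparison`: the symmetric correlation matrix with
#'   methods as dimnames. `tidy()` returns the long form, `autoplot()` a
#'   tile heatmap.
#' @export
compare_factor_sets <- function(factor_sets) {
  if (length(factor_sets) < 2L) abort("at least 2 factor sets are required.")
  if (is.null(names(factor_sets)) || any(!nzchar(names(factor_sets)))) {
    abort("`factor_sets` must be a named list.")
  }
  vecs <- lapply(factor_sets, factor_vector)
  samples <- names(vecs[[1L]])
  for (nm in names(vecs)) {
    if (!setequal(names(vecs[[nm]]), samples) || length(vecs[[nm]]) != length(samples)) {
      abort(paste0("factor set '", nm, "' covers different samples."))
    }
    vecs[[nm]] <- vecs[[nm]][samples]
  }
  lf <- vapply(vecs, function(f) log2(f), double(length(samples)))
  out <- stats::cor(lf, method = "pearson")
  structure(out, class = c("tx_factor_comparison", class(out)))
}

#' @export
tidy.tx_factor_comparison <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE)) |>
    setNames(c("method_a", "method_b", "correlation"))
}

#' @export
autoplot.tx_factor_comparison <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$method_a, y = .data$method_b, fill = .data$correlation)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r(log2 f)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Uniform-gene fitness terrain over trim cutoffs
#'
#' For every combination of lower and upper trim cutoffs on a resolution
#' grid (cut points at multiples of `resolution` up to 1, lower < upper),
#' the ubiquitous set is rebuilt, Total-Ubiquitous scaling applied, and the
#' uniform genes counted. Combinations with an empty ubiquitous set score
#' zero. The scan shows how robust the cutoff choice is and where the
#' count is maximized.
#'
#' @param data An expression tibble.
#' @param resolution Grid step in (0, 0.5) (default 0.05).
#' @param cov_cutoff CoV cutoff for the uniform count.
#' @return A `tx_grid_scan` tibble with columns `lower`, `upper`,
#'   `n_uniform`; the best combination is in attribute `argmax`.
#'   `autoplot()` draws the terrain as a tile map.
#' @export
cutoff_grid_scan <- function(data, resolution = 0.05, cov_cutoff = 0.25) {
  data <- check_expression(data)
  if (!(resolution > 0 && resolution < 0.5)) abort("`resolution` must be in (0, 0.5).")
  cuts <- seq(resolution, 1, by = resolution)
  grid <- tidyr::expand_grid(lower = cuts, upper = cuts) |>
    dplyr::filter(.data$lower < .data$upper)
  grid$n_uniform <- purrr::map2_int(grid$lower, grid$upper, function(lo, up) {
    pool <- ubiquitous_genes(data, lo, up)
    if (!nrow(pool)) return(0L)
    res <- tryCatch(normalize_total_ubiquitous(data, pool),
                    error = function(e) NULL)
    if (is.null(res)) return(0L)
    nrow(count_uniform(res$data, cov_cutoff))
  })
  best <- grid[which.max(grid$n_uniform), ]
  out <- structure(grid, class = c("tx_grid_scan", class(grid)))
  attr(out, "argmax") <- best
  attr(out, "cov_cutoff") <- cov_cutoff
  out
}

#' @export
autoplot.tx_grid_scan <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$lower, y = .data$upper, fill = .data$n_uniform)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "lower trim cutoff", y = "upper trim cutoff",
                  fill = "uniform\ngenes") +
    ggplot2::theme_minimal()
}

#' Evaluate a normalized matrix
#'
#' Bundles the package's two success metrics -- the uniform-gene count and
#' the gene-pair ranking decorrelation -- plus the specific-gene count into
#' one report row.
#'
#' @param data A normalized expression tibble (or a `tx_norm` result).
#' @param method Label for the report (taken from a `tx_norm` input when
#'   omitted).
#' @param cov_cutoff CoV cutoff for uniform genes.
#' @param pool Decorrelation pool; defaults to the wide-trim ubiquitous set.
#' @param n_pairs,seed Passed to [ranking_decorrelation()].
#' @return A one-row tibble: `method`, `uniform_count`, `specific_count`,
#'   `cov_cutoff`, `mean_pair_correlation`, `median_pair_correlation`,
#'   `n_pairs_sampled`, `seed`.
#' @export
evaluate_scaling <- function(data, method = NULL, cov_cutoff = 0.25,
                             pool = NULL, n_pairs = 1e5, seed = 1L) {
  if (inherits(data, "tx_norm")) {
    method <- method %||% data$method
    data <- data$data
  }
  data <- check_expression(data)
  dec <- ranking_decorrelation(data, pool = pool, n_pairs = n_pairs, seed = seed)
  tibble(
    method = method %||% "unnamed",
    uniform_count = nrow(count_uniform(data, cov_cutoff)),
    specific_count = nrow(specific_genes(data)),
    cov_cutoff = cov_cutoff,
    mean_pair_correlation = dec$mean,
    median_pair_correlation = dec$median,
    n_pairs_sampled = dec$n_pairs,
    seed = seed
  )
}
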