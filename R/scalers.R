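#' Canonicalize scaling factors to product 1
#'
#' Divides each factor by the geometric mean of the set, so the product of
#' the adjusted factors equals 1 and the global scale of the data set is
#' maintained. Ratios between factors are preserved exactly; the operation
#' is idempotent and invariant to a common rescaling of the input.
#'
#' @param factors A factor tibble (see [scaling_factors()]) or named numeric
#'   vector.
#' @return A factor tibble with attribute `adjusted = TRUE`.
#' @export
#' @examples
#' adjust_factors(c(a = 4, b = 1))  # -> 2, 0.5
adjust_factors <- function(factors) {
  f <- factor_vector(factors)
  g <- exp(mean(log(f)))
  scaling_factors(f / g, adjusted = TRUE)
}

# shared tail: factors -> adjusted factors -> scaled matrix -> result
finish_factor_method <- function(method, data, f, details = list(), adjust = TRUE) {
  factors <- if (adjust) adjust_factors(scaling_factors(f)) else scaling_factors(f)
  new_tx_norm(method, apply_factors(data, factors), factors, details)
}

#' Scale each sample to a fixed total of one million (CPM)
#'
#' The only method here that scales samples independently of each other:
#' factors are `1e6 / column total`, so every sample sums to one million
#' afterwards. Factors are reported unadjusted (the absolute CPM scale is
#' the point of the method).
#'
#' @param data An expression tibble.
#' @return A `tx_norm` result.
#' @export
normalize_cpm <- function(data) {
  data <- check_expression(data)
  totals <- colSums(expr_matrix(data))
  if (any(totals <= 0)) {
    abort(paste0("sample '", names(totals)[totals <= 0][1L], "' has zero total expression."))
  }
  finish_factor_method("cpm", data, 1e6 / totals, adjust = FALSE)
}

#' Scale each sample to the average total count per sample
#'
#' Variant of CPM that preserves the grand total of the data set: every
#' column is scaled to the mean column total.
#'
#' @inheritParams normalize_cpm
#' @return A `tx_norm` result.
#' @export
normalize_total <- function(data) {
  data <- check_expression(data)
  totals <- colSums(expr_matrix(data))
  if (any(totals <= 0)) {
    abort(paste0("sample '", names(totals)[totals <= 0][1L], "' has zero total expression."))
  }
  finish_factor_method("total", data, mean(totals) / totals, adjust = FALSE)
}

# nearest-rank quantile on the ascending sorted values
nearest_rank_value <- function(v, q) {
  v <- sort(v)
  v[max(1L, ceiling(q * length(v)))]
}

#' Scale samples to equalize an expression percentile
#'
#' The expression value at quantile `q` of each sample (nearest-rank method,
#' over all genes or over nonzero genes only) is scaled to the arithmetic
#' mean of that value across samples. `q = 0.75` is upper-quartile scaling,
#' `q = 0.90` upper-decile.
#'
#' @inheritParams normalize_cpm
#' @param q Quantile in (0, 1).
#' @param nonzero_only Compute the percentile over nonzero values only;
#'   useful for sparse matrices whose low quantiles are zero.
#' @return A `tx_norm` result.
#' @export
normalize_percentile <- function(data, q = 0.75, nonzero_only = FALSE) {
  data <- check_expression(data)
  if (!(q > 0 && q < 1)) abort("`q` must be in (0, 1).")
  m <- expr_matrix(data)
  v <- vapply(seq_len(ncol(m)), function(k) {
    x <- m[, k]
    if (nonzero_only) x <- x[x > 0]
    if (!length(x)) return(0)
    nearest_rank_value(x, q)
  }, double(1L))
  names(v) <- colnames(m)
  if (any(v <= 0)) {
    abort(paste0(
      "the ", q, "-quantile of sample '", names(v)[v <= 0][1L],
      "' is zero; use nonzero_only = TRUE or a higher q."
    ))
  }
  finish_factor_method(
    paste0("percentile_", q, if (nonzero_only) "_nonzero" else ""),
    data, mean(v) / v,
    details = list(q = q, nonzero_only = nonzero_only, values = v),
    adjust = FALSE
  )
}

# weighted geometric mean of guide genes per sample; guides must be nonzero
guide_geomeans <- function(m, genes, weights) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) abort(paste0("guide gene not in matrix: ", missing[1L]))
  g <- m[genes, , drop = FALSE]
  zero <- which(g <= 0, arr.ind = TRUE)
  if (nrow(zero)) {
    abort(paste0(
      "guide gene '", rownames(g)[zero[1L, 1L]], "' has a zero value in sample '",
      colnames(g)[zero[1L, 2L]], "'; exclude it from the guide set."
    ))
  }
  w <- weights / sum(weights)
  exp(colSums(log(g) * w))
}

#' Scale samples to equalize guide genes
#'
#' Computes for each sample the weighted geometric mean of the guide genes'
#' expression, and scales so that this mean is identical across samples;
#' factors are product-1 adjusted. With a single guide this is classic
#' housekeeping-gene scaling; with several equally weighted guides it is the
#' geNorm-style geometric averaging; with centrality weights it is the final
#' stage of NCS.
#'
#' @inheritParams normalize_cpm
#' @param guides A character vector of gene ids (weight 1 each) or a tibble
#'   with columns `gene` and `weight` (non-negative, at least one positive).
#' @param method_name Label recorded on the result.
#' @return A `tx_norm` result; `details$guides` records the guides used.
#' @export
normalize_guide <- function(data, guides, method_name = "guide") {
  data <- check_expression(data)
  if (is.character(guides)) guides <- tibble(gene = guides, weight = 1)
  if (!all(c("gene", "weight") %in% names(guides))) {
    abort("`guides` needs `gene` and `weight` columns.")
  }
  guides <- dplyr::filter(guides, .data$weight > 0)
  if (!nrow(guides)) abort("at least one guide gene with positive weight is required.")
  if (any(!is.finite(guides$weight))) abort("guide weights must be finite.")
  m <- expr_matrix(data)
  g <- guide_geomeans(m, guides$gene, guides$weight)
  finish_factor_method(
    method_name, data, 1 / g,
    details = list(guides = guides$gene, weights = guides$weight, guide_means = g)
  )
}

#' The nine housekeeping genes of the geNorm panel
#'
#' The classic ten-gene geNorm panel minus YWHAZ (which is typically not
#' observed in all samples of diverse-tissue data sets).
#'
#' @return A character vector of gene symbols.
#' @export
housekeeping_genes <- function() {
  c("ACTB", "B2M", "GAPDH", "HMBS", "HPRT1", "RPL13A", "SDHA", "TBP", "UBC")
}

#' geNorm gene-stability ranking and selection
#'
#' Implements the geNorm stability measure: for candidate `j`,
#' `M_j` is the mean over all other candidates `h` of the standard deviation
#' across samples of `log2(Y_j / Y_h)`. The least stable (highest `M`) gene
#' is removed and `M` recomputed, iterating until `k` candidates remain.
#'
#' @inheritParams normalize_cpm
#' @param candidates Character vector (or `gene`/`weight` tibble) of
#'   candidate control genes, nonzero in all samples; at least 3.
#' @param k Number of control genes to retain (`3 <= k <= length(candidates)`).
#' @return A list with `ranking` (tibble `gene`, `m_value`, `selected`,
#'   ordered most stable first; `m_value` is the stability at the round the
#'   gene was dropped, or the final-round value for survivors) and
#'   `selected` (character vector of the `k` survivors).
#' @export
genorm_select <- function(data, candidates = housekeeping_genes(), k = 3L) {
  data <- check_expression(data)
  if (is.data.frame(candidates)) candidates <- candidates$gene
  candidates <- intersect(candidates, expr_genes(data))
  if (length(candidates) < 3L) abort("at least 3 candidate genes present in the matrix are required.")
  if (k < 3L || k > length(candidates)) abort("`k` must be between 3 and the number of candidates.")
  m <- expr_matrix(data)[candidates, , drop = FALSE]
  if (any(m <= 0)) abort("geNorm candidates must be nonzero in all samples.")
  lm2 <- log2(m)

  m_values <- function(rows) {
    vapply(rows, function(j) {
      others <- setdiff(rows, j)
      mean(vapply(others, function(h) sd(lm2[j, ] - lm2[h, ]), double(1L)))
    }, double(1L))
  }

  alive <- candidates
  dropped <- character()
  dropped_m <- double()
  while (length(alive) > k) {
    mv <- m_values(alive)
    worst <- which.max(mv)  # ties: first index, i.e. candidate order
    dropped <- c(alive[worst], dropped)
    dropped_m <- c(mv[worst], dropped_m)
    alive <- alive[-worst]
  }
  final_m <- m_values(alive)
  ranking <- tibble(
    gene = c(alive[order(final_m, alive)], dropped),
    m_value = unname(c(final_m[order(final_m, alive)], dropped_m)),
    selected = c(rep(TRUE, length(alive)), rep(FALSE, length(dropped)))
  )
  list(ranking = ranking, selected = alive)
}

#' geNorm normalization
#'
#' Selects the `k` most stable control genes with [genorm_select()] and
#' scales to their geometric mean via [normalize_guide()].
#'
#' @inheritParams genorm_select
#' @return A `tx_norm` result; `details$ranking` carries the stability table.
#' @export
normalize_genorm <- function(data, candidates = housekeeping_genes(), k = 3L) {
  sel <- genorm_select(data, candidates, k)
  out <- normalize_guide(data, sel$selected, method_name = paste0("genorm_", k))
  out$details$ranking <- sel$ranking
  out
}

#' Select the most stable genes from a large pool
#'
#' Single-pass variant of the geNorm stability measure for pools of
#' thousands of genes: each pool gene's `M` is the mean standard deviation
#' of its log2 ratios against a fixed seeded subsample of the pool (size
#' `min(subsample, pool size)`), rather than the full iterative O(n^2)
#' exclusion. The `n` lowest-`M` genes are returned with weight 1.
#'
#' @inheritParams normalize_cpm
#' @param pool Character vector or tibble (`gene` column) of pool genes,
#'   typically the wide-trim (0.05, 0.95) ubiquitous set; nonzero in all
#'   samples.
#' @param n Number of stable genes to select (default 100).
#' @param subsample Size of the seeded reference subsample (default 100).
#' @param seed Integer seed controlling the reference subsample.
#' @return A tibble with columns `gene`, `weight` (all 1), and `m_value`,
#'   ordered most stable first.
#' @export
stability_select <- function(data, pool, n = 100L, subsample = 100L, seed = 1L) {
  data <- check_expression(data)
  if (is.data.frame(pool)) pool <- pool$gene
  if (length(pool) < 2L) abort("the stability pool needs at least 2 genes.")
  m <- expr_matrix(data)[pool, , drop = FALSE]
  if (any(m <= 0)) abort("stability pool genes must be nonzero in all samples.")
  if (n > length(pool)) {
    warn("`n` exceeds the pool size; returning the whole pool.")
    n <- length(pool)
  }
  lm2 <- log2(m)
  ref <- withr::with_seed(seed, sample(pool, min(subsample, length(pool))))
  ref_idx <- match(ref, pool)
  mv <- vapply(seq_along(pool), function(j) {
    others <- setdiff(ref_idx, j)
    mean(vapply(others, function(h) sd(lm2[j, ] - lm2[h, ]), double(1L)))
  }, double(1L))
  ord <- order(mv, pool)
  keep <- head(ord, n)
  tibble(gene = pool[keep], weight = 1, m_value = mv[keep])
}

#' Stability normalization
#'
#' Scales to the geometric mean of the `n` most stable ubiquitous genes,
#' using the wide (0.05, 0.95) trim profile to build the pool.
#'
#' @inheritParams stability_select
#' @return A `tx_norm` result.
#' @export
normalize_stability <- function(data, n = 100L, subsample = 100L, seed = 1L) {
  data <- check_expression(data)
  pool <- ubiquitous_genes(data, 0.05, 0.95)
  if (!nrow(pool)) abort("empty wide-trim ubiquitous pool; cannot run the Stability method.")
  stable <- stability_select(data, pool, n = n, subsample = subsample, seed = seed)
  out <- normalize_guide(data, stable$gene, method_name = "stability")
  out$details$m_values <- stable
  out
}

#' Scale by randomly picked ubiquitous genes
#'
#' Negative control for guide-based methods: draws `n` genes from the
#' ubiquitous pool without replacement (seeded) and scales to their
#' geometric mean. `n = 10` mirrors geNorm-sized guide sets, `n = 100`
#' NCS/Stability-sized ones.
#'
#' @inheritParams normalize_cpm
#' @param pool Character vector or tibble (`gene` column) of ubiquitous genes.
#' @param n Number of genes to draw (`n <= length(pool)`).
#' @param seed Integer seed for the draw.
#' @return A `tx_norm` result.
#' @export
normalize_random_ubiquitous <- function(data, pool, n = 100L, seed = 1L) {
  data <- check_expression(data)
  if (is.data.frame(pool)) pool <- pool$gene
  if (n > length(pool)) abort("`n` exceeds the pool size.")
  picked <- withr::with_seed(seed, sample(pool, n))
  out <- normalize_guide(data, picked, method_name = paste0("random_ubiquitous_", n))
  out$details$seed <- seed
  out
}

#' Scale to equalize the total expression of ubiquitous genes
#'
#' Each sample's summed expression over the ubiquitous pool is scaled to the
#' arithmetic mean of those totals across samples; all other genes follow
#' the same factor.
#'
#' @inheritParams normalize_cpm
#' @param pool Character vector or tibble (`gene` column) of ubiquitous
#'   genes; when `NULL` the default-trim (0.30, 0.85) ubiquitous set of the
#'   matrix is used.
#' @param lower_cut,upper_cut Trim profile used when `pool` is `NULL`.
#' @return A `tx_norm` result.
#' @export
normalize_total_ubiquitous <- function(data, pool = NULL,
                                       lower_cut = 0.30, upper_cut = 0.85) {
  data <- check_expression(data)
  if (is.null(pool)) pool <- ubiquitous_genes(data, lower_cut, upper_cut)
  if (is.data.frame(pool)) pool <- pool$gene
  if (!length(pool)) abort("empty ubiquitous pool.")
  m <- expr_matrix(data)
  missing <- setdiff(pool, rownames(m))
  if (length(missing)) abort(paste0("pool gene not in matrix: ", missing[1L]))
  totals <- colSums(m[pool, , drop = FALSE])
  if (any(totals <= 0)) abort("a sample has zero total over the pool.")
  finish_factor_method(
    "total_ubiquitous", data, mean(totals) / totals,
    details = list(guides = pool, pool_totals = totals),
    adjust = FALSE
  )
}

#' Mock normalization by random factors
#'
#' Scales each sample by `2^r` with `r` uniform on `[-0.5, 0.5)`, i.e.
#' factors in `[0.707, 1.414)`. A negative control: any method worth using
#' should beat it.
#'
#' @inheritParams normalize_cpm
#' @param seed Integer seed.
#' @return A `tx_norm` result (factors reported unadjusted, as drawn).
#' @export
normalize_random <- function(data, seed = 1L) {
  data <- check_expression(data)
  samples <- expr_samples(data)
  f <- withr::with_seed(seed, 2^runif(length(samples), -0.5, 0.5))
  names(f) <- samples
  finish_factor_method("random", data, f, details = list(seed = seed), adjust = FALSE)
}

# rank-trim helper: keep entries whose ascending rank r satisfies
# r > trim * n and r <= (1 - trim) * n
rank_trim_keep <- function(x, trim) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  r > trim * n & r <= (1 - trim) * n
}

#' Trimmed mean of M-values (TMM) scaling
#'
#' For each sample against a reference sample: genes expressed in both are
#' kept; per-gene log fractions give the average expression `A_g` and the
#' log-ratio `M_g`; the top and bottom `trim_a` of genes by `A` and then the
#' top and bottom `trim_m` by `M` are trimmed; the log scaling ratio is the
#' average of the remaining `M_g` weighted by inverse delta-method
#' asymptotic variances. Final factors fold in the column totals and are
#' product-1 adjusted.
#'
#' @inheritParams normalize_cpm
#' @param reference Reference sample id (default: first sample).
#' @param trim_m Fraction trimmed from each end of the `M` distribution
#'   (default 0.30).
#' @param trim_a Fraction trimmed from each end of the `A` distribution
#'   (default 0.05).
#' @return A `tx_norm` result; `details$tmm` holds the per-sample TMM ratios.
#' @export
normalize_tmm <- function(data, reference = NULL, trim_m = 0.30, trim_a = 0.05) {
  data <- check_expression(data)
  m <- expr_matrix(data)
  samples <- colnames(m)
  reference <- reference %||% samples[1L]
  if (!reference %in% samples) abort(paste0("no such reference sample: ", reference))
  totals <- colSums(m)
  if (any(totals <= 0)) abort("a sample has zero total expression.")
  yr <- m[, reference]
  tmm <- setNames(rep(1, length(samples)), samples)
  for (k in setdiff(samples, reference)) {
    yk <- m[, k]
    both <- yk > 0 & yr > 0
    fk <- yk[both] / totals[k]
    fr <- yr[both] / totals[reference]
    a <- log(fk) + log(fr)
    mg <- log(fk) - log(fr)
    keep <- rank_trim_keep(a, trim_a)
    keep[keep] <- rank_trim_keep(mg[keep], trim_m)
    if (sum(keep) < 3L) {
      abort(paste0("fewer than 3 genes survive TMM trimming for sample '", k, "'."))
    }
    v <- (totals[k] - yk[both]) / (totals[k] * yk[both]) +
      (totals[reference] - yr[both]) / (totals[reference] * yr[both])
    w <- 1 / v[keep]
    tmm[k] <- exp(sum(w * mg[keep]) / sum(w))
  }
  finish_factor_method(
    "tmm", data, 1 / (totals * tmm),
    details = list(reference = reference, tmm = tmm, trim_m = trim_m, trim_a = trim_a)
  )
}

#' Normalize an expression matrix by a named method
#'
#' Dispatcher over all implemented methods; the workhorse behind the
#' command-line tool. Method-specific parameters are passed through `...`.
#'
#' @inheritParams normalize_cpm
#' @param method One of `"cpm"`, `"total"`, `"upper_quartile"`,
#'   `"upper_decile"`, `"percentile"`, `"housekeeping"`, `"genorm"`,
#'   `"stability"`, `"random_ubiquitous"`, `"all_ubiquitous"`,
#'   `"total_ubiquitous"`, `"random"`, `"tmm"`, `"quantile"`, `"ncs"`,
#'   `"es"`.
#' @param ... Passed to the method implementation.
#' @return A `tx_norm` result.
#' @export
normalize_expression <- function(data, method, ...) {
  data <- check_expression(data)
  args <- list(...)
  wide_pool <- function() {
    pool <- ubiquitous_genes(data, 0.05, 0.95)
    if (!nrow(pool)) abort("empty wide-trim ubiquitous pool.")
    pool
  }
  switch(
    method,
    cpm = normalize_cpm(data),
    total = normalize_total(data),
    upper_quartile = normalize_percentile(data, q = 0.75, ...),
    upper_decile = normalize_percentile(data, q = 0.90, ...),
    percentile = do.call(normalize_percentile, c(list(data), args)),
    housekeeping = {
      gene <- args$gene %||% intersect(housekeeping_genes(), expr_genes(data))[1L]
      if (is.na(gene)) abort("no housekeeping gene present in the matrix.")
      normalize_guide(data, gene, method_name = paste0("housekeeping_", gene))
    },
    guide = do.call(normalize_guide, c(list(data), args)),
    genorm = do.call(normalize_genorm, c(list(data), args)),
    stability = do.call(normalize_stability, c(list(data), args)),
    random_ubiquitous = do.call(
      normalize_random_ubiquitous,
      c(list(data, pool = args$pool %||% wide_pool()),
        args[setdiff(names(args), "pool")])
    ),
    all_ubiquitous = {
      pool <- args$pool %||% wide_pool()
      normalize_guide(data, if (is.data.frame(pool)) pool$gene else pool,
                      method_name = "all_ubiquitous")
    },
    total_ubiquitous = do.call(normalize_total_ubiquitous, c(list(data), args)),
    random = do.call(normalize_random, c(list(data), args)),
    tmm = do.call(normalize_tmm, c(list(data), args)),
    quantile = normalize_quantile(data),
    ncs = do.call(normalize_ncs, c(list(data), args)),
    es = do.call(normalize_es, c(list(data), args)),
    abort(paste0("unknown normalization method: ", method))
  )
}
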