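#' Per-sample trimmed gene set
#'
#' Genes observed with nonzero expression in the sample are ranked in
#' ascending expression order (ties broken by gene id) and the upper and
#' lower tails of the distribution are removed: with `n` nonzero genes,
#' ranks `r` with `r > lower_cut * n` and `r <= upper_cut * n` are kept.
#' The default cutoffs retain the 30th-85th percentile band; the wider
#' (0.05, 0.95) profile is used by the Stability and NCS methods.
#'
#' @param data An expression tibble.
#' @param sample Sample id to trim.
#' @param lower_cut,upper_cut Trim fractions, `0 <= lower_cut < upper_cut <= 1`.
#' @return A tibble with columns `gene`, `rank`, `value` for the retained
#'   genes, in rank order.
#' @export
#' @examples
#' m <- tibble::tibble(gene = paste0("g", 1:10), s1 = 0:9, s2 = 1:10)
#' trimmed_set(m, "s1", 0.30, 0.85)
trimmed_set <- function(data, sample, lower_cut = 0.30, upper_cut = 0.85) {
  data <- check_expression(data)
  if (!sample %in% expr_samples(data)) abort(paste0("no such sample: ", sample))
  if (!(lower_cut >= 0 && lower_cut < upper_cut && upper_cut <= 1)) {
    abort("need 0 <= lower_cut < upper_cut <= 1.")
  }
  genes <- expr_genes(data)
  v <- data[[sample]]
  keep <- v > 0
  if (!any(keep)) abort(paste0("sample '", sample, "' has no nonzero genes."))
  genes <- genes[keep]
  v <- v[keep]
  ord <- order(v, genes)
  n <- length(ord)
  r <- seq_len(n)
  sel <- r > lower_cut * n & r <= upper_cut * n
  tibble(gene = genes[ord][sel], rank = r[sel], value = v[ord][sel])
}

#' Ubiquitous genes: intersection of per-sample trimmed sets
#'
#' A gene is ubiquitous when it lies in the trimmed set of (essentially)
#' every sample: nonzero everywhere and never in the trimmed top or bottom
#' ranks of any sample's expression distribution. `min_membership < 1`
#' relaxes the strict intersection to genes present in at least
#' `ceiling(min_membership * N)` trimmed sets; relaxation is never applied
#' silently -- the caller opts in.
#'
#' @inheritParams trimmed_set
#' @param min_membership Minimum fraction of samples whose trimmed set must
#'   contain the gene (default 1: strict intersection).
#' @return A tibble with columns `gene` and `n_sets` (number of trimmed sets
#'   containing the gene), in input gene order. An empty tibble is a legal
#'   result. Attributes `lower_cut`, `upper_cut`, `min_membership` record
#'   the parameters.
#' @export
ubiquitous_genes <- function(data, lower_cut = 0.30, upper_cut = 0.85,
                             min_membership = 1) {
  data <- check_expression(data)
  if (!(min_membership > 0 && min_membership <= 1)) {
    abort("`min_membership` must be in (0, 1].")
  }
  samples <- expr_samples(data)
  counts <- integer(nrow(data))
  names(counts) <- expr_genes(data)
  for (s in samples) {
    ts <- trimmed_set(data, s, lower_cut, upper_cut)
    counts[ts$gene] <- counts[ts$gene] + 1L
  }
  need <- ceiling(min_membership * length(samples))
  out <- tibble(gene = names(counts), n_sets = unname(counts)) |>
    dplyr::filter(.data$n_sets >= need)
  attr(out, "lower_cut") <- lower_cut
  attr(out, "upper_cut") <- upper_cut
  attr(out, "min_membership") <- min_membership
  out
}

#' Sample-specific genes (Jongeneel specificity)
#'
#' A gene is specific to a sample when its expression there strictly exceeds
#' the sum of its expression in all other samples combined, and the gene is
#' observed (nonzero) in at least half of the samples.
#'
#' @param data An expression tibble.
#' @return A tibble with columns `gene`, `sample` (the sample the gene is
#'   specific to), `value`, and `other_total`.
#' @export
specific_genes <- function(data) {
  data <- check_expression(data)
  m <- expr_matrix(data)
  n <- ncol(m)
  top <- max.col(m, ties.method = "first")
  top_val <- m[cbind(seq_len(nrow(m)), top)]
  other <- rowSums(m) - top_val
  present <- rowSums(m > 0)
  sel <- top_val > other & present >= ceiling(n / 2)
  tibble(
    gene = rownames(m)[sel],
    sample = colnames(m)[top[sel]],
    value = unname(top_val[sel]),
    other_total = unname(other[sel])
  )
}

#' Cap a gene pool at the most highly expressed members
#'
#' Keeps the `n_max` genes with the highest geometric mean expression across
#' samples (ties broken by gene id). Genes with any zero value are excluded
#' before ranking since their geometric mean is undefined. Used to cap the
#' ubiquitous pool before the quadratic pairwise stage of NCS.
#'
#' @param data An expression tibble.
#' @param genes Character vector of candidate gene ids (or a tibble with a
#'   `gene` column).
#' @param n_max Maximum pool size.
#' @return A tibble with columns `gene` and `geo_mean`, in decreasing
#'   `geo_mean` order.
#' @export
top_expressed_subset <- function(data, genes, n_max = 2000L) {
  data <- check_expression(data)
  if (is.data.frame(genes)) genes <- genes$gene
  if (n_max < 1) abort("`n_max` must be at least 1.")
  m <- expr_matrix(data)
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) abort(paste0("gene not in matrix: ", missing[1L]))
  m <- m[genes, , drop = FALSE]
  ok <- rowSums(m <= 0) == 0
  m <- m[ok, , drop = FALSE]
  gm <- exp(rowMeans(log(m)))
  ord <- order(-gm, rownames(m))
  keep <- head(ord, n_max)
  tibble(gene = rownames(m)[keep], geo_mean = unname(gm[keep]))
}
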