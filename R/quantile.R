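#' Quantile normalization
#'
#' The one rank-based, non-factor method: each column is sorted ascending
#' (zeros included, ties broken by gene id), the mean value at each rank
#' across samples is computed, and every gene receives the mean at its rank.
#' Genes tied on input value within a column receive the average of the
#' rank-means they span, so equal inputs map to equal outputs. After
#' normalization every column has an identical sorted value vector and the
#' grand sum of the matrix is preserved; within-column rank order is
#' unchanged, but within-sample expression ratios are not (the method is
#' nonlinear).
#'
#' @param data An expression tibble.
#' @return A `tx_norm` result with `factors = NULL`.
#' @export
normalize_quantile <- function(data) {
  data <- check_expression(data)
  m <- expr_matrix(data)
  genes <- rownames(m)
  n <- nrow(m)
  ords <- lapply(seq_len(ncol(m)), function(k) order(m[, k], genes))
  sorted <- vapply(seq_len(ncol(m)), function(k) m[ords[[k]], k], double(n))
  rank_means <- rowMeans(sorted)
  out <- m
  for (k in seq_len(ncol(m))) {
    o <- ords[[k]]
    # average the rank-means spanned by each run of tied input values
    out[o, k] <- stats::ave(rank_means, m[o, k], FUN = mean)
  }
  new_tx_norm("quantile", expr_rebuild(data, out), factors = NULL,
              details = list(rank_means = rank_means))
}
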