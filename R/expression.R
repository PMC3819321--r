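#' Validate an expression table
#'
#' The package represents a gene-by-sample expression matrix as a tibble whose
#' first column holds unique gene identifiers (character) and whose remaining
#' columns hold one numeric vector of non-negative expression values per
#' sample. Expression is measured in average fold coverage per transcribed
#' base or in raw counts; unobserved genes are encoded as 0, never as `NA`.
#'
#' @param data A data frame in the layout described above.
#' @param min_samples,min_genes Minimum dimensions required by the caller.
#' @return `data`, invisibly, as a tibble; an error describes the first
#'   offending cell otherwise.
#' @export
#' @examples
#' check_expression(tibble::tibble(gene = c("a", "b"), s1 = 1:2, s2 = 3:4))
check_expression <- function(data, min_samples = 2L, min_genes = 2L) {
  if (!is.data.frame(data) || ncol(data) < 2L) {
    abort("`data` must be a data frame with a gene-id column plus at least one sample column.")
  }
  samples <- names(data)[-1L]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample id: ", samples[duplicated(samples)][1L]))
  }
  data <- as_tibble(data)
  genes <- data[[1L]]
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id: ", genes[duplicated(genes)][1L]))
  }
  if (length(samples) < min_samples) {
    abort(paste0("at least ", min_samples, " samples are required."))
  }
  if (nrow(data) < min_genes) {
    abort(paste0("at least ", min_genes, " genes are required."))
  }
  for (s in samples) {
    v <- data[[s]]
    if (!is.numeric(v)) {
      abort(paste0("sample '", s, "' contains non-numeric values."))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(paste0(
        "negative or non-finite value at gene '", genes[bad[1L]],
        "', sample '", s, "' (", format(v[bad[1L]]), "); ",
        "absent observations must be encoded as 0."
      ))
    }
  }
  invisible(data)
}

# gene ids of an expression table
expr_genes <- function(data) as.character(data[[1L]])

# sample ids of an expression table
expr_samples <- function(data) names(data)[-1L]

# dense numeric matrix (genes x samples) with dimnames
expr_matrix <- function(data) {
  m <- as.matrix(data[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr_genes(data)
  m
}

# rebuild an expression tibble from a matrix, keeping the original id column name
expr_rebuild <- function(data, m) {
  out <- as_tibble(as.data.frame(m))
  names(out) <- colnames(m)
  dplyr::bind_cols(data[, 1L, drop = FALSE], out)
}

#' Construct or validate a scaling-factor table
#'
#' Scaling factors are one positive multiplier per sample; applying them
#' multiplies every expression value of sample `k` by `factor[k]`. The
#' `adjusted` attribute records whether the product-1 canonicalization of
#' [adjust_factors()] has been applied.
#'
#' @param x A data frame with columns `sample` and `factor`, or a numeric
#'   vector (optionally named by sample) combined with `samples`.
#' @param samples Sample ids used when `x` is an unnamed numeric vector.
#' @param adjusted Logical flag stored on the result.
#' @return A tibble with columns `sample` (character) and `factor` (double).
#' @export
#' @examples
#' scaling_factors(c(s1 = 2, s2 = 0.5))
scaling_factors <- function(x, samples = NULL, adjusted = FALSE) {
  if (is.data.frame(x)) {
    if (!all(c("sample", "factor") %in% names(x))) {
      abort("a factor table needs `sample` and `factor` columns.")
    }
    out <- tibble(sample = as.character(x$sample), factor = as.double(x$factor))
  } else if (is.numeric(x)) {
    ids <- samples %||% names(x)
    if (is.null(ids)) abort("numeric factors need names or a `samples` vector.")
    out <- tibble(sample = as.character(ids), factor = as.double(x))
  } else {
    abort("`x` must be a data frame or a numeric vector.")
  }
  if (anyDuplicated(out$sample)) abort("duplicate sample id in factors.")
  if (any(!is.finite(out$factor) | out$factor <= 0)) {
    abort("all scaling factors must be positive and finite.")
  }
  attr(out, "adjusted") <- isTRUE(adjusted)
  out
}

# named vector of factors aligned to the samples of `data`
factor_vector <- function(factors, data = NULL) {
  factors <- scaling_factors(factors)
  f <- setNames(factors$factor, factors$sample)
  if (!is.null(data)) {
    samples <- expr_samples(data)
    if (!setequal(samples, names(f)) || length(f) != length(samples)) {
      abort("factor table does not cover exactly the samples of the matrix.")
    }
    f <- f[samples]
  }
  f
}

# scale every column of an expression table by its factor
apply_factors <- function(data, factors) {
  f <- factor_vector(factors, data)
  m <- expr_matrix(data)
  expr_rebuild(data, sweep(m, 2L, f, `*`))
}
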