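# Container for the outcome of a normalization method: the scaled matrix,
# the per-sample factors (absent for quantile normalization), and the
# parameters/guides that produced them.
new_tx_norm <- function(method, data, factors = NULL, details = list()) {
  structure(
    list(method = method, data = data, factors = factors, details = details),
    class = "tx_norm"
  )
}

#' @export
print.tx_norm <- function(x, ...) {
  cat("<tx_norm> method:", x$method, "\n")
  cat("  ", nrow(x$data), "genes x", length(expr_samples(x$data)), "samples\n")
  if (!is.null(x$factors)) {
    f <- factor_vector(x$factors)
    cat("  factors:", paste0(
      names(f), "=", formatC(f, digits = 4, format = "fg"),
      collapse = ", "
    ), "\n")
  } else {
    cat("  rank-based method: no per-sample factors\n")
  }
  invisible(x)
}

#' Tidy a normalization result
#'
#' `tidy()` returns the per-sample scaling factors (an empty tibble for
#' quantile normalization, which has none); `glance()` returns a one-row
#' summary.
#'
#' @param x A `tx_norm` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tx_norm <- function(x, ...) {
  if (is.null(x$factors)) {
    return(tibble(sample = character(), factor = double(), method = character()))
  }
  dplyr::mutate(scaling_factors(x$factors), method = x$method)
}

#' @rdname tidy.tx_norm
#' @export
glance.tx_norm <- function(x, ...) {
  tibble(
    method = x$method,
    n_genes = nrow(x$data),
    n_samples = length(expr_samples(x$data)),
    n_guides = length(x$details$guides %||% character()),
    adjusted = isTRUE(attr(x$factors, "adjusted"))
  )
}

#' Plot the scaling factors of a normalization result
#'
#' @param object A `tx_norm` object with factors.
#' @param ... Unused.
#' @return A ggplot: per-sample log2 scaling factors.
#' @export
autoplot.tx_norm <- function(object, ...) {
  if (is.null(object$factors)) {
    abort("quantile normalization produces no factors to plot.")
  }
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = log2(.data$factor))) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "log2 scaling factor",
      title = paste0("Scaling factors: ", object$method)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
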