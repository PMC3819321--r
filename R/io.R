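#' Read an expression matrix from a delimited text file
#'
#' The file must carry a header row of sample identifiers; the first column
#' holds gene identifiers and every remaining cell a non-negative number.
#' Row and column order are preserved exactly.
#'
#' @param path Path to a TSV (or CSV) file.
#' @param delim Field delimiter; tab by default, `","` for CSV.
#' @return A validated expression tibble (see [check_expression()]).
#' @export
read_expression <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  data <- suppressWarnings(readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(
      readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE, na = character(),
    name_repair = "minimal"
  ))
  if (nrow(readr::problems(data)) > 0) {
    p <- readr::problems(data)
    abort(paste0(
      "non-numeric cell at row ", p$row[1L], ", column ", p$col[1L],
      " of ", path
    ))
  }
  check_expression(data)
}

#' Write an expression matrix as a delimited text file
#'
#' @param data An expression tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param digits Significant digits written for expression values.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, delim = "\t", digits = 6L) {
  data <- check_expression(data)
  m <- expr_matrix(data)
  out <- expr_rebuild(data, signif(m, digits))
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a gene list, optionally weighted
#'
#' One gene id per line; an optional tab-separated second column carries a
#' positive guide weight (default 1). Used for housekeeping-gene panels and
#' other guide-gene sets.
#'
#' @param path Path to the list file.
#' @return A tibble with columns `gene` and `weight`, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty gene list: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1L), 1L)
  weight <- vapply(parts, function(p) {
    if (length(p) < 2L) return(1)
    w <- suppressWarnings(as.double(p[[2L]]))
    if (!is.finite(w) || w <= 0) {
      abort(paste0("gene '", p[[1L]], "': weight must be a positive number, got '", p[[2L]], "'"))
    }
    w
  }, double(1L))
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene in list: ", genes[duplicated(genes)][1L]))
  }
  tibble(gene = genes, weight = weight)
}

#' Read or write a scaling-factor table
#'
#' Two-column TSV: sample id, factor.
#'
#' @param path Path to the factor file.
#' @return For `read_factors()`, a factor tibble (see [scaling_factors()]).
#' @export
read_factors <- function(path) {
  x <- readr::read_tsv(path, col_types = "cd", progress = FALSE, show_col_types = FALSE)
  names(x) <- c("sample", "factor")
  scaling_factors(x)
}

#' @rdname read_factors
#' @param factors A factor tibble or named numeric vector.
#' @export
write_factors <- function(factors, path) {
  factors <- scaling_factors(factors)
  readr::write_tsv(factors, path, progress = FALSE)
  invisible(path)
}
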