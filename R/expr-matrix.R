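#' Gene-by-sample expression matrix with a declared scale
#'
#' Thin container pairing a numeric gene-by-sample matrix with the scale
#' its values are on. Downstream operations declare which scale they need
#' and convert explicitly via [as_linear()] / [as_log2p1()], so no function
#' ever has to guess whether a matrix holds linear intensities or
#' log2(x + 1) values.
#'
#' @param values Numeric matrix; rownames are gene ids, colnames sample ids.
#'   Both id sets must be unique and non-empty; all values must be finite,
#'   and non-negative when `scale` is `"linear"`.
#' @param scale `"linear"` or `"log2p1"` (values are log2(x + 1)).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `scale`.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expr_matrix(m, "linear")
#' dim(em)
#' @export
expr_matrix <- function(values, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (scale == "linear" && any(values < 0))
    stop("negative values are not allowed on the linear scale")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Convert an expression matrix to the linear scale
#'
#' @param x An [expr_matrix].
#' @return An `expr_matrix` on the linear scale (identity if already linear;
#'   `2^v - 1` otherwise).
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "linear") return(x)
  v <- 2^x$values - 1
  v[v < 0] <- 0  # guard against tiny negative rounding residue
  expr_matrix(v, "linear")
}

#' Convert an expression matrix to the log2(x + 1) scale
#'
#' @param x An [expr_matrix].
#' @return An `expr_matrix` on the `log2p1` scale.
#' @export
as_log2p1 <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "log2p1") return(x)
  expr_matrix(log2(x$values + 1), "log2p1")
}
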