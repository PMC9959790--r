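#' Fit a column scaler
#'
#' Divides every column by its (n-1) sample standard deviation, optionally
#' subtracting the column mean first. Constant columns are rejected: a
#' variable with no variance carries no chemometric information and would
#' divide by zero.
#'
#' @param x numeric matrix, samples in rows.
#' @param center subtract column means before dividing? Default `FALSE`
#'   (plain sd-scaling).
#' @return A list of class `col_scaler` with `center` (numeric vector or
#'   `NULL`) and `sd`.
#' @export
col_scaler <- function(x, center = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least two rows to estimate scale", call. = FALSE)
  mu <- colMeans(x)
  sds <- sqrt(pmax(0, (colSums(x^2) - n * mu^2) / (n - 1)))
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(center = if (center) mu else NULL, sd = sds),
            class = "col_scaler")
}

#' Apply (or fit-and-apply) sd-scaling to a matrix
#'
#' @param x numeric matrix.
#' @param scaler a `col_scaler`; when missing one is fit on `x`.
#' @param center passed to [col_scaler()] when fitting.
#' @return The scaled matrix with the scaler attached as attribute
#'   `"scaler"`.
#' @export
scale_matrix <- function(x, scaler = NULL, center = FALSE) {
  x <- as.matrix(x)
  if (is.null(scaler)) scaler <- col_scaler(x, center = center)
  if (length(scaler$sd) != ncol(x))
    stop("variable mismatch: scaler has ", length(scaler$sd),
         " columns, data has ", ncol(x), call. = FALSE)
  if (!is.null(scaler$center)) x <- sweep(x, 2, scaler$center, `-`)
  out <- sweep(x, 2, scaler$sd, `/`)
  attr(out, "scaler") <- scaler
  out
}
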