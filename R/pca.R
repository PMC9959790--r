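#' Principal component analysis of an sd-scaled matrix
#'
#' Columns are divided by their standard deviations (uncentred by default,
#' so the first component absorbs the common positive offset of
#' concentration data) and the scaled matrix is decomposed by SVD. The
#' explained percentage of component k is \eqn{100\,\sigma_k^2 /
#' \sum_j \sigma_j^2} over the full decomposition of the same matrix.
#'
#' @param x numeric matrix, samples in rows.
#' @param n_pc number of components to retain (default: full rank).
#' @param center subtract column means before scaling? Default `FALSE`.
#' @param scale divide columns by their sd? Default `TRUE`.
#' @return An object of class `pca_sd` with `scores`, `loadings`
#'   (orthonormal columns), `explained_pct`, `singular_values`, `scaler`,
#'   `center`.
#' @export
pca_sd <- function(x, n_pc = NULL, center = FALSE, scale = TRUE) {
  x <- as.matrix(x)
  full <- min(dim(x))
  n_pc <- n_pc %||% full
  if (n_pc > full)
    stop("n_pc exceeds min(n, p) = ", full, call. = FALSE)
  scaler <- if (scale) col_scaler(x, center = center) else
    structure(list(center = if (center) colMeans(x) else NULL,
                   sd = rep(1, ncol(x))), class = "col_scaler")
  xs <- scale_matrix(x, scaler)
  sv <- svd(xs)
  expl <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(scores = sv$u[, seq_len(n_pc), drop = FALSE] %*%
                   diag(sv$d[seq_len(n_pc)], n_pc),
                 loadings = sv$v[, seq_len(n_pc), drop = FALSE],
                 explained_pct = expl[seq_len(n_pc)],
                 singular_values = sv$d,
                 scaler = scaler, center = center, n_pc = n_pc),
            class = "pca_sd")
}

#' @export
print.pca_sd <- function(x, ...) {
  cat(sprintf("<pca_sd> %d components retained\n", x$n_pc))
  cat("explained %:",
      paste(sprintf("%.2f", x$explained_pct), collapse = " "), "\n")
  invisible(x)
}
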