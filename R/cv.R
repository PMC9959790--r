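#' Contiguous block assignment
#'
#' Splits `n` samples, in their stored row order, into `k` contiguous
#' blocks of near-equal size (sizes differ by at most one, larger blocks
#' first).
#'
#' @param n number of samples.
#' @param k number of blocks.
#' @return Integer vector of block indices, length `n`.
#' @export
contiguous_blocks <- function(n, k) {
  stopifnot(k >= 2, n >= k)
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep(seq_len(k), sizes)
}

#' Contiguous-block cross-validation of a PLS-DA model
#'
#' Cross-validates the latent-variable count: samples are split in row
#' order into contiguous blocks; each block in turn is held out, a model
#' is refit on the remainder at every component count, and the held-out
#' predictions accumulate into per-component RMSECV. The chosen model
#' size is the RMSECV argmin (smallest count on ties). RMSEC and R2 come
#' from the full-data fit; Q2 = 1 - PRESS/TSS with TSS taken about the
#' mean of y over the cross-validated samples.
#'
#' @param x numeric matrix, samples in rows (row order defines the
#'   blocks).
#' @param y class vector as in [pls_da()].
#' @param n_blocks number of contiguous blocks (default 7).
#' @param max_lv maximum latent-variable count examined (default
#'   `min(n - 1, p)` capped by the smallest training fold).
#' @param center,scale passed to [pls_da()].
#' @return Object of class `cv_pls`: `rmsecv`, `rmsec`, `q2`, `r2` (one
#'   entry per component count), `ncomp` (chosen), `blocks`, and the full
#'   fit `model` at the chosen size.
#' @export
cv_pls <- function(x, y, n_blocks = 7, max_lv = NULL, center = TRUE,
                   scale = TRUE) {
  x <- as.matrix(x)
  y <- coerce_class01(y)
  n <- nrow(x); p <- ncol(x)
  blocks <- contiguous_blocks(n, n_blocks)
  min_train <- n - max(tabulate(blocks))
  max_lv <- min(max_lv %||% Inf, min_train - 1L, p)
  if (max_lv < 1L) stop("no admissible latent-variable count", call. = FALSE)
  press <- numeric(max_lv)
  yhat_cv <- matrix(NA_real_, n, max_lv)
  used <- rep(FALSE, n)
  for (b in seq_len(n_blocks)) {
    hold <- blocks == b
    ytr <- y[!hold]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %d skipped: training remainder is single-class", b))
      next
    }
    fit <- pls_da(x[!hold, , drop = FALSE], ytr, ncomp = max_lv,
                  center = center, scale = scale)
    yh <- fit$ybar + scale_matrix(x[hold, , drop = FALSE], fit$scaler) %*% fit$B
    yhat_cv[hold, seq_len(fit$ncomp)] <- yh
    if (fit$ncomp < max_lv)       # rank-deficient fold: reuse last component
      yhat_cv[hold, seq.int(fit$ncomp + 1L, max_lv)] <- yh[, fit$ncomp]
    used[hold] <- TRUE
  }
  if (!any(used)) stop("all cross-validation folds degenerate", call. = FALSE)
  ycv <- y[used]
  press <- colSums((yhat_cv[used, , drop = FALSE] - ycv)^2)
  rmsecv <- sqrt(press / sum(used))
  tss <- sum((ycv - mean(y))^2)
  q2 <- 1 - press / tss
  full <- pls_da(x, y, ncomp = max_lv, center = center, scale = scale)
  rmsec <- r2 <- numeric(max_lv)
  tss_full <- sum((y - mean(y))^2)
  fhat <- full$ybar + scale_matrix(x, full$scaler) %*% full$B
  for (a in seq_len(full$ncomp)) {
    rmsec[a] <- sqrt(mean((fhat[, a] - y)^2))
    r2[a] <- 1 - sum((y - fhat[, a])^2) / tss_full
  }
  if (full$ncomp < max_lv) {
    rmsec[seq.int(full$ncomp + 1L, max_lv)] <- rmsec[full$ncomp]
    r2[seq.int(full$ncomp + 1L, max_lv)] <- r2[full$ncomp]
  }
  ncomp <- which.min(rmsecv)          # first minimum on ties
  model <- pls_da(x, y, ncomp = max(1L, min(ncomp, full$ncomp)),
                  center = center, scale = scale)
  structure(list(rmsecv = rmsecv, rmsec = rmsec, q2 = q2, r2 = r2,
                 ncomp = ncomp, blocks = blocks, model = model,
                 n_blocks = n_blocks),
            class = "cv_pls")
}

#' @export
print.cv_pls <- function(x, ...) {
  cat(sprintf("<cv_pls> %d contiguous blocks, %d component counts examined\n",
              x$n_blocks, length(x$rmsecv)))
  cat(sprintf("  chosen LVs = %d: RMSECV %.4f, RMSEC %.4f, Q2 %.4f, R2 %.4f\n",
              x$ncomp, x$rmsecv[x$ncomp], x$rmsec[x$ncomp],
              x$q2[x$ncomp], x$r2[x$ncomp]))
  invisible(x)
}

#' @export
plot.cv_pls <- function(x, ...) {
  a <- seq_along(x$rmsecv)
  plot(a, x$rmsecv, type = "b", pch = 16, xlab = "latent variables",
       ylab = "RMSE", ylim = range(c(x$rmsecv, x$rmsec)), ...)
  lines(a, x$rmsec, type = "b", pch = 1, lty = 2)
  graphics::abline(v = x$ncomp, col = "grey60", lty = 3)
  graphics::legend("topright", c("RMSECV", "RMSEC"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
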