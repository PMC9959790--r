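#' Fit a PLS-DA model
#'
#' Partial least squares regression of a 0/1 class-membership vector on
#' the (autoscaled) concentration matrix, fit by the sequential NIPALS
#' decomposition. With a single response the NIPALS weight update is
#' closed-form and deterministic: each latent variable's weight vector is
#' the normalised covariance X'y of the deflated data, so no random
#' initialisation is involved. Class labels are predicted afterwards by
#' thresholding the continuous estimate (see [classify()]).
#'
#' @param x numeric matrix, samples in rows.
#' @param y class vector: numeric 0/1, logical, or a 2-level factor whose
#'   first level is coded 1 (positive).
#' @param ncomp number of latent variables (1 <= ncomp <= min(n-1, p)).
#' @param center subtract column means (and the y mean) before fitting?
#'   Default `TRUE` (autoscaling, standard chemometric practice).
#' @param scale divide columns by their sd? Default `TRUE`.
#' @return Object of class `plsda`: weights `W`, loadings `P`, y-loadings
#'   `q`, scores `T`, regression vectors per component count, scaler,
#'   fitted values and training labels.
#' @export
pls_da <- function(x, y, ncomp, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  y <- coerce_class01(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in y", call. = FALSE)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, p)", call. = FALSE)
  scaler <- if (scale) col_scaler(x, center = center) else
    structure(list(center = if (center) colMeans(x) else NULL,
                   sd = rep(1, p)), class = "col_scaler")
  X <- scale_matrix(x, scaler)
  ybar <- if (center) mean(y) else 0
  yc <- y - ybar
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- X; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) { # no covariance left
      ncomp <- a - 1L
      if (ncomp == 0L) stop("y has no covariance with x", call. = FALSE)
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      break
    }
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    pp <- drop(crossprod(Xd, tt)) / tt2
    qq <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pp)
    yd <- yd - tt * qq
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
  }
  # regression vector on the scaled-x scale for each component count
  R <- W %*% solve(crossprod(P, W))          # T = X R
  B <- sapply(seq_len(ncomp), function(a)
    drop(R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]))
  B <- matrix(B, nrow = p)
  fitted <- ybar + drop(X %*% B[, ncomp])
  structure(list(ncomp = ncomp, W = W, P = P, q = q, scores = Tm, B = B,
                 scaler = scaler, ybar = ybar, center = center,
                 y = y, fitted.values = fitted,
                 variables = colnames(x) %||% paste0("V", seq_len(p))),
            class = "plsda")
}

coerce_class01 <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
    as.numeric(y == levels(y)[1])
  } else if (is.logical(y)) {
    as.numeric(y)
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1)))
      stop("numeric y must be coded 0/1", call. = FALSE)
    y
  }
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d latent variable(s), %d variables, %d samples\n",
              x$ncomp, nrow(x$B), length(x$y)))
  cat(sprintf("  RMSEC = %.4f\n", sqrt(mean((x$fitted.values - x$y)^2))))
  invisible(x)
}

#' @export
coef.plsda <- function(object, ncomp = object$ncomp, raw = FALSE, ...) {
  b <- object$B[, ncomp]
  names(b) <- object$variables
  if (!raw) return(b)
  braw <- b / object$scaler$sd
  icpt <- object$ybar -
    if (!is.null(object$scaler$center)) sum(object$scaler$center * braw) else 0
  c("(Intercept)" = icpt, braw)
}

#' Predict continuous class estimates from a PLS-DA model
#'
#' @param object a [pls_da()] fit.
#' @param newdata matrix with the model's variables (defaults to the
#'   training data).
#' @param ncomp number of latent variables to use (default: all fitted).
#' @param type `"response"` for the continuous estimate, `"class"` to
#'   threshold it with [classify()].
#' @param threshold classification threshold when `type = "class"`.
#' @param ... unused.
#' @return Numeric vector of estimates, or 0/1 labels for
#'   `type = "class"`.
#' @export
predict.plsda <- function(object, newdata = NULL, ncomp = object$ncomp,
                          type = c("response", "class"), threshold = 0.4, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    yhat <- if (ncomp == object$ncomp) object$fitted.values else NULL
  } else yhat <- NULL
  if (is.null(yhat)) {
    X <- as.matrix(newdata %||% stop("newdata required"))
    if (ncol(X) != nrow(object$B))
      stop("variable mismatch: model has ", nrow(object$B),
           " variables, newdata has ", ncol(X), call. = FALSE)
    Xs <- scale_matrix(X, object$scaler)
    yhat <- object$ybar + drop(Xs %*% object$B[, ncomp])
  }
  if (type == "class") classify(yhat, threshold) else yhat
}

#' @export
fitted.plsda <- function(object, ...) object$fitted.values

#' @export
residuals.plsda <- function(object, ...) object$y - object$fitted.values

#' @export
summary.plsda <- function(object, ...) {
  rmsec <- sqrt(mean((object$fitted.values - object$y)^2))
  tss <- sum((object$y - mean(object$y))^2)
  r2 <- 1 - sum((object$y - object$fitted.values)^2) / tss
  cat(sprintf("PLS-DA fit: %d latent variables, %d variables\n",
              object$ncomp, nrow(object$B)))
  cat(sprintf("  RMSEC %.4f, R2 %.4f\n", rmsec, r2))
  cm <- confusion(object$y, classify(object$fitted.values))
  print(cm)
  invisible(list(rmsec = rmsec, r2 = r2, confusion = cm))
}
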