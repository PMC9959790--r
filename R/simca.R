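#' Fit a one-class SIMCA model
#'
#' Soft independent modelling of class analogy: a PCA model is fit on the
#' members of the target class only (class-local autoscaling), and a new
#' sample is accepted when it falls inside the class acceptance boundary
#' in (leverage, residual) space.
#'
#' Two statistics describe a sample relative to the class model with k
#' retained components: the leverage \eqn{h_i = 1/n + \sum_k
#' t_{ik}^2 / (t_k' t_k)} (a Hotelling-type distance inside the score
#' space) and the Q residual \eqn{Q_i = \|x_i - \hat x_i\|^2} (squared
#' reconstruction error orthogonal to it). Critical limits: leverage from
#' the F distribution on (k, n - k) degrees of freedom (prediction form,
#' so new in-class samples are covered), Q from the Jackson-Mudholkar
#' approximation on the discarded eigenvalues.
#'
#' The boundary is rectangular — a sample must pass both limits — so each
#' limit is taken at the Sidak-adjusted per-statistic level
#' \eqn{1-(1-\alpha)^{1/2}}; the score-space and residual statistics are
#' independent for Gaussian data, making the joint in-class acceptance
#' approximately \eqn{1-\alpha}. `limit_rule = "combined"` instead accepts
#' when \eqn{\sqrt{(Q/Q_{crit})^2 + (h/h_{crit})^2} \le 1}.
#'
#' @param x_class matrix of class-member rows (at least `ncomp + 2`).
#' @param ncomp number of principal components retained.
#' @param alpha joint significance level of the boundary (default 0.05,
#'   i.e. a 95 percent acceptance region).
#' @param center,scale class-local autoscaling flags (defaults `TRUE`).
#' @param limit_rule `"rectangular"` (default) or `"combined"`.
#' @return Object of class `simca`: loadings, eigenvalues, critical
#'   limits, scaler, and the training (h, Q) table.
#' @export
simca <- function(x_class, ncomp, alpha = 0.05, center = TRUE, scale = TRUE,
                  limit_rule = c("rectangular", "combined")) {
  limit_rule <- match.arg(limit_rule)
  x_class <- as.matrix(x_class)
  n <- nrow(x_class); p <- ncol(x_class)
  if (n < ncomp + 2L)
    stop("class needs at least ncomp + 2 members", call. = FALSE)
  stopifnot(ncomp >= 1L, alpha > 0, alpha < 1)
  scaler <- if (scale) col_scaler(x_class, center = center) else
    structure(list(center = if (center) colMeans(x_class) else NULL,
                   sd = rep(1, p)), class = "col_scaler")
  Xs <- scale_matrix(x_class, scaler)
  sv <- svd(Xs)
  if (ncomp > sum(sv$d > max(dim(Xs)) * .Machine$double.eps * sv$d[1]))
    stop("ncomp exceeds the rank of the class data", call. = FALSE)
  P <- sv$v[, seq_len(ncomp), drop = FALSE]
  d2 <- sv$d[seq_len(ncomp)]^2                      # t_k' t_k
  lambda_all <- sv$d^2 / (n - 1)
  lambda_out <- lambda_all[-seq_len(ncomp)]
  # per-statistic confidence under the rectangular rule (Sidak split)
  a_each <- if (limit_rule == "rectangular") 1 - sqrt(1 - alpha) else alpha
  h_crit <- 1 / n + ncomp * (n + 1) * (n - 1) /
    (n * (n - ncomp)) * qf(1 - a_each, ncomp, n - ncomp) / (n - 1)
  q_crit <- jackson_mudholkar(lambda_out, a_each)
  Tm <- Xs %*% P
  h <- 1 / n + rowSums(sweep(Tm^2, 2, d2, `/`))
  Q <- rowSums((Xs - Tm %*% t(P))^2)
  structure(list(ncomp = ncomp, alpha = alpha, limit_rule = limit_rule,
                 loadings = P, score_ss = d2, eigenvalues = lambda_all,
                 n_train = n, scaler = scaler,
                 h_crit = h_crit, q_crit = q_crit,
                 train = data.frame(leverage = h, residual = Q),
                 variables = colnames(x_class) %||% paste0("V", seq_len(p))),
            class = "simca")
}

# Jackson-Mudholkar upper quantile for the squared reconstruction error,
# from the discarded eigenvalues. Degenerate cases (no or numerically
# zero discarded variance) give a tiny positive limit so that exact-rank
# models accept their own training samples.
jackson_mudholkar <- function(lambda_out, alpha) {
  lambda_out <- lambda_out[lambda_out > 0]
  if (!length(lambda_out)) return(.Machine$double.eps)
  th1 <- sum(lambda_out); th2 <- sum(lambda_out^2); th3 <- sum(lambda_out^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  ca <- qnorm(1 - alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
           1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' @export
print.simca <- function(x, ...) {
  cat(sprintf("<simca> %d PCs on %d class members, alpha = %.2f (%s limits)\n",
              x$ncomp, x$n_train, x$alpha, x$limit_rule))
  cat(sprintf("  critical leverage %.4f, critical Q %.4f\n",
              x$h_crit, x$q_crit))
  invisible(x)
}

#' Score samples against a SIMCA class model
#'
#' @param object a [simca()] model.
#' @param newdata matrix with the model's variables.
#' @param ... unused.
#' @return data.frame with per-sample `leverage`, `residual` and
#'   `accepted`.
#' @export
predict.simca <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$loadings))
    stop("variable mismatch: model has ", nrow(object$loadings),
         " variables, newdata has ", ncol(X), call. = FALSE)
  Xs <- scale_matrix(X, object$scaler)
  Tm <- Xs %*% object$loadings
  h <- 1 / object$n_train + rowSums(sweep(Tm^2, 2, object$score_ss, `/`))
  Q <- rowSums((Xs - Tm %*% t(object$loadings))^2)
  acc <- if (object$limit_rule == "rectangular")
    (h <= object$h_crit) & (Q <= object$q_crit)
  else
    sqrt((Q / object$q_crit)^2 + (h / object$h_crit)^2) <= 1
  data.frame(leverage = h, residual = Q, accepted = acc)
}

#' @export
plot.simca <- function(x, newdata = NULL, ...) {
  tab <- if (is.null(newdata)) x$train else predict(x, newdata)
  plot(tab$leverage, tab$residual, xlab = "sample leverage",
       ylab = "Q residual", ...)
  graphics::abline(v = x$h_crit, h = x$q_crit, lty = 2, col = "grey40")
  invisible(x)
}

#' Per-variable leverages of a SIMCA model
#'
#' Row sums of the squared loadings over the retained components: how much
#' each analyte contributes to the class subspace. Values lie in [0, 1]
#' and sum to the number of retained components.
#'
#' @param m a [simca()] model.
#' @return Named numeric vector.
#' @export
simca_variable_leverage <- function(m) {
  stopifnot(inherits(m, "simca"))
  lev <- rowSums(m$loadings^2)
  names(lev) <- m$variables
  lev
}

#' PRESS-based component selection for SIMCA
#'
#' Contiguous-block cross-validation inside the class. For every
#' component count k and every held-out sample, each variable in turn is
#' predicted from the remaining variables through the training loadings
#' (the held-out sample's scores are estimated without the target
#' variable, so the prediction is honest) and PRESS_k accumulates the
#' squared prediction errors. Unlike a plain projection residual — which
#' decreases monotonically in k by construction — this element-wise PRESS
#' turns up again once components start fitting noise, so its argmin is a
#' usable model size (smallest k on ties). When an out-of-class set is
#' supplied, the alternative criterion — the component count maximising
#' the geometric mean of cross-validated sensitivity and specificity — is
#' reported alongside.
#'
#' @param x_class class-member matrix.
#' @param max_pc largest component count examined (truncated with a
#'   warning if a fold cannot support it).
#' @param n_blocks contiguous blocks (default 7).
#' @param x_out optional out-of-class matrix for the geometric-mean
#'   criterion.
#' @param alpha boundary level used for the geometric-mean criterion.
#' @param center,scale autoscaling flags.
#' @return List of class `simca_press`: `press` (one entry per k),
#'   `ncomp` (PRESS argmin), and when `x_out` is given `gmean`,
#'   `ncomp_gmean`.
#' @export
simca_cv_press <- function(x_class, max_pc, n_blocks = 7, x_out = NULL,
                           alpha = 0.05, center = TRUE, scale = TRUE) {
  x_class <- as.matrix(x_class)
  n <- nrow(x_class)
  blocks <- contiguous_blocks(n, n_blocks)
  min_train <- n - max(tabulate(blocks))
  kmax <- min(max_pc, min_train - 1L, ncol(x_class))
  if (kmax < max_pc)
    warning("max_pc truncated to ", kmax, " by fold size")
  press <- numeric(kmax)
  sens_k <- matrix(NA_real_, n_blocks, kmax)
  spec_k <- matrix(NA_real_, n_blocks, kmax)
  for (b in seq_len(n_blocks)) {
    hold <- blocks == b
    xtr <- x_class[!hold, , drop = FALSE]
    scaler <- if (scale) col_scaler(xtr, center = center) else
      structure(list(center = if (center) colMeans(xtr) else NULL,
                     sd = rep(1, ncol(xtr))), class = "col_scaler")
    Xs <- scale_matrix(xtr, scaler)
    sv <- svd(Xs)
    Xh <- scale_matrix(x_class[hold, , drop = FALSE], scaler)
    p <- ncol(Xh)
    for (k in seq_len(kmax)) {
      P <- sv$v[, seq_len(k), drop = FALSE]
      for (j in seq_len(p)) {
        Pj <- P[-j, , drop = FALSE]
        # scores of the held-out rows estimated without variable j
        tj <- Xh[, -j, drop = FALSE] %*% Pj %*%
          solve(crossprod(Pj) + diag(1e-12, k))
        press[k] <- press[k] + sum((Xh[, j] - tj %*% P[j, ])^2)
      }
    }
    if (!is.null(x_out)) {
      for (k in seq_len(kmax)) {
        m <- simca(xtr, ncomp = k, alpha = alpha, center = center,
                   scale = scale)
        sens_k[b, k] <- mean(predict(m, x_class[hold, , drop = FALSE])$accepted)
        spec_k[b, k] <- mean(!predict(m, x_out)$accepted)
      }
    }
  }
  out <- list(press = press, ncomp = which.min(press), n_blocks = n_blocks)
  if (!is.null(x_out)) {
    g <- sqrt(colMeans(sens_k) * colMeans(spec_k))
    out$gmean <- g
    out$ncomp_gmean <- which.max(g)
  }
  structure(out, class = "simca_press")
}

#' @export
print.simca_press <- function(x, ...) {
  cat(sprintf("<simca_press> PRESS argmin at %d PC(s)\n", x$ncomp))
  if (!is.null(x$gmean))
    cat(sprintf("  geometric-mean criterion: %d PC(s)\n", x$ncomp_gmean))
  invisible(x)
}
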