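# Shared subset evaluator: cross-validated RMSECV of a PLS-DA model on a
# candidate variable subset, with the latent-variable count re-selected
# per subset by the cv_pls argmin rule (capped at the subset size).
# Results are memoised per call through `cache`.
eval_subset <- function(x, y, subset, n_blocks, max_lv, cache) {
  key <- paste(subset, collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  cv <- cv_pls(x[, subset, drop = FALSE], y, n_blocks = n_blocks,
               max_lv = min(max_lv, length(subset)))
  val <- cv$rmsecv[cv$ncomp]
  cache[[key]] <- val
  val
}

#' Replacement-method variable selection for PLS-DA
#'
#' Local-search selection of a fixed-size variable subset minimising the
#' cross-validated prediction error: starting from a random d-subset, each
#' slot in turn is offered every non-member variable and the swap that
#' most reduces RMSECV is kept (ties retain the incumbent; among equally
#' good challengers the lowest column index wins); sweeps repeat until the
#' subset is stable. A d-variable model admits d such paths — one per
#' starting slot — and the search is repeated from several random starts;
#' the best subset across all paths and starts is returned.
#'
#' @param x numeric matrix, samples in rows.
#' @param y class vector as in [pls_da()].
#' @param d subset size (1 <= d <= ncol(x)).
#' @param n_blocks,max_lv cross-validation spec passed to [cv_pls()]; the
#'   latent-variable count is re-selected per candidate subset, capped at
#'   `min(d, max_lv)`.
#' @param n_starts number of random starts (default 10).
#' @param seed integer seed for the random starts.
#' @return Object of class `rm_select`: `selected` (sorted column
#'   indices), `variables` (their names), `rmsecv`, `trajectory`
#'   (data.frame of accepted replacements with their start and path, so
#'   the error is non-increasing within each search path),
#'   `n_evaluations`, `converged`.
#' @export
rm_select <- function(x, y, d, n_blocks = 7, max_lv = NULL, n_starts = 10,
                      seed = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (d < 1L || d > p) stop("d must be in 1..ncol(x)", call. = FALSE)
  max_lv <- min(max_lv %||% d, d)
  if (!is.null(seed)) set.seed(seed)
  cache <- new.env(parent = emptyenv())
  if (d == p) {
    val <- eval_subset(x, y, seq_len(p), n_blocks, max_lv, cache)
    return(structure(list(selected = seq_len(p),
                          variables = colnames(x) %||% paste0("V", seq_len(p)),
                          rmsecv = val,
                          trajectory = data.frame(step = 0L, start = 0L,
                                                  path = 0L,
                                                  subset = paste(seq_len(p), collapse = ","),
                                                  rmsecv = val),
                          n_evaluations = 1L, n_starts = 0L,
                          converged = TRUE),
                     class = "rm_select"))
  }
  best_set <- NULL; best_val <- Inf
  traj <- list(); step <- 0L
  for (s in seq_len(n_starts)) {
    start_set <- sort(sample.int(p, d))
    for (path in seq_len(d)) {
      set <- start_set
      val <- eval_subset(x, y, set, n_blocks, max_lv, cache)
      slot_order <- c(seq.int(path, d), if (path > 1) seq_len(path - 1L))
      repeat {
        changed <- FALSE
        for (slot in slot_order) {
          out_vars <- setdiff(seq_len(p), set)
          cand_vals <- vapply(out_vars, function(v) {
            trial <- set; trial[slot] <- v
            eval_subset(x, y, sort(trial), n_blocks, max_lv, cache)
          }, 0)
          i <- which.min(cand_vals)          # lowest index on ties
          if (cand_vals[i] < val) {          # strict improvement only
            set[slot] <- out_vars[i]
            val <- cand_vals[i]
            step <- step + 1L
            traj[[step]] <- data.frame(step = step, start = s, path = path,
                                       subset = paste(sort(set), collapse = ","),
                                       rmsecv = val)
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      set <- sort(set)
      better <- val < best_val ||
        (val == best_val && !is.null(best_set) &&
           paste(set, collapse = ",") < paste(best_set, collapse = ","))
      if (is.null(best_set) || better) { best_set <- set; best_val <- val }
    }
  }
  vars <- (colnames(x) %||% paste0("V", seq_len(p)))[best_set]
  structure(list(selected = best_set, variables = vars, rmsecv = best_val,
                 trajectory = if (length(traj)) do.call(rbind, traj) else
                   data.frame(step = integer(), start = integer(),
                              path = integer(), subset = character(),
                              rmsecv = numeric()),
                 n_evaluations = length(ls(cache)), n_starts = n_starts,
                 converged = TRUE),
            class = "rm_select")
}

#' @export
print.rm_select <- function(x, ...) {
  cat(sprintf("<rm_select> %d variable(s): %s\n", length(x$selected),
              paste(x$variables, collapse = ", ")))
  cat(sprintf("  RMSECV %.4f after %d accepted replacements (%d subsets evaluated)\n",
              x$rmsecv, nrow(x$trajectory), x$n_evaluations))
  invisible(x)
}

#' Exhaustive subset search (oracle for the replacement method)
#'
#' Evaluates the cross-validated RMSECV of every d-variable subset and
#' returns the global minimum (lexicographically smallest subset on
#' ties). Intended as a validation oracle at small p; refuses to run
#' beyond the evaluation budget.
#'
#' @inheritParams rm_select
#' @param budget maximum number of subsets evaluated (default 10000).
#' @return An `rm_select`-classed result with the global optimum.
#' @export
exhaustive_select <- function(x, y, d, n_blocks = 7, max_lv = NULL,
                              budget = 10000) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (d < 1L || d > p) stop("d must be in 1..ncol(x)", call. = FALSE)
  n_sub <- choose(p, d)
  if (n_sub > budget)
    stop(sprintf("C(%d, %d) = %.0f exceeds the budget of %d subsets; lower p or d",
                 p, d, n_sub, budget), call. = FALSE)
  max_lv <- min(max_lv %||% d, d)
  cache <- new.env(parent = emptyenv())
  subsets <- combn(p, d)
  vals <- apply(subsets, 2, function(s)
    eval_subset(x, y, s, n_blocks, max_lv, cache))
  i <- which.min(vals)      # combn order is lexicographic; first min wins
  best <- subsets[, i]
  structure(list(selected = best,
                 variables = (colnames(x) %||% paste0("V", seq_len(p)))[best],
                 rmsecv = vals[i],
                 trajectory = data.frame(step = seq_len(ncol(subsets)),
                                         subset = apply(subsets, 2, paste,
                                                        collapse = ","),
                                         rmsecv = vals),
                 n_evaluations = ncol(subsets), n_starts = 0L,
                 converged = TRUE),
            class = "rm_select")
}
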