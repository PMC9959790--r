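#' Volcano statistics: per-analyte fold change and t-test
#'
#' For each analyte the fold change is the ratio of the positive-class
#' mean to the negative-class mean, and the p-value comes from a
#' two-sample t-test (Welch's unequal-variance form by default; the
#' pooled Student form is available). No multiple-testing correction is
#' applied by default — the significance flag uses the raw p < 0.05 rule —
#' but Benjamini-Hochberg adjusted p-values can be reported alongside.
#'
#' @param x numeric matrix, samples in rows, analytes in columns.
#' @param labels class vector as in [pls_da()] (positive class coded 1).
#' @param test `"welch"` (default) or `"student"`.
#' @param p_adjust also report Benjamini-Hochberg adjusted p-values?
#' @param alpha significance cut for the `significant` flag (default
#'   0.05).
#' @return data.frame of class `volcano_table`: `analyte`, `fold_change`,
#'   `p_value`, `significant` (p < alpha), `extreme_fc` (fc < 0.5 or
#'   fc > 2), optionally `p_adjusted`.
#' @export
volcano <- function(x, labels, test = c("welch", "student"),
                    p_adjust = FALSE, alpha = 0.05) {
  test <- match.arg(test)
  x <- as.matrix(x)
  y <- coerce_class01(labels)
  if (sum(y == 1) < 2L || sum(y == 0) < 2L)
    stop("each class needs at least two samples", call. = FALSE)
  pos <- x[y == 1, , drop = FALSE]
  neg <- x[y == 0, , drop = FALSE]
  fc <- colMeans(pos) / colMeans(neg)
  fc[colMeans(neg) == 0] <- NA_real_
  pv <- vapply(seq_len(ncol(x)), function(j)
    t.test(pos[, j], neg[, j], var.equal = (test == "student"))$p.value, 0)
  out <- data.frame(analyte = colnames(x) %||% paste0("V", seq_len(ncol(x))),
                    fold_change = fc, p_value = pv,
                    significant = pv < alpha,
                    extreme_fc = !is.na(fc) & (fc < 0.5 | fc > 2),
                    stringsAsFactors = FALSE)
  if (p_adjust) out$p_adjusted <- stats::p.adjust(pv, method = "BH")
  class(out) <- c("volcano_table", "data.frame")
  out
}

#' @export
plot.volcano_table <- function(x, alpha = 0.05, ...) {
  plot(log2(x$fold_change), -log10(x$p_value),
       xlab = "log2 fold change (positive / negative)",
       ylab = "-log10 p", pch = 16,
       col = ifelse(x$significant, "firebrick", "grey50"), ...)
  graphics::abline(h = -log10(alpha), lty = 2, col = "grey40")
  graphics::abline(v = c(-1, 1), lty = 3, col = "grey70")
  invisible(x)
}

#' Repeated-split false positive / false negative frequencies
#'
#' Runs the PLS-DA pipeline on `k` seeded random train/validation splits
#' (no stratification) and counts, per sample, how often it was called a
#' false positive or a false negative — separately for the runs where it
#' sat in the training set and those where it was held out.
#'
#' @param x numeric matrix, samples in rows.
#' @param labels class vector (positive class coded 1).
#' @param k number of repeated splits (default 10).
#' @param n_train training-set size per split (default 300).
#' @param ncomp latent variables of each PLS-DA fit (default 4).
#' @param threshold classification threshold (default 0.4).
#' @param seed integer seed.
#' @return data.frame with one row per sample: `fp_train`, `fn_train`,
#'   `fp_valid`, `fn_valid`, `n_train_runs`, `n_valid_runs`.
#' @export
repeat_split_frequency <- function(x, labels, k = 10, n_train = 300,
                                   ncomp = 4, threshold = 0.4, seed = 1L) {
  x <- as.matrix(x)
  y <- coerce_class01(labels)
  n <- nrow(x)
  stopifnot(k >= 1, n_train < n)
  set.seed(seed)
  cnt <- data.frame(sample = rownames(x) %||% as.character(seq_len(n)),
                    fp_train = 0L, fn_train = 0L, fp_valid = 0L,
                    fn_valid = 0L, n_train_runs = 0L, n_valid_runs = 0L,
                    stringsAsFactors = FALSE)
  for (r in seq_len(k)) {
    repeat {
      tr <- sort(sample.int(n, n_train))
      if (length(unique(y[tr])) == 2L) break
      warning("single-class training split resampled")
    }
    fit <- pls_da(x[tr, , drop = FALSE], y[tr],
                  ncomp = min(ncomp, length(tr) - 1L, ncol(x)))
    pred_tr <- classify(predict(fit, x[tr, , drop = FALSE]), threshold)
    va <- setdiff(seq_len(n), tr)
    pred_va <- classify(predict(fit, x[va, , drop = FALSE]), threshold)
    cnt$fp_train[tr] <- cnt$fp_train[tr] + (y[tr] == 0 & pred_tr == 1)
    cnt$fn_train[tr] <- cnt$fn_train[tr] + (y[tr] == 1 & pred_tr == 0)
    cnt$n_train_runs[tr] <- cnt$n_train_runs[tr] + 1L
    cnt$fp_valid[va] <- cnt$fp_valid[va] + (y[va] == 0 & pred_va == 1)
    cnt$fn_valid[va] <- cnt$fn_valid[va] + (y[va] == 1 & pred_va == 0)
    cnt$n_valid_runs[va] <- cnt$n_valid_runs[va] + 1L
  }
  cnt
}

#' Export an analysis report bundle as delimited text
#'
#' Writes whichever result tables are supplied (confusion matrices with
#' row percentages, ROC points, volcano table, RM trajectory, frequency
#' distributions, FP/FN frequencies) as TSV files plus a manifest
#' recording the seed and a content hash of the configuration, so that a
#' bundle can be regenerated byte-identically.
#'
#' @param results named list; recognised entries: `confusion` (a
#'   [confusion()] or named list of them), `roc` (a [roc_curve()]),
#'   `volcano` (a [volcano()] table), `rm` (an [rm_select()] result),
#'   `frequency` (a [frequency_distribution()] table), `fpfn` (a
#'   [repeat_split_frequency()] table).
#' @param dir output directory, created if needed.
#' @param seed seed recorded in the manifest.
#' @param config optional list of run parameters; hashed into the
#'   manifest.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(results, dir, seed = NA_integer_, config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    written <<- c(written, path)
  }
  conf_table <- function(cm) {
    m <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2, byrow = TRUE)
    pct <- sweep(m, 1, pmax(1L, rowSums(m)), `/`) * 100
    data.frame(true_class = c("positive", "negative"),
               pred_positive = m[, 1],
               pred_positive_pct = sprintf("%.1f", pct[, 1]),
               pred_negative = m[, 2],
               pred_negative_pct = sprintf("%.1f", pct[, 2]),
               stringsAsFactors = FALSE)
  }
  if (!is.null(results$confusion)) {
    cm <- results$confusion
    if (inherits(cm, "confusion")) cm <- list(confusion = cm)
    for (nm in names(cm)) emit(conf_table(cm[[nm]]), nm)
  }
  if (!is.null(results$roc)) emit(results$roc$curve, "roc_points")
  if (!is.null(results$volcano)) emit(results$volcano, "volcano")
  if (!is.null(results$rm)) emit(results$rm$trajectory, "rm_trajectory")
  if (!is.null(results$frequency)) emit(results$frequency, "frequency_distribution")
  if (!is.null(results$fpfn)) emit(results$fpfn, "fp_fn_frequency")
  cfg <- tempfile()
  dput(config, cfg)
  hash <- unname(tools::md5sum(cfg))
  unlink(cfg)
  manifest <- data.frame(file = c(basename(written)),
                         stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.tsv")
  con <- file(path, "w")
  writeLines(sprintf("#! seed\t%s", seed), con)
  writeLines(sprintf("#! config_md5\t%s", hash), con)
  write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(written, path))
}
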