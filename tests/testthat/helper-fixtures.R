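# Shared fixtures, all generated in code.

# Realistic per-analyte molar concentrations: the cohort design means
# converted to mM at the default 50 mg / 1 mL preparation, optionally
# jittered lognormally.
realistic_mM <- function(panel = default_panel(), jitter_sd = 0, seed = NULL) {
  eff <- honeynmr:::cohort_effect_table()
  i <- match(eff$analyte_id, panel$analytes$analyte_id)
  mw <- panel$analytes$molecular_weight[i]
  unit <- panel$analytes$unit_class[i]
  mgkg <- ifelse(unit == "g_per_100g", eff$mean_negative * 1e4,
                 eff$mean_negative)
  mM <- mgkg / (mw * 20)
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mM <- mM * exp(rnorm(length(mM), 0, jitter_sd))
  }
  stats::setNames(mM, eff$analyte_id)
}

# A planted-signal classification instance: y depends on three known
# columns of standard-normal X.
planted_instance <- function(n = 100, p = 12, markers = c(2, 7, 11),
                             noise_sd = 0.6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  score <- rowSums(X[, markers, drop = FALSE]) + rnorm(n, sd = noise_sd)
  y <- as.integer(score > stats::quantile(score, 0.6))
  list(X = X, y = y, markers = markers)
}

# Small flat spectrum on an even grid, for integration arithmetic.
flat_spectrum <- function(n = 101, value = 1, lo = 0, hi = 1) {
  nmr_spectrum(seq(lo, hi, length.out = n), rep(value, n), referenced = TRUE)
}
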