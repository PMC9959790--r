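#' Lineshape and grid parameters for the spectrum simulator
#'
#' @param linewidth_hz full width at half maximum of the Lorentzian lines,
#'   Hz (default 1.0).
#' @param spectrometer_mhz proton frequency used to convert Hz to ppm
#'   (default 700.15).
#' @param points grid size (default 2^15); must be at least 1024.
#' @param ppm_range length-2 numeric, the simulated window (default
#'   -0.5..9.5 ppm).
#' @param noise_sd additive Gaussian noise standard deviation expressed as
#'   a fraction of the TMSP apex height (default 0, noiseless).
#' @param baseline_coeffs polynomial baseline coefficients in ascending
#'   order of power of ppm (default none).
#' @param tail_limit_ppm support half-width of each line (default
#'   0.05 ppm): intensity beyond this distance from a line's centre is
#'   zero. This emulates fully processed spectra in which regional
#'   polynomial baseline correction has removed the long-range Lorentzian
#'   tails of the dominant sugar resonances; set to `Inf` for untruncated
#'   lines.
#' @return A list of class `lineshape_params`.
#' @export
lineshape_params <- function(linewidth_hz = 1.0, spectrometer_mhz = 700.15,
                             points = 2^15, ppm_range = c(-0.5, 9.5),
                             noise_sd = 0, baseline_coeffs = numeric(),
                             tail_limit_ppm = 0.05) {
  stopifnot(linewidth_hz > 0, spectrometer_mhz > 0, points >= 1024,
            noise_sd >= 0, length(ppm_range) == 2L, tail_limit_ppm > 0)
  structure(list(linewidth_hz = linewidth_hz,
                 spectrometer_mhz = spectrometer_mhz,
                 points = as.integer(points),
                 ppm_range = sort(as.numeric(ppm_range)),
                 noise_sd = noise_sd,
                 baseline_coeffs = baseline_coeffs,
                 tail_limit_ppm = tail_limit_ppm),
            class = "lineshape_params")
}

#' Simulate a honey mixture spectrum with known concentrations
#'
#' Forward model of the quantitation chain: each analyte region receives a
#' Lorentzian singlet centred in the region whose summed intensity inside
#' the region equals `concentration_mM * n_protons_effective /
#' scaling_factor * K`, with one proportionality constant K shared by all
#' peaks including the 9-proton TMSP singlet at 0.0 ppm. Gaussian noise
#' (sd = `noise_sd` times the TMSP apex height) and a polynomial baseline
#' are added last.
#'
#' @param panel an [analyte_panel()].
#' @param concentrations_mM named numeric vector, analyte_id -> mM. Every
#'   name must exist in the panel; values must be nonnegative.
#' @param shape a [lineshape_params()].
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_sd = 0`).
#' @param shift_ppm rigid mis-referencing applied to the whole axis
#'   (default 0). When nonzero the returned spectrum is marked
#'   unreferenced so that [reference_spectrum()] can undo it.
#' @param sample_id,sample_mass_mg,solvent_volume_mL metadata recorded on
#'   the spectrum (defaults: 50 mg in 1 mL, the standard preparation).
#' @return An [nmr_spectrum()].
#' @export
simulate_spectrum <- function(panel, concentrations_mM,
                              shape = lineshape_params(), seed = NULL,
                              shift_ppm = 0, sample_id = "synthetic",
                              sample_mass_mg = 50, solvent_volume_mL = 1) {
  stopifnot(inherits(panel, "analyte_panel"), inherits(shape, "lineshape_params"))
  ids <- names(concentrations_mM)
  known <- c(panel$analytes$analyte_id, "tmsp")
  if (is.null(ids) || !all(ids %in% known))
    stop("unknown analyte(s): ",
         paste(setdiff(ids, known), collapse = ", "), call. = FALSE)
  if (any(concentrations_mM < 0))
    stop("negative concentration supplied", call. = FALSE)
  ppm <- seq(shape$ppm_range[1], shape$ppm_range[2],
             length.out = shape$points)
  y <- numeric(shape$points)
  gamma <- shape$linewidth_hz / shape$spectrometer_mhz / 2  # HWHM, ppm
  K <- 1000                                                  # area unit per mM*proton
  add_peak <- function(y, lo, hi, target_area) {
    if (lo < ppm[1] || hi > ppm[length(ppm)])
      stop(sprintf("region [%.3f, %.3f] outside the simulated grid", lo, hi),
           call. = FALSE)
    centre <- (lo + hi) / 2
    raw <- gamma^2 / ((ppm - centre)^2 + gamma^2)   # unit-apex Lorentzian
    raw[abs(ppm - centre) > shape$tail_limit_ppm] <- 0
    s_in <- sum(raw[ppm >= lo & ppm <= hi])
    y + raw * (target_area / s_in)
  }
  conc <- concentrations_mM
  conc[["tmsp"]] <- panel$is_concentration_mM
  for (id in names(conc)) {
    rr <- panel$regions[panel$regions$analyte_id == id, , drop = FALSE]
    prof <- numeric(shape$points)
    targets <- conc[[id]] * rr$n_protons_effective / rr$scaling_factor * K
    for (j in seq_len(nrow(rr)))
      prof <- add_peak(prof, rr$ppm_min[j], rr$ppm_max[j], targets[j])
    if (nrow(rr) > 1L && sum(targets) > 0) {
      # adjacent regions of one analyte cross-spill; recalibrate the
      # combined area over the union of its regions (what quantitation sums)
      in_union <- Reduce(`|`, lapply(seq_len(nrow(rr)), function(j)
        ppm >= rr$ppm_min[j] & ppm <= rr$ppm_max[j]))
      prof <- prof * (sum(targets) / sum(prof[in_union]))
    }
    y <- y + prof
  }
  if (shape$noise_sd > 0) {
    tm <- panel$regions[panel$regions$analyte_id == "tmsp", ][1, ]
    apex <- max(y[ppm >= tm$ppm_min & ppm <= tm$ppm_max])
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), sd = shape$noise_sd * apex)
  }
  if (length(shape$baseline_coeffs))
    y <- y + drop(outer(ppm, seq_along(shape$baseline_coeffs) - 1, `^`) %*%
                    shape$baseline_coeffs)
  nmr_spectrum(ppm + shift_ppm, y, referenced = (shift_ppm == 0),
               meta = list(sample_id = sample_id,
                           sample_mass_mg = sample_mass_mg,
                           solvent_volume_mL = solvent_volume_mL))
}

#' Simulate replicate concentration maps
#'
#' Emulates replicate sample preparations: each analyte value is perturbed
#' multiplicatively by `1 + e`, `e ~ N(0, cv)`, truncated at zero.
#'
#' @param concentrations named numeric vector (analyte -> concentration).
#' @param cv coefficient of variation of the replicate noise (>= 0).
#' @param k number of replicates (>= 1).
#' @param seed integer seed.
#' @return A list of `k` named numeric vectors.
#' @export
simulate_replicates <- function(concentrations, cv, k, seed = NULL) {
  stopifnot(k >= 1, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(k), function(i) {
    out <- pmax(0, concentrations * (1 + rnorm(length(concentrations),
                                               sd = cv)))
    names(out) <- names(concentrations)
    out
  })
}

# Synthetic cohort effect table. Means are in each analyte's reporting
# unit (g/100g for fructose and glucose, mg/kg otherwise). The values are
# synthetic design constants, not measured honey compositions: they are
# chosen so that the positive class carries the documented marker
# structure (trigonelline elevated more than twofold with most positive
# samples above 20 mg/kg, proline elevated, ethanol and the
# succinate/MGDH/MGMH/leptosperin/HPLA/1,3-butanediol/lactate group at
# less than half, alanine and phenylalanine at less than half).
cohort_effect_table <- function() {
  E <- function(id, mean_neg, fold, cv)
    data.frame(analyte_id = id, mean_negative = mean_neg,
               mean_positive = mean_neg * fold, cv_negative = cv,
               cv_positive = 0.7 * cv, stringsAsFactors = FALSE)
  rbind(
    E("hmf",              100,  0.60, 0.60),
    E("trigonelline",       8,  4.40, 0.40),
    E("formate",           25,  0.80, 0.40),
    E("leptosperin",       15,  0.40, 1.00),
    E("methyl_syringate",   6,  0.70, 0.90),
    E("pla",               15,  0.70, 0.80),
    E("phenylalanine",     25,  0.40, 0.90),
    E("hpla",              20,  0.45, 0.90),
    E("tyrosine",          20,  0.70, 0.60),
    E("maltose",        15000,  0.85, 0.30),
    E("sucrose",         3000,  0.60, 0.80),
    E("kojibiose",       8000,  0.85, 0.30),
    E("nigerose",        5000,  0.85, 0.30),
    E("turanose",        6000,  0.85, 0.30),
    E("trehalose",       1500,  1.00, 0.50),
    E("dha",               60,  0.60, 1.00),
    E("fructose",        37.5,  1.03, 0.08),
    E("glucose",         30.0,  1.04, 0.10),
    E("citrate",          150,  0.80, 0.50),
    E("malate",           250,  0.90, 0.50),
    E("succinate",         40,  0.45, 0.80),
    E("mgmh",              18,  0.45, 0.80),
    E("proline",          280,  1.80, 0.25),
    E("acetate",          120,  0.80, 0.50),
    E("quercitol",         50,  0.90, 0.80),
    E("alanine",           30,  0.40, 0.90),
    E("lactate",          110,  0.45, 0.80),
    E("mgdh",              25,  0.45, 0.80),
    E("threonine",         25,  0.70, 0.50),
    E("ethanol",           90,  0.25, 0.30),
    E("butanediol_13",     60,  0.45, 0.90),
    E("valine",            20,  0.70, 0.50),
    E("isoleucine",        15,  1.00, 0.50)
  )
}

#' Design of a synthetic two-class concentration cohort
#'
#' @param n_positive,n_negative class sizes (defaults 105 and 319, the
#'   emulated survey's Canadian / non-Canadian split of 424 samples).
#' @param effects data.frame with columns `analyte_id`, `mean_negative`,
#'   `mean_positive`, `cv_negative`, `cv_positive`; defaults to the
#'   built-in synthetic effect table (see [simulate_cohort()]). The
#'   positive (single-origin) class is more homogeneous than the pooled
#'   worldwide negative class, so its default coefficients of variation
#'   are 0.7 times the negative-class values.
#' @param distribution `"lognormal"` (default; honey analytes are positive
#'   and right-skewed) or `"truncated_normal"`.
#' @param correlation optional positive-definite analyte correlation
#'   matrix applied through a Gaussian copula.
#' @param seed integer seed stored with the design.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_positive = 105, n_negative = 319,
                          effects = cohort_effect_table(),
                          distribution = c("lognormal", "truncated_normal"),
                          correlation = NULL, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_positive + n_negative >= 2, all(effects$mean_negative > 0),
            all(effects$mean_positive > 0), all(effects$cv_negative >= 0),
            all(effects$cv_positive >= 0))
  if (!is.null(correlation)) {
    p <- nrow(effects)
    if (!is.matrix(correlation) || any(dim(correlation) != p))
      stop("correlation must be a ", p, "x", p, " matrix", call. = FALSE)
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("correlation matrix is not positive definite", call. = FALSE)
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 effects = effects, distribution = distribution,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a class-structured concentration cohort
#'
#' Draws a samples-by-analytes concentration matrix with two classes whose
#' per-analyte means follow the design's effect table. The default design
#' emulates the structure of a 424-sample honey survey with 105 positive
#' (Canadian) samples: trigonelline more than twofold elevated in the
#' positive class with most positive samples above 20 mg/kg, proline
#' elevated, and ethanol, succinate, MGDH, MGMH, leptosperin, HPLA,
#' 1,3-butanediol, lactate, alanine and phenylalanine all below half the
#' negative-class mean. All default values are synthetic design constants,
#' not measurements.
#'
#' @param design a [cohort_design()].
#' @param seed overrides the design's stored seed when given.
#' @param panel an [analyte_panel()] supplying units and LOQs for the
#'   flag matrix (default [default_panel()]).
#' @return A list of class `honey_cohort`: `concentrations` (matrix,
#'   samples x analytes, positive class first), `class` (factor
#'   positive/negative), `units`, `loq_flags`, `sample_meta` (data.frame
#'   with class, country, floral, replicate_group), `design`.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = NULL,
                            panel = default_panel()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed %||% design$seed)
  eff <- design$effects
  p <- nrow(eff)
  n <- design$n_positive + design$n_negative
  cls <- factor(rep(c("positive", "negative"),
                    c(design$n_positive, design$n_negative)),
                levels = c("positive", "negative"))
  means <- ifelse(cls == "positive",
                  1, 0) %o% eff$mean_positive +
    ifelse(cls == "negative", 1, 0) %o% eff$mean_negative
  Z <- matrix(rnorm(n * p), n, p)
  if (!is.null(design$correlation))
    Z <- Z %*% chol(design$correlation)
  X <- matrix(0, n, p, dimnames = list(sprintf("sample_%03d", seq_len(n)),
                                       eff$analyte_id))
  cvs <- cbind(ifelse(cls == "positive", 1, 0) %o% eff$cv_positive +
                 ifelse(cls == "negative", 1, 0) %o% eff$cv_negative)
  for (j in seq_len(p)) {
    m <- means[, j]; cv <- cvs[, j]
    if (design$distribution == "lognormal") {
      sdl <- sqrt(log(1 + cv^2))
      X[, j] <- exp(log(m) - sdl^2 / 2 + sdl * Z[, j])
    } else {
      x <- m * (1 + cv * Z[, j])
      bad <- which(x < 0)
      while (length(bad)) {           # resample below-zero draws (truncation)
        x[bad] <- m[bad] * (1 + cv * rnorm(length(bad)))
        bad <- bad[x[bad] < 0]
      }
      X[, j] <- x
    }
  }
  ord <- match(eff$analyte_id, panel$analytes$analyte_id)
  loq <- panel$analytes$loq_mgkg[ord]
  unit <- ifelse(panel$analytes$unit_class[ord] == "g_per_100g",
                 "g/100g", "mg/kg")
  mgkg <- sweep(X, 2, ifelse(unit == "g/100g", 1e4, 1), `*`)
  flags <- sweep(mgkg, 2, loq, `<`)
  meta <- data.frame(
    sample_id = rownames(X),
    class = cls,
    country = ifelse(cls == "positive", "Canada", "Other"),
    floral = "unknown",
    replicate_group = seq_len(n),
    stringsAsFactors = FALSE)
  structure(list(concentrations = X, class = cls, units = unit,
                 loq_flags = flags, sample_meta = meta, design = design),
            class = "honey_cohort")
}

#' @export
print.honey_cohort <- function(x, ...) {
  cat(sprintf("<honey_cohort> %d samples x %d analytes (%d positive, %d negative)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              sum(x$class == "positive"), sum(x$class == "negative")))
  invisible(x)
}

#' Write a cohort's concentration table to delimited text
#'
#' @param cohort a `honey_cohort` from [simulate_cohort()].
#' @param path output TSV path. A units header line (`#!`) precedes the
#'   table; class and country are carried as leading columns.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "honey_cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#! units\t",
                    paste(cohort$units, collapse = "\t")), con)
  tab <- data.frame(sample_id = rownames(cohort$concentrations),
                    class = as.character(cohort$class),
                    country = cohort$sample_meta$country,
                    cohort$concentrations, check.names = FALSE,
                    stringsAsFactors = FALSE)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a cohort concentration table written by [write_cohort()]
#'
#' @param path TSV path.
#' @return A list with `concentrations`, `class`, `units`, `sample_meta`.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  units <- strsplit(sub("^#! units\t", "", lines[grepl("^#!", lines)][1]),
                    "\t")[[1]]
  tab <- read.delim(text = lines[!grepl("^#!", lines)], check.names = FALSE,
                    stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -(1:3)])
  rownames(X) <- tab$sample_id
  list(concentrations = X,
       class = factor(tab$class, levels = c("positive", "negative")),
       units = units,
       sample_meta = tab[, 1:3])
}
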