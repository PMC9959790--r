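#' Integrate a spectral region by plain point summation
#'
#' Returns the sum of intensities at grid points whose chemical shift lies
#' in `[ppm_min, ppm_max]` (both endpoints inclusive). No baseline fitting
#' and no deconvolution are applied: the spectra are assumed to be fully
#' processed absorption spectra.
#'
#' @param s a referenced [nmr_spectrum()].
#' @param ppm_min,ppm_max region limits in ppm.
#' @return The raw area (sum of point intensities).
#' @export
integrate_region <- function(s, ppm_min, ppm_max) {
  stopifnot(inherits(s, "nmr_spectrum"))
  if (!s$referenced)
    stop("spectrum must be referenced before integration", call. = FALSE)
  if (ppm_min >= ppm_max) stop("ppm_min must be < ppm_max", call. = FALSE)
  if (ppm_min < min(s$ppm) || ppm_max > max(s$ppm))
    stop(sprintf("region [%.3f, %.3f] lies outside the axis [%.3f, %.3f]",
                 ppm_min, ppm_max, min(s$ppm), max(s$ppm)), call. = FALSE)
  sum(s$intensity[s$ppm >= ppm_min & s$ppm <= ppm_max])
}

#' Analyte limit of quantification in mg/kg
#'
#' Converts the base molar LOQ (a one-proton singlet with signal-to-noise
#' 10:1, 0.01 mM on the reference instrument configuration) to an
#' analyte-specific mass-fraction LOQ: the molar limit is worsened by the
#' signal multiplicity and improved by the number of protons contributing
#' to the integrated region, then converted using the molecular weight and
#' the sample preparation.
#'
#' @param base_mM molar LOQ of a one-proton singlet (default 0.01 mM).
#' @param n_protons_region protons contributing to the integrated region.
#' @param multiplicity_penalty factor >= 1 accounting for signal splitting
#'   (a doublet spreads the same area over two lines, etc.).
#' @param mw molecular weight, g/mol.
#' @param mass_mg,volume_mL sample preparation (defaults 50 mg in 1 mL).
#' @return LOQ in mg analyte per kg honey.
#' @export
loq_mgkg <- function(base_mM = 0.01, n_protons_region, multiplicity_penalty = 1,
                     mw, mass_mg = 50, volume_mL = 1) {
  if (any(base_mM <= 0) || any(n_protons_region <= 0) || any(mw <= 0) ||
      any(mass_mg <= 0) || any(volume_mL <= 0))
    stop("all LOQ arguments must be positive", call. = FALSE)
  if (any(multiplicity_penalty <= 0))
    stop("multiplicity penalty must be positive", call. = FALSE)
  base_mM * (multiplicity_penalty / n_protons_region) * mw *
    volume_mL / (mass_mg * 1e-3)
}

# mg/kg from mM given the sample preparation; g/100g = mg/kg / 1e4.
mm_to_mgkg <- function(mM, mw, mass_mg, volume_mL) {
  mM * mw * volume_mL / (mass_mg * 1e-3)
}

#' Quantify all panel analytes in one referenced spectrum
#'
#' Implements internal-standard quantitation: for analyte a with combined
#' region area A_a, effective proton count N_a and back-calculation factor
#' s_a, the molar concentration is
#' \deqn{C_a = (A_a / N_a) / (A_{TMSP} / 9) \times C_{TMSP} \times s_a,}
#' i.e. the proton-normalised area ratio to the 9-proton TMSP methyl
#' resonance times the known TMSP concentration, scaled back to the whole
#' molecule when the region covers only one anomer. Multi-region analytes
#' (fructose) sum both the areas and the proton-equivalent counts of their
#' regions. Concentrations are converted to each analyte's reporting unit
#' using the sample mass and solvent volume in the spectrum metadata.
#'
#' @param s a referenced [nmr_spectrum()]; `meta$sample_mass_mg` and
#'   `meta$solvent_volume_mL` default to 50 mg and 1 mL if unset.
#' @param panel an [analyte_panel()].
#' @return A `quant_result`: data.frame with one row per analyte
#'   (`analyte_id`, `name`, `mM`, `concentration`, `unit`, `loq_flag`)
#'   and attributes `sample_id`, `replicate`, `tmsp_area`.
#' @export
quantify <- function(s, panel) {
  stopifnot(inherits(s, "nmr_spectrum"), inherits(panel, "analyte_panel"))
  if (!s$referenced)
    stop("spectrum must be referenced before quantitation", call. = FALSE)
  mass_mg <- s$meta$sample_mass_mg %||% 50
  volume_mL <- s$meta$solvent_volume_mL %||% 1
  if (is.na(mass_mg) || is.na(volume_mL))
    stop("sample mass and solvent volume are required", call. = FALSE)
  tm <- panel$regions[panel$regions$analyte_id == "tmsp", ][1, ]
  a_tmsp <- integrate_region(s, tm$ppm_min, tm$ppm_max)
  if (a_tmsp <= 0)
    stop("calibration error: TMSP area is not positive", call. = FALSE)
  ana <- panel$analytes
  out <- lapply(seq_len(nrow(ana)), function(i) {
    a <- ana[i, ]
    rr <- panel$regions[panel$regions$analyte_id == a$analyte_id, , drop = FALSE]
    if (a$combine_rule == "sum_regions") {
      area <- sum(vapply(seq_len(nrow(rr)), function(j)
        integrate_region(s, rr$ppm_min[j], rr$ppm_max[j]), 0))
      n_eff <- sum(rr$n_protons_effective)
      s_a <- rr$scaling_factor[1]
    } else {
      area <- integrate_region(s, rr$ppm_min[1], rr$ppm_max[1])
      n_eff <- rr$n_protons_effective[1]
      s_a <- rr$scaling_factor[1]
    }
    mM <- (area / n_eff) / (a_tmsp / tm$n_protons_effective) *
      panel$is_concentration_mM * s_a
    mgkg <- mm_to_mgkg(mM, a$molecular_weight, mass_mg, volume_mL)
    conc <- if (a$unit_class == "g_per_100g") mgkg / 1e4 else mgkg
    data.frame(analyte_id = a$analyte_id, name = a$name, mM = mM,
               concentration = conc,
               unit = if (a$unit_class == "g_per_100g") "g/100g" else "mg/kg",
               loq_flag = mgkg < a$loq_mgkg, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("quant_result", "data.frame"),
            sample_id = s$meta$sample_id %||% NA_character_,
            replicate = s$meta$replicate %||% NA_integer_,
            tmsp_area = a_tmsp)
}

#' Average replicate quantitation results
#'
#' Arithmetic per-analyte mean across replicate measurements of one
#' sample, with the (n-1) sample standard deviation attached and the LOQ
#' flag re-evaluated on the mean.
#'
#' @param results list of `quant_result` objects for the same sample.
#' @param panel the [analyte_panel()] used (supplies LOQs for re-flagging).
#' @return A `quant_result` with an extra `sd` column (NA for a single
#'   replicate).
#' @export
average_triplicates <- function(results, panel) {
  stopifnot(length(results) >= 1L)
  ids <- vapply(results, function(r) as.character(attr(r, "sample_id")), "")
  if (length(unique(ids)) > 1L)
    stop("mixed sample ids: ", paste(unique(ids), collapse = ", "),
         call. = FALSE)
  base <- results[[1]]
  conc <- sapply(results, function(r) r$concentration)
  mM <- sapply(results, function(r) r$mM)
  if (is.null(dim(conc))) { conc <- matrix(conc, ncol = 1); mM <- matrix(mM, ncol = 1) }
  m <- rowMeans(conc)
  s <- if (ncol(conc) > 1L) apply(conc, 1, sd) else rep(NA_real_, nrow(conc))
  out <- base
  out$mM <- rowMeans(mM)
  out$concentration <- m
  out$sd <- s
  mgkg <- ifelse(out$unit == "g/100g", m * 1e4, m)
  loq <- panel$analytes$loq_mgkg[match(out$analyte_id, panel$analytes$analyte_id)]
  out$loq_flag <- mgkg < loq
  structure(out, class = c("quant_result", "data.frame"),
            sample_id = attr(base, "sample_id"), replicate = NA_integer_,
            tmsp_area = mean(vapply(results, attr, 0, "tmsp_area")))
}

#' Concentration frequency distribution with LOQ flagging
#'
#' Segments the observed concentration range into equal bins (by default
#' 1 percent of the range each) and counts samples per bin, flagging bins
#' that lie entirely below the limit of quantification.
#'
#' @param values numeric concentration vector.
#' @param bin_fraction bin width as a fraction of the range (default 0.01).
#' @param loq optional LOQ on the same scale as `values`.
#' @return data.frame with `bin_low`, `bin_high`, `count`, `below_loq`.
#' @export
frequency_distribution <- function(values, bin_fraction = 0.01, loq = NULL) {
  stopifnot(length(values) >= 1L, bin_fraction > 0)
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    warning("all values equal; returning a single bin")
    return(data.frame(bin_low = lo, bin_high = hi, count = length(values),
                      below_loq = if (is.null(loq)) FALSE else hi <= loq))
  }
  nb <- max(1L, round(1 / bin_fraction))
  breaks <- seq(lo, hi, length.out = nb + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             count = counts,
             below_loq = if (is.null(loq)) rep(FALSE, nb) else breaks[-1] <= loq)
}
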