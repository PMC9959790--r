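#' Construct a 1D NMR spectrum object
#'
#' A spectrum is a strictly monotone chemical-shift axis (ppm, relative to
#' TMSP = 0) with one intensity per point. Axes are stored ascending
#' regardless of the order they were supplied in.
#'
#' @param ppm numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity numeric vector of absorption intensities, same length.
#' @param referenced logical; has the axis been referenced to TMSP at 0 ppm?
#' @param meta named list of sample metadata. Recognised entries:
#'   `sample_id`, `replicate`, `sample_mass_mg`, `solvent_volume_mL`.
#' @return An object of class `nmr_spectrum`: a list with elements `ppm`,
#'   `intensity`, `referenced`, `meta`.
#' @export
nmr_spectrum <- function(ppm, intensity, referenced = FALSE, meta = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length", call. = FALSE)
  if (length(ppm) < 2L)
    stop("a spectrum needs at least two points", call. = FALSE)
  if (any(!is.finite(ppm)))
    stop("format error: non-finite ppm values", call. = FALSE)
  d <- diff(ppm)
  if (any(d == 0))
    stop("format error: duplicated ppm values in axis", call. = FALSE)
  if (!(all(d > 0) || all(d < 0)))
    stop("format error: ppm axis is not monotone", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("format error: non-finite intensities", call. = FALSE)
  if (d[1] < 0) {            # store ascending
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  structure(list(ppm = ppm, intensity = intensity,
                 referenced = isTRUE(referenced), meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f..%.3f ppm, %sreferenced\n",
              length(x$ppm), min(x$ppm), max(x$ppm),
              if (x$referenced) "" else "not "))
  if (!is.null(x$meta$sample_id))
    cat("  sample:", x$meta$sample_id,
        if (!is.null(x$meta$replicate)) sprintf("(replicate %s)", x$meta$replicate) else "",
        "\n")
  invisible(x)
}

#' Read a 1D spectrum from disk
#'
#' Two dialects are supported: plain two-column delimited text
#' (ppm, intensity; tab-, comma- or space-separated, `#` comments allowed)
#' and single-block JCAMP-DX with an `XYDATA=(X++(Y..Y))` table on an
#' evenly spaced axis.
#'
#' @param path file path.
#' @param dialect `"two_column_text"` or `"jcamp_dx"`.
#' @return An [nmr_spectrum()] with `referenced = FALSE` unless the file
#'   carries a `$REFERENCED` flag (JCAMP-DX, written by [write_spectrum()]).
#' @export
read_spectrum <- function(path, dialect = c("two_column_text", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "two_column_text") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    parts <- strsplit(trimws(lines), "[\t, ]+")
    if (any(lengths(parts) < 2L))
      stop("format error: expected two columns (ppm, intensity)", call. = FALSE)
    tok1 <- vapply(parts, `[[`, "", 1L)
    tok2 <- vapply(parts, `[[`, "", 2L)
    ppm <- suppressWarnings(as.numeric(tok1))
    y <- suppressWarnings(as.numeric(tok2))
    bad <- (is.na(ppm) & toupper(tok1) != "NAN") |
      (is.na(y) & toupper(tok2) != "NAN")
    if (any(bad))
      stop("format error: non-numeric values in spectrum table", call. = FALSE)
    nmr_spectrum(ppm, y)        # non-finite intensities rejected there
  } else {
    read_jcamp(path)
  }
}

#' Write a 1D spectrum to disk
#'
#' @inheritParams read_spectrum
#' @param s an [nmr_spectrum()].
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("two_column_text", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(s, "nmr_spectrum"))
  if (dialect == "two_column_text") {
    writeLines(sprintf("%.12g\t%.12g", s$ppm, s$intensity), path)
  } else {
    write_jcamp(s, path)
  }
  invisible(path)
}

# Minimal single-block JCAMP-DX (AFFN, X++(Y..Y)) writer. Requires an
# evenly spaced axis; values are written in full precision so that a
# write/read round trip is exact to floating precision.
write_jcamp <- function(s, path) {
  n <- length(s$ppm)
  step <- diff(s$ppm)
  if (max(abs(step - step[1])) > 1e-9 * abs(step[1]))
    stop("JCAMP-DX output requires an evenly spaced ppm axis", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  title <- s$meta$sample_id %||% "spectrum"
  hdr <- c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=5.00",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##FIRSTX=%.12g", s$ppm[1]),
    sprintf("##LASTX=%.12g", s$ppm[n]),
    sprintf("##NPOINTS=%d", n),
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##$REFERENCED=%d", as.integer(s$referenced))
  )
  if (!is.null(s$meta$sample_mass_mg))
    hdr <- c(hdr, sprintf("##$SAMPLEMASSMG=%.12g", s$meta$sample_mass_mg))
  if (!is.null(s$meta$solvent_volume_mL))
    hdr <- c(hdr, sprintf("##$SOLVENTVOLUMEML=%.12g", s$meta$solvent_volume_mL))
  writeLines(hdr, con)
  writeLines("##XYDATA=(X++(Y..Y))", con)
  idx <- split(seq_len(n), ceiling(seq_len(n) / 4))
  for (ii in idx) {
    writeLines(paste(c(sprintf("%.12g", s$ppm[ii[1]]),
                       sprintf("%.12g", s$intensity[ii])), collapse = " "), con)
  }
  writeLines("##END=", con)
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    i <- grep(sprintf("^##\\$?%s=", key), lines)
    if (!length(i)) return(NULL)
    sub(sprintf("^##\\$?%s=", key), "", lines[i[1]])
  }
  firstx <- as.numeric(get_field("FIRSTX"))
  lastx <- as.numeric(get_field("LASTX"))
  npts <- as.integer(get_field("NPOINTS"))
  xf <- as.numeric(get_field("XFACTOR") %||% "1")
  yf <- as.numeric(get_field("YFACTOR") %||% "1")
  if (!length(firstx) || !length(lastx) || !length(npts))
    stop("format error: missing FIRSTX/LASTX/NPOINTS in JCAMP-DX header",
         call. = FALSE)
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("format error: no XYDATA block", call. = FALSE)
  end <- grep("^##END=", lines)
  end <- if (length(end)) end[end > start[1]][1] else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  y <- unlist(lapply(strsplit(trimws(body), "[ \t]+"), function(tok) {
    as.numeric(tok[-1])                       # first token is the line's X
  }), use.names = FALSE)
  if (length(y) != npts)
    stop(sprintf("format error: NPOINTS=%d but %d intensities read",
                 npts, length(y)), call. = FALSE)
  ppm <- seq(firstx * xf, lastx * xf, length.out = npts)
  meta <- list()
  if (!is.null(get_field("TITLE"))) meta$sample_id <- get_field("TITLE")
  if (!is.null(get_field("SAMPLEMASSMG")))
    meta$sample_mass_mg <- as.numeric(get_field("SAMPLEMASSMG"))
  if (!is.null(get_field("SOLVENTVOLUMEML")))
    meta$solvent_volume_mL <- as.numeric(get_field("SOLVENTVOLUMEML"))
  refd <- identical(get_field("REFERENCED"), "1")
  nmr_spectrum(ppm, y * yf, referenced = refd, meta = meta)
}

#' Reference a spectrum to the internal standard
#'
#' Shifts the chemical-shift axis so that the maximum-intensity point inside
#' a search window (by default the 0.2 ppm neighbourhood of 0) sits exactly
#' at `ref_ppm`. Intensities are untouched; the operation is idempotent to
#' within one grid step.
#'
#' @param s an [nmr_spectrum()].
#' @param search_window length-2 numeric, the ppm interval searched for the
#'   reference peak apex. Must lie within the axis.
#' @param ref_ppm target chemical shift of the apex (default 0, TMSP).
#' @return The shifted spectrum with `referenced = TRUE`.
#' @export
reference_spectrum <- function(s, search_window = c(-0.1, 0.1), ref_ppm = 0) {
  stopifnot(inherits(s, "nmr_spectrum"))
  lo <- min(search_window); hi <- max(search_window)
  if (lo < min(s$ppm) || hi > max(s$ppm))
    stop("search window lies outside the ppm axis", call. = FALSE)
  in_win <- which(s$ppm >= lo & s$ppm <= hi)
  if (!length(in_win)) stop("search window contains no grid points", call. = FALSE)
  ints <- s$intensity[in_win]
  mx <- max(ints)
  cand <- in_win[ints == mx]
  if (length(cand) > 1L) {
    warning("flat maximum in reference window; tie broken to the point nearest ref_ppm")
    cand <- cand[which.min(abs(s$ppm[cand] - ref_ppm))]
  }
  shift <- ref_ppm - s$ppm[cand]
  nmr_spectrum(s$ppm + shift, s$intensity, referenced = TRUE, meta = s$meta)
}
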