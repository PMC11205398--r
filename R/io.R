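#' Read a spectrum from disk
#'
#' Supports plain two-column delimited text (`ppm<TAB>intensity`) and the
#' JCAMP-DX `##XYDATA=(X++(Y..Y))` dialect written by [write_spectrum()].
#' Files with a descending ppm axis are accepted and flipped to the
#' package's ascending internal convention. If a target `grid` is supplied
#' and differs from the file's axis, intensities are resampled onto it by
#' linear interpolation (which preserves the integral of smooth spectra to
#' well under 0.5 percent).
#'
#' @param path Input file.
#' @param format `"auto"` (sniff), `"two_column_text"` or `"jcamp_dx"`.
#' @param grid Optional [nmr_grid()] to resample onto.
#' @param freq_mhz Spectrometer frequency to record when the file format
#'   does not carry one.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "two_column_text", "jcamp_dx"),
                          grid = NULL, freq_mhz = 400) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), "##")) "jcamp_dx" else "two_column_text"
  }
  xy <- switch(format,
               two_column_text = .read_two_column(path),
               jcamp_dx = .read_jcamp(path))
  ppm <- xy$ppm
  y <- xy$y
  d <- diff(ppm)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("non-monotone ppm axis in ", path)
  if (d[1] < 0) {            # descending file: flip to ascending storage
    ppm <- rev(ppm)
    y <- rev(y)
  }
  if (!is.null(xy$freq_mhz)) freq_mhz <- xy$freq_mhz
  if (is.null(grid)) {
    grid <- nmr_grid(ppm[1], ppm[length(ppm)], length(ppm), freq_mhz)
    return(nmr_spectrum(grid, y))
  }
  native <- nmr_grid(ppm[1], ppm[length(ppm)], length(ppm), freq_mhz)
  if (grids_equal(native, grid) &&
      max(abs(ppm - ppm_axis(grid))) < 1e-9 * max(1, abs(grid$ppm_max)))
    return(nmr_spectrum(grid, y))
  yi <- stats::approx(ppm, y, xout = ppm_axis(grid), rule = 2)$y
  nmr_spectrum(grid, yi)
}

.read_two_column <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- strsplit(trimws(lines[keep]), "[\t ,]+")
  lineno <- which(keep)
  n <- length(rows)
  if (n == 0) stop("no data rows in ", path)
  ppm <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) < 2 || anyNA(v[1:2]))
      stop(sprintf("malformed row at line %d of %s", lineno[i], path))
    ppm[i] <- v[1]; y[i] <- v[2]
  }
  list(ppm = ppm, y = y, freq_mhz = NULL)
}

.read_jcamp <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    m <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^##", key, "="), "", m[1])
  }
  xy_at <- grep("^##XYDATA=", lines)
  if (length(xy_at) == 0) stop("no ##XYDATA block in ", path)
  endat <- grep("^##END", lines)
  endat <- if (length(endat)) min(endat[endat > xy_at[1]]) else length(lines) + 1L
  npoints <- as.integer(hdr("NPOINTS"))
  firstx <- as.numeric(hdr("FIRSTX"))
  lastx <- as.numeric(hdr("LASTX"))
  xfac <- as.numeric(hdr("XFACTOR")); if (is.na(xfac) || !length(xfac)) xfac <- 1
  yfac <- as.numeric(hdr("YFACTOR")); if (is.na(yfac) || !length(yfac)) yfac <- 1
  freq <- suppressWarnings(as.numeric(hdr("\\.OBSERVE FREQUENCY")))
  if (anyNA(c(npoints, firstx, lastx)))
    stop("JCAMP-DX header missing NPOINTS/FIRSTX/LASTX in ", path)
  y <- numeric(0)
  for (ln in lines[(xy_at[1] + 1L):(endat - 1L)]) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (anyNA(v)) stop("malformed JCAMP-DX data line: ", ln)
    y <- c(y, v[-1])           # first value on each line is the X check value
  }
  if (length(y) != npoints)
    stop(sprintf("JCAMP-DX data has %d points, header says %d",
                 length(y), npoints))
  list(ppm = seq(firstx * xfac, lastx * xfac, length.out = npoints),
       y = y * yfac,
       freq_mhz = if (length(freq) && !is.na(freq)) freq else NULL)
}

#' Write a spectrum to disk
#'
#' Two-column text is `ppm<TAB>intensity`, one row per grid point, at full
#' double precision. JCAMP-DX output uses the AFFN `##XYDATA=(X++(Y..Y))`
#' form with `YFACTOR=1` so that [read_spectrum()] round-trips it exactly.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path Output file.
#' @param format `"two_column_text"` or `"jcamp_dx"`.
#' @param title Title record for JCAMP-DX output.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           format = c("two_column_text", "jcamp_dx"),
                           title = "nmrxai spectrum") {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (length(spectrum$intensities) == 0) stop("empty intensity vector")
  ppm <- ppm_axis(spectrum$grid)
  y <- spectrum$intensities
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (format == "two_column_text") {
    writeLines(paste(sprintf("%.17g", ppm), sprintf("%.17g", y), sep = "\t"),
               con)
  } else {
    g <- spectrum$grid
    writeLines(c(
      paste0("##TITLE=", title),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=NMR SPECTRUM",
      "##XUNITS=PPM",
      "##YUNITS=ARBITRARY UNITS",
      sprintf("##.OBSERVE FREQUENCY=%.17g", g$freq_mhz),
      sprintf("##FIRSTX=%.17g", g$ppm_min),
      sprintf("##LASTX=%.17g", g$ppm_max),
      "##XFACTOR=1",
      "##YFACTOR=1",
      sprintf("##NPOINTS=%d", g$n_points),
      sprintf("##FIRSTY=%.17g", y[1]),
      "##XYDATA=(X++(Y..Y))"), con)
    per <- 4L
    for (i0 in seq(1L, g$n_points, by = per)) {
      i1 <- min(i0 + per - 1L, g$n_points)
      writeLines(paste(sprintf("%.17g", c(ppm[i0], y[i0:i1])), collapse = " "),
                 con)
    }
    writeLines("##END=", con)
  }
  invisible(path)
}
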