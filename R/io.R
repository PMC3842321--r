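#' Read a 1D spectrum from disk
#'
#' Two plain-text dialects are supported. The TSV dialect is the package's
#' canonical fixture format: `#key=value` metadata lines (`sample_id`,
#' `weight_mg`, `group`, `spectrometer_mhz`) followed by two tab-separated
#' numeric columns (ppm, intensity). The JCAMP-DX dialect is the minimal
#' uncompressed `##XYDATA=(X++(Y..Y))` form (no AFFN compression variants).
#'
#' @param path File path.
#' @param format `"tsv"` or `"jcamp"`; default guessed from the extension
#'   (`.jdx`/`.dx` are JCAMP, anything else TSV).
#' @param require_weight If `TRUE`, error when the file carries no
#'   `weight_mg` (tissue spectra must have a weight).
#' @return A [spectrum1d].
#' @export
read_spectrum <- function(path, format = NULL, require_weight = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "tsv"
  }
  format <- match.arg(format, c("tsv", "jcamp"))
  s <- if (format == "tsv") read_spectrum_tsv(path) else read_spectrum_jcamp(path)
  if (require_weight && is.null(s$weight_mg))
    stopf("tissue spectrum '%s' has no weight_mg", path)
  s
}

read_spectrum_tsv <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lineno <- seq_along(lines)
  keep <- lines != ""
  lines <- lines[keep]; lineno <- lineno[keep]
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (i in which(is_meta)) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0)
      stopf("%s: line %d: malformed metadata line '%s'", path, lineno[i],
            lines[i])
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  data_lines <- lines[!is_meta]
  data_lineno <- lineno[!is_meta]
  if (length(data_lines) < 2) stopf("%s: fewer than 2 data lines", path)
  parts <- strsplit(data_lines, "[\t ]+")
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stopf("%s: line %d: expected two numeric columns", path, data_lineno[bad[1]])
  ppm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  ity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  bad <- which(!is.finite(ppm) | !is.finite(ity))
  if (length(bad))
    stopf("%s: line %d: non-numeric value", path, data_lineno[bad[1]])
  spectrum1d(
    sample_id = meta$sample_id %||% basename(path),
    ppm = ppm, intensity = ity,
    weight_mg = if (!is.null(meta$weight_mg)) as.numeric(meta$weight_mg) else NULL,
    group_label = meta$group,
    spectrometer_mhz = if (!is.null(meta$spectrometer_mhz))
      as.numeric(meta$spectrometer_mhz) else 500.13)
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  xy_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) {
      kv <- sub("^##", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) stopf("%s: line %d: malformed JCAMP label '%s'", path, i, ln)
      key <- toupper(trimws(substr(kv, 1, eq - 1)))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      if (startsWith(key, "XYDATA")) { xy_start <- i + 1L; break }
      hdr[[key]] <- val
    }
  }
  if (is.na(xy_start)) stopf("%s: no ##XYDATA record", path)
  xf <- as.numeric(hdr[["XFACTOR"]] %||% "1")
  yf <- as.numeric(hdr[["YFACTOR"]] %||% "1")
  npt <- if (!is.null(hdr[["NPOINTS"]])) as.integer(hdr[["NPOINTS"]]) else NA_integer_
  firstx <- if (!is.null(hdr[["FIRSTX"]])) as.numeric(hdr[["FIRSTX"]]) else NA_real_
  lastx <- if (!is.null(hdr[["LASTX"]])) as.numeric(hdr[["LASTX"]]) else NA_real_
  dx <- if (!is.na(npt) && npt > 1 && !is.na(firstx) && !is.na(lastx))
    (lastx - firstx) / (npt - 1) else NA_real_
  body <- trimws(lines[seq(xy_start, length(lines))])
  lineno <- seq(xy_start, length(lines))
  keep <- body != ""
  body <- body[keep]; lineno <- lineno[keep]
  end <- which(startsWith(body, "##"))
  if (length(end)) { body <- body[seq_len(end[1] - 1)]; lineno <- lineno[seq_len(end[1] - 1)] }
  parsed <- lapply(strsplit(body, "[,\t ]+"), function(v)
    suppressWarnings(as.numeric(v)))
  bad <- which(vapply(parsed, function(v) length(v) < 2 || any(!is.finite(v)),
                      logical(1)))
  if (length(bad))
    stopf("%s: line %d: malformed XYDATA line", path, lineno[bad[1]])
  pieces <- lapply(seq_along(parsed), function(i) {
    vals <- parsed[[i]]
    x0 <- vals[1] * xf
    ys <- vals[-1] * yf
    if (length(ys) > 1 && is.na(dx))
      stopf("%s: line %d: multi-Y line needs FIRSTX/LASTX/NPOINTS", path,
            lineno[i])
    xs <- if (length(ys) == 1) x0 else x0 + dx * (seq_along(ys) - 1)
    cbind(xs, ys)
  })
  xy <- do.call(rbind, pieces)
  ppm <- xy[, 1]; ity <- xy[, 2]
  if (length(ppm) < 2) stopf("%s: fewer than 2 XYDATA points", path)
  wt <- if (!is.null(hdr[["$WEIGHT_MG"]])) as.numeric(hdr[["$WEIGHT_MG"]]) else NULL
  mhz <- if (!is.null(hdr[["$SPECTROMETER_MHZ"]]))
    as.numeric(hdr[["$SPECTROMETER_MHZ"]]) else 500.13
  spectrum1d(sample_id = hdr[["TITLE"]] %||% basename(path),
             ppm = ppm, intensity = ity, weight_mg = wt,
             group_label = hdr[["$GROUP"]], spectrometer_mhz = mhz)
}

#' Write a 1D spectrum to disk
#'
#' Values are written with 12 significant digits; the file round-trips
#' through [read_spectrum] losslessly at that precision. Spectra without a
#' weight (standard solutions) omit the weight line.
#'
#' @param s A [spectrum1d].
#' @param path Output path.
#' @param format `"tsv"` or `"jcamp"`.
#' @export
write_spectrum <- function(s, path, format = c("tsv", "jcamp")) {
  stopifnot(inherits(s, "spectrum1d"))
  format <- match.arg(format)
  num <- function(x) sprintf("%.12g", x)
  if (format == "tsv") {
    hdr <- c(sprintf("#sample_id=%s", s$sample_id))
    if (!is.null(s$weight_mg)) hdr <- c(hdr, sprintf("#weight_mg=%s", num(s$weight_mg)))
    if (!is.null(s$group_label)) hdr <- c(hdr, sprintf("#group=%s", s$group_label))
    hdr <- c(hdr, sprintf("#spectrometer_mhz=%s", num(s$spectrometer_mhz)))
    body <- paste(num(s$ppm), num(s$intensity), sep = "\t")
    writeLines(c(hdr, body), path)
  } else {
    n <- length(s$ppm)
    hdr <- c(sprintf("##TITLE=%s", s$sample_id),
             "##JCAMP-DX=4.24", "##DATA TYPE=NMR SPECTRUM",
             "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
             sprintf("##$SPECTROMETER_MHZ=%s", num(s$spectrometer_mhz)))
    if (!is.null(s$weight_mg)) hdr <- c(hdr, sprintf("##$WEIGHT_MG=%s", num(s$weight_mg)))
    if (!is.null(s$group_label)) hdr <- c(hdr, sprintf("##$GROUP=%s", s$group_label))
    hdr <- c(hdr,
             "##XFACTOR=1", "##YFACTOR=1",
             sprintf("##FIRSTX=%s", num(s$ppm[1])),
             sprintf("##LASTX=%s", num(s$ppm[n])),
             sprintf("##NPOINTS=%d", n),
             "##XYDATA=(X++(Y..Y))")
    body <- paste(num(s$ppm), num(s$intensity))
    writeLines(c(hdr, body, "##END="), path)
  }
  invisible(path)
}
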