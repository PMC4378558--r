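# Reading centroided spectra (peak-list text, mzXML, mzML) and writing
# deconvolution results as msalign-style mass lists.
#
# mzXML/mzML support is intentionally narrow: centroided peak arrays
# (32/64-bit floats, zlib or no compression) plus precursor metadata.
# Profile-mode scans are skipped with a warning when the metadata says so.

#' Construct a spectrum
#'
#' @param mz,intensity Numeric vectors of equal length. Peaks are sorted by
#'   m/z; duplicate m/z values are merged with intensities summed.
#' @param id Spectrum identifier.
#' @param ms_level MS level (integer).
#' @param precursor_mz,precursor_charge,precursor_mass,activation Optional
#'   precursor metadata. If `precursor_mass` is missing but m/z and charge
#'   are present it is derived as `(mz - 1.007276) * z`.
#' @return Object of class `spectrum`: a list with a `peaks` data frame
#'   (`mz`, `intensity`) and the metadata fields.
#' @export
new_spectrum <- function(mz, intensity, id = "spectrum", ms_level = 2L,
                         precursor_mz = NA_real_, precursor_charge = NA_integer_,
                         precursor_mass = NA_real_, activation = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0))
      stop("peak m/z values must be positive and finite")
    if (any(!is.finite(intensity)) || any(intensity < 0))
      stop("peak intensities must be non-negative and finite")
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  if (is.na(precursor_mass) && !is.na(precursor_mz) && !is.na(precursor_charge))
    precursor_mass <- (precursor_mz - PROTON_MASS) * precursor_charge
  structure(list(
    id = as.character(id),
    ms_level = as.integer(ms_level),
    peaks = data.frame(mz = mz, intensity = intensity),
    precursor_mz = precursor_mz,
    precursor_charge = precursor_charge,
    precursor_mass = precursor_mass,
    activation = activation
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum '%s' (MS%d): %d peaks", x$id, x$ms_level,
              nrow(x$peaks)))
  if (!is.na(x$precursor_mass))
    cat(sprintf(", precursor mass %.4f Da", x$precursor_mass))
  cat("\n")
  invisible(x)
}

#' Read centroided spectra
#'
#' Reads mzXML, mzML, or the package's two-column peak-list text format
#' (whitespace-separated `mz intensity` lines, `#` comments). The format is
#' guessed from the file extension/content unless given.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"mzxml"`, `"mzml"`, `"peaklist"`.
#' @return List of `spectrum` objects (a peak-list file yields one).
#' @export
read_spectra <- function(path, format = c("auto", "mzxml", "mzml", "peaklist")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, mzxml = "mzxml", mzml = "mzml", "peaklist")
    if (format == "peaklist") {
      head1 <- tolower(paste(readLines(path, n = 5L, warn = FALSE),
                             collapse = " "))
      if (grepl("<mzxml", head1, fixed = TRUE)) format <- "mzxml"
      else if (grepl("<mzml", head1, fixed = TRUE)) format <- "mzml"
    }
  }
  switch(format,
         peaklist = list(read_peaklist(path)),
         mzxml = read_mzxml(path),
         mzml = read_mzml(path))
}

read_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(new_spectrum(numeric(0), numeric(0),
                        id = basename(path)))
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("peak list ", path, ": line ", bad[1], " does not have two columns")
  mz <- as.numeric(vapply(fields, `[[`, "", 1L))
  intensity <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (anyNA(mz) || anyNA(intensity))
    stop("peak list ", path, ": non-numeric values")
  new_spectrum(mz, intensity, id = basename(path))
}

#' Write a spectrum as a peak-list text file
#'
#' @param spectrum A `spectrum`.
#' @param path Output file.
#' @export
write_peaklist <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", spectrum$id), con)
  writeLines(sprintf("%.6f %.6f", spectrum$peaks$mz, spectrum$peaks$intensity),
             con)
  invisible(path)
}

## decode a base64-encoded binary peak array
decode_binary_array <- function(b64, precision = 64L, endian = "little",
                                compressed = FALSE) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (compressed)
    raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", n = length(raw) %/% (precision %/% 8L),
          size = precision %/% 8L, endian = endian)
}

read_mzxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  scans <- xml2::xml_find_all(doc, ".//scan")
  out <- list()
  for (sc in scans) {
    num <- xml2::xml_attr(sc, "num")
    centroided <- xml2::xml_attr(sc, "centroided")
    if (!is.na(centroided) && centroided %in% c("0", "false")) {
      warning("scan ", num, ": profile mode, skipped")
      next
    }
    pk <- xml2::xml_find_first(sc, "./peaks")
    if (is.na(pk))
      stop("mzXML scan ", num, ": missing <peaks>")
    precision <- as.integer(xml2::xml_attr(pk, "precision"))
    if (is.na(precision)) precision <- 32L
    byte_order <- xml2::xml_attr(pk, "byteOrder")
    endian <- if (!is.na(byte_order) && byte_order == "network") "big" else "little"
    comp <- xml2::xml_attr(pk, "compressionType")
    vals <- tryCatch(
      decode_binary_array(xml2::xml_text(pk), precision, endian,
                          compressed = !is.na(comp) && comp == "zlib"),
      error = function(e) stop("mzXML scan ", num, ": ", conditionMessage(e)))
    n <- length(vals) %/% 2L
    mz <- vals[seq(1L, by = 2L, length.out = n)]
    intensity <- vals[seq(2L, by = 2L, length.out = n)]
    prec <- xml2::xml_find_first(sc, "./precursorMz")
    pmz <- NA_real_; pz <- NA_integer_
    if (!is.na(prec)) {
      pmz <- as.numeric(xml2::xml_text(prec))
      pz <- as.integer(xml2::xml_attr(prec, "precursorCharge"))
    }
    out[[length(out) + 1L]] <- new_spectrum(
      mz, intensity, id = paste0("scan=", num),
      ms_level = as.integer(xml2::xml_attr(sc, "msLevel")),
      precursor_mz = pmz, precursor_charge = pz,
      activation = xml2::xml_attr(sc, "activationMethod"))
  }
  out
}

read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  out <- list()
  for (sp in spectra) {
    id <- xml2::xml_attr(sp, "id")
    cv_acc <- function(node, acc)
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc))
    if (!is.na(cv_acc(sp, "MS:1000128"))) {      # profile spectrum
      warning("spectrum ", id, ": profile mode, skipped")
      next
    }
    lvl <- cv_acc(sp, "MS:1000511")
    ms_level <- if (!is.na(lvl)) as.integer(xml2::xml_attr(lvl, "value")) else 1L
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- intensity <- NULL
    for (arr in arrays) {
      precision <- if (!is.na(cv_acc(arr, "MS:1000523"))) 64L
                   else if (!is.na(cv_acc(arr, "MS:1000521"))) 32L else 64L
      compressed <- !is.na(cv_acc(arr, "MS:1000574"))
      vals <- tryCatch(
        decode_binary_array(xml2::xml_text(
          xml2::xml_find_first(arr, "./binary")), precision, "little",
          compressed),
        error = function(e) stop("mzML spectrum ", id, ": ",
                                 conditionMessage(e)))
      if (!is.na(cv_acc(arr, "MS:1000514"))) mz <- vals
      if (!is.na(cv_acc(arr, "MS:1000515"))) intensity <- vals
    }
    if (is.null(mz) || is.null(intensity))
      stop("mzML spectrum ", id, ": missing m/z or intensity array")
    ion <- xml2::xml_find_first(sp, ".//selectedIon")
    pmz <- NA_real_; pz <- NA_integer_
    if (!is.na(ion)) {
      v <- cv_acc(ion, "MS:1000744")
      if (!is.na(v)) pmz <- as.numeric(xml2::xml_attr(v, "value"))
      v <- cv_acc(ion, "MS:1000041")
      if (!is.na(v)) pz <- as.integer(xml2::xml_attr(v, "value"))
    }
    out[[length(out) + 1L]] <- new_spectrum(
      mz, intensity, id = id, ms_level = ms_level,
      precursor_mz = pmz, precursor_charge = pz)
  }
  out
}

#' Write a deconvolution result as an msalign-style mass list
#'
#' One `BEGIN IONS`/`END IONS` block per result, with header fields
#' (`ID`, `PRECURSOR_MZ`, `PRECURSOR_CHARGE`, `PRECURSOR_MASS`,
#' `ACTIVATION`) followed by one tab-separated row per reported envelope:
#' monoisotopic mass (5 decimals), intensity, charge, raw L-score, local FDR.
#'
#' @param result A `deconv_result` (see [deconvolute()]).
#' @param path Output file; an open connection is also accepted.
#' @export
write_masslist <- function(result, path) {
  stopifnot(inherits(result, "deconv_result"))
  con <- if (inherits(path, "connection")) path else file(path, "w")
  if (!inherits(path, "connection")) on.exit(close(con))
  writeLines("BEGIN IONS", con)
  writeLines(sprintf("ID=%s", result$id), con)
  hdr <- function(key, val, fmt = "%s") {
    if (!is.na(val)) writeLines(sprintf(paste0(key, "=", fmt), val), con)
  }
  hdr("PRECURSOR_MZ", result$precursor_mz, "%.5f")
  hdr("PRECURSOR_CHARGE", result$precursor_charge, "%d")
  hdr("PRECURSOR_MASS", result$precursor_mass, "%.5f")
  hdr("ACTIVATION", result$activation)
  e <- result$entries
  if (nrow(e))
    writeLines(sprintf("%.5f\t%.2f\t%d\t%.4f\t%.4f",
                       e$mass, e$intensity, e$charge, e$score, e$fdr), con)
  writeLines("END IONS", con)
  invisible(path)
}

#' Read an msalign-style mass list written by [write_masslist()]
#'
#' @param path Input file.
#' @return List of `deconv_result` objects.
#' @export
read_masslist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    stop("malformed mass list: unbalanced BEGIN/END IONS")
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, "", 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    rows <- block[!hdr]
    rows <- rows[nzchar(trimws(rows))]
    e <- if (length(rows)) {
      m <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
      data.frame(mass = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]),
                 charge = as.integer(m[, 3]), score = as.numeric(m[, 4]),
                 fdr = as.numeric(m[, 5]))
    } else {
      data.frame(mass = numeric(0), intensity = numeric(0),
                 charge = integer(0), score = numeric(0), fdr = numeric(0))
    }
    out[[b]] <- structure(list(
      id = get("ID"),
      precursor_mz = as.numeric(get("PRECURSOR_MZ")),
      precursor_charge = as.integer(get("PRECURSOR_CHARGE")),
      precursor_mass = as.numeric(get("PRECURSOR_MASS")),
      activation = get("ACTIVATION"),
      entries = e
    ), class = "deconv_result")
  }
  out
}
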