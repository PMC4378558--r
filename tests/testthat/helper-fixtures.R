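# Programmatic mzXML / mzML fixtures (built at test time; base64 payloads
# encoded from the peak arrays with the precision/compression under test).

encode_peaks_mzxml <- function(mz, intensity, precision = 32L) {
  vals <- as.vector(rbind(mz, intensity))   # interleaved m/z, intensity
  raw <- writeBin(vals, raw(), size = precision %/% 8L, endian = "big")
  jsonlite::base64_enc(raw)
}

write_mzxml_fixture <- function(path, scans, precision = 32L) {
  lines <- c('<?xml version="1.0" encoding="ISO-8859-1"?>',
             '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
             '<msRun scanCount="2">')
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    centroided <- if (!is.null(sc$centroided)) sc$centroided else "1"
    lines <- c(lines, sprintf(
      '<scan num="%d" msLevel="2" centroided="%s" peaksCount="%d">',
      i, centroided, length(sc$mz)))
    if (!is.null(sc$precursor_mz))
      lines <- c(lines, sprintf(
        '<precursorMz precursorCharge="%d">%.6f</precursorMz>',
        sc$precursor_charge, sc$precursor_mz))
    lines <- c(lines, sprintf(
      '<peaks precision="%d" byteOrder="network" contentType="m/z-int" compressionType="none">%s</peaks>',
      precision, encode_peaks_mzxml(sc$mz, sc$intensity, precision)),
      "</scan>")
  }
  writeLines(c(lines, "</msRun>", "</mzXML>"), path)
  path
}

encode_array_mzml <- function(vals, precision = 64L, zlib = FALSE) {
  raw <- writeBin(vals, raw(), size = precision %/% 8L, endian = "little")
  if (zlib)
    raw <- memCompress(raw, type = "gzip")
  jsonlite::base64_enc(raw)
}

write_mzml_fixture <- function(path, scans, precision = 64L, zlib = FALSE) {
  comp_cv <- if (zlib)
    '<cvParam accession="MS:1000574" name="zlib compression"/>'
  else
    '<cvParam accession="MS:1000576" name="no compression"/>'
  prec_cv <- if (precision == 64L)
    '<cvParam accession="MS:1000523" name="64-bit float"/>'
  else
    '<cvParam accession="MS:1000521" name="32-bit float"/>'
  lines <- c('<?xml version="1.0" encoding="utf-8"?>',
             '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
             '<run id="run1"><spectrumList count="1">')
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    mode_cv <- if (isTRUE(sc$profile))
      '<cvParam accession="MS:1000128" name="profile spectrum"/>'
    else
      '<cvParam accession="MS:1000127" name="centroid spectrum"/>'
    lines <- c(lines, sprintf(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      i - 1L, i, length(sc$mz)),
      '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
      mode_cv)
    if (!is.null(sc$precursor_mz))
      lines <- c(lines,
        '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
        sprintf('<cvParam accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
                sc$precursor_mz),
        sprintf('<cvParam accession="MS:1000041" name="charge state" value="%d"/>',
                sc$precursor_charge),
        '</selectedIon></selectedIonList></precursor></precursorList>')
    lines <- c(lines, '<binaryDataArrayList count="2">',
      '<binaryDataArray>', prec_cv, comp_cv,
      '<cvParam accession="MS:1000514" name="m/z array"/>',
      sprintf('<binary>%s</binary>', encode_array_mzml(sc$mz, precision, zlib)),
      '</binaryDataArray>',
      '<binaryDataArray>', prec_cv, comp_cv,
      '<cvParam accession="MS:1000515" name="intensity array"/>',
      sprintf('<binary>%s</binary>',
              encode_array_mzml(sc$intensity, precision, zlib)),
      '</binaryDataArray>', '</binaryDataArrayList>', '</spectrum>')
  }
  writeLines(c(lines, '</spectrumList></run>', '</mzML>'), path)
  path
}
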