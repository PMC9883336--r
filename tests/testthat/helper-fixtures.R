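# shared fixtures, built once per test process

.cache <- new.env(parent = emptyenv())

# the full default screening database (one- and two-FuFA candidates)
shared_db <- function() {
  if (is.null(.cache$db))
    .cache$db <- enumerate_candidates(default_building_blocks(),
                                      fufa_per_tag = 1:2)
  .cache$db
}

# a small database for quick screening tests
small_db <- function() {
  if (is.null(.cache$small))
    .cache$small <- enumerate_candidates(
      default_building_blocks(), fufa_per_tag = 1,
      conv = c("P", "O", "L", "Ln"),
      fufas = c("9M5", "11M3", "9D5", "11D3"))
  .cache$small
}

# every FuFA short form printed in the reference tables
printed_fufa_tokens <- function() {
  c("9M3", "9D3", "9M5", "11M3", "9D5", "11D3", "11M5", "11D5",
    "7M5", "7D5", "13M3", "13D3")
}

# random valid CHNO formula for property tests
random_formula <- function() {
  n <- sample(1:4, 1)
  syms <- sample(c("C", "H", "O", "N"), n)
  structure(as.integer(sample(1:60, n, replace = TRUE)), names = syms)
}

# random TAG composition from the default blocks
random_tag <- function(blocks = default_building_blocks()) {
  pool <- c(blocks$conventional, blocks$fufas)
  picks <- sample(length(pool), 3, replace = TRUE)
  build_tag(pool[[picks[1]]], pool[[picks[2]]], pool[[picks[3]]])
}

# minimal uncompressed mzML writer used to exercise the reader; emits
# little-endian 64-bit floats, base64, no compression
write_test_mzml <- function(path, spectra, ms1_scans = 0) {
  enc <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                   size = 8, endian = "little"))
  spec_xml <- function(i, id, prec, mz, inten, level = 2, centroid = TRUE) {
    prec_xml <- if (level == 2 && is.finite(prec)) sprintf(paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
      'name="selected ion m/z" value="%.6f"/></selectedIon>',
      '</selectedIonList><activation/></precursor></precursorList>'), prec)
      else ""
    mode_cv <- if (centroid)
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
      else '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%s" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '%s%s<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray></binaryDataArrayList></spectrum>'),
      i, id, length(mz), level, mode_cv, prec_xml,
      nchar(enc(mz)), enc(mz), nchar(enc(inten)), enc(inten))
  }
  body <- character(0)
  idx <- 0
  for (k in seq_len(ms1_scans)) {
    body <- c(body, spec_xml(idx, idx + 1, NA,
                             c(500.1, 600.2), c(10, 20), level = 1))
    idx <- idx + 1
  }
  for (s in spectra) {
    # mzR expects numeric scan identifiers in "scan=<n>"
    body <- c(body, spec_xml(idx, idx + 1, s$precursor_mz,
                             s$peaks$mz, s$peaks$intensity))
    idx <- idx + 1
  }
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://example.org"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
    '</software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run" defaultInstrumentConfigurationRef="ic">',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">%s</spectrumList>',
    '</run></mzML>'), idx, paste(body, collapse = ""))
  writeLines(doc, path)
  invisible(path)
}
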