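# mzML input/output. Reading goes through the mzR parser; writing is a
# minimal MS1-only mzML 1.1.0 serializer (64-bit floats, no compression)
# sufficient for round-tripping simulated centroid runs.

.b64_doubles <- function(x) {
  b64 <- jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  gsub("\n", "", b64, fixed = TRUE) # single-line base64 as mzML readers expect
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a raw run to mzML
#'
#' Serializes the MS1 scans of a `raw_run` as a minimal, schema-conforming
#' mzML 1.1.0 document (centroid spectra, 64-bit float arrays, uncompressed).
#' MS2 scans are not written.
#'
#' @param run a `raw_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  n <- length(run$ms1)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="',
    .xml_escape(run$run_id), '">')
  w('  <cvList count="2">')
  w('    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
  w('    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>')
  w('  </cvList>')
  w('  <fileDescription>')
  w('    <fileContent>')
  w('      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
  w('      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
  w('    </fileContent>')
  w('  </fileDescription>')
  w('  <softwareList count="1">')
  w('    <software id="agpglyco" version="0.1.0">')
  w('      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="agpglyco"/>')
  w('    </software>')
  w('  </softwareList>')
  w('  <instrumentConfigurationList count="1">')
  w('    <instrumentConfiguration id="IC1">')
  w('      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>')
  w('    </instrumentConfiguration>')
  w('  </instrumentConfigurationList>')
  w('  <dataProcessingList count="1">')
  w('    <dataProcessing id="DP1">')
  w('      <processingMethod order="1" softwareRef="agpglyco">')
  w('        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>')
  w('      </processingMethod>')
  w('    </dataProcessing>')
  w('  </dataProcessingList>')
  w('  <run id="', .xml_escape(run$run_id), '" defaultInstrumentConfigurationRef="IC1">')
  w('    <spectrumList count="', n, '" defaultDataProcessingRef="DP1">')
  for (i in seq_len(n)) {
    s <- run$ms1[[i]]
    np <- length(s$mz)
    mz_b <- .b64_doubles(s$mz)
    in_b <- .b64_doubles(s$intensity)
    w('      <spectrum index="', i - 1L, '" id="scan=', i, '" defaultArrayLength="', np, '">')
    w('        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>')
    w('        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>')
    w('        <scanList count="1">')
    w('          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>')
    w('          <scan>')
    w('            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      format(s$rt, digits = 12), '" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>')
    w('          </scan>')
    w('        </scanList>')
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="', nchar(mz_b), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
    w('            <binary>', mz_b, '</binary>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="', nchar(in_b), '">')
    w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    w('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
    w('            <binary>', in_b, '</binary>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

#' Read an mzML file into a raw run
#'
#' Parses MS1 (and, when present, MS2) scans through the mzR backend.
#'
#' @param path mzML file path.
#' @param run_id run identifier; default the file name without extension.
#' @return a `raw_run`.
#' @export
read_mzml <- function(path, run_id = tools::file_path_sans_ext(basename(path))) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  ms1 <- list(); ms2 <- list()
  for (i in seq_len(nrow(hd))) {
    scan <- list(rt = hd$retentionTime[i] / 60, # mzR reports seconds
                 mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
    if (hd$msLevel[i] == 1L) {
      ms1[[length(ms1) + 1L]] <- scan
    } else {
      scan$precursor_mz <- hd$precursorMZ[i]
      ms2[[length(ms2) + 1L]] <- scan
    }
  }
  raw_run(run_id, ms1, if (length(ms2) > 0) ms2)
}
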