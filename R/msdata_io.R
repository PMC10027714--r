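# Standard-format IO. mzML reading/writing is delegated to Bioconductor's
# mzR (ProteoWizard backend); ground-truth chemical links are kept in a JSON
# sidecar rather than embedded in the mzML, so the files stay standard.

#' Write an acquisition run to mzML
#'
#' Serialises a simulated [run_acquisition()] result as indexed mzML 1.1
#' (64-bit m/z, 32-bit intensity, zlib-compressed), positive polarity,
#' centroid spectra. MS2 spectra carry their isolation window and, when the
#' scan targeted a specific precursor (DDA), the precursor m/z.
#'
#' @param run An `acquisition_run` with at least one scan.
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$scans)
  if (n == 0L) stop("cannot write an empty acquisition run")
  pk <- lapply(run$scans, function(s) {
    p <- s$peaks
    colnames(p) <- c("mz", "intensity")
    p
  })
  lvl <- run$ms_level
  npeaks <- vapply(pk, nrow, integer(1L))
  tic <- vapply(pk, function(p) sum(p[, "intensity"]), numeric(1L))
  bp <- t(vapply(pk, function(p) {
    if (nrow(p) == 0L) return(c(0, 0))
    i <- which.max(p[, "intensity"])
    c(p[i, "mz"], p[i, "intensity"])
  }, numeric(2L)))
  win <- t(vapply(run$scans, function(s) {
    if (s$ms_level == 1L) return(c(NA_real_, NA_real_, NA_real_))
    w <- s$isolation_window
    target <- if (!is.null(s$precursor_mz)) s$precursor_mz else mean(w)
    c(target, target - w[1L], w[2L] - target)
  }, numeric(3L)))
  prec_mz <- ifelse(lvl == 2L, win[, 1L], NA_real_)
  prec_int <- vapply(run$scans, function(s) {
    if (s$ms_level == 2L && !is.null(s$precursor_intensity))
      s$precursor_intensity else if (s$ms_level == 2L) 0 else NA_real_
  }, numeric(1L))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = lvl, polarity = rep(1L, n),
    peaksCount = npeaks, totIonCurrent = tic,
    retentionTime = run$rt,
    basePeakMZ = bp[, 1L], basePeakIntensity = bp[, 2L],
    collisionEnergy = ifelse(lvl == 2L, 25, NA_real_),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, "mz"]) else 0,
                   numeric(1L)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, "mz"]) else 0,
                    numeric(1L)),
    precursorScanNum = ifelse(lvl == 2L, 0L, NA_integer_),
    precursorMZ = prec_mz,
    precursorCharge = ifelse(lvl == 2L, 1L, NA_integer_),
    precursorIntensity = prec_int,
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_,
    mergedResultEndScanNum = NA_integer_,
    injectionTime = rep(0, n),
    filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = win[, 1L],
    isolationWindowLowerOffset = win[, 2L],
    isolationWindowUpperOffset = win[, 3L],
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml",
                   rtime_seconds = TRUE)
  invisible(path)
}

#' Read an mzML file
#'
#' Loads all spectra from an mzML file: MS level, retention time (seconds),
#' centroid peak arrays, and precursor/isolation metadata for MS2 scans.
#' Empty spectra are preserved.
#'
#' @param path Path to an mzML file.
#' @return An `mzml_document`: list with `header` (data frame) and `scans`
#'   (list of `ms_scan` objects).
#' @export
read_mzml <- function(path) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pk[[i]]
    colnames(p) <- c("mz", "intensity")
    iso <- NULL
    prec <- NULL
    if (hdr$msLevel[i] == 2L) {
      t0 <- hdr$isolationWindowTargetMZ[i]
      if (!is.na(t0))
        iso <- c(t0 - hdr$isolationWindowLowerOffset[i],
                 t0 + hdr$isolationWindowUpperOffset[i])
      if (!is.na(hdr$precursorMZ[i]) && hdr$precursorMZ[i] > 0)
        prec <- hdr$precursorMZ[i]
    }
    pint <- if (hdr$msLevel[i] == 2L && !is.na(hdr$precursorIntensity[i]) &&
                hdr$precursorIntensity[i] > 0) hdr$precursorIntensity[i]
    new_scan(i, hdr$msLevel[i], hdr$retentionTime[i], p,
             isolation_window = iso, precursor_mz = prec,
             precursor_intensity = pint)
  })
  structure(list(header = hdr, scans = scans), class = "mzml_document")
}

#' Write the ground-truth sidecar of MS2-scan to chemical links
#'
#' @param run An `acquisition_run`.
#' @param chemicals The `chemical_set` the run was produced from.
#' @param path Output JSON path.
#' @export
write_ground_truth_links <- function(run, chemicals, path) {
  ms2 <- which(run$ms_level == 2L)
  links <- lapply(ms2, function(i) {
    list(scan_id = i, chem_ids = chemicals$id[run$ground_truth_links[[i]]])
  })
  jsonlite::write_json(links, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Export spectra to MSP format
#'
#' Writes a list of spectra (two-column mz/intensity matrices) as an NIST
#' MSP text library, usable by external spectral-matching tools.
#'
#' @param spectra Named list of peak matrices.
#' @param path Output path.
#' @param precursor_mz Optional numeric vector of precursor m/z values.
#' @param rt Optional numeric vector of retention times (seconds).
#' @export
write_msp <- function(spectra, path, precursor_mz = NULL, rt = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  nm <- names(spectra)
  if (is.null(nm)) nm <- paste0("spectrum_", seq_along(spectra))
  for (i in seq_along(spectra)) {
    p <- spectra[[i]]
    writeLines(paste0("NAME: ", nm[i]), con)
    if (!is.null(precursor_mz))
      writeLines(sprintf("PRECURSORMZ: %.5f", precursor_mz[i]), con)
    if (!is.null(rt))
      writeLines(sprintf("RETENTIONTIME: %.3f", rt[i] / 60), con)
    writeLines(paste0("Num Peaks: ", nrow(p)), con)
    if (nrow(p))
      writeLines(sprintf("%.5f %.2f", p[, "mz"], p[, "intensity"]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export spectra to MGF format
#'
#' @inheritParams write_msp
#' @export
write_mgf <- function(spectra, path, precursor_mz = NULL, rt = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  nm <- names(spectra)
  if (is.null(nm)) nm <- paste0("spectrum_", seq_along(spectra))
  for (i in seq_along(spectra)) {
    p <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", nm[i]), con)
    if (!is.null(precursor_mz))
      writeLines(sprintf("PEPMASS=%.5f", precursor_mz[i]), con)
    if (!is.null(rt))
      writeLines(sprintf("RTINSECONDS=%.3f", rt[i]), con)
    writeLines("CHARGE=1+", con)
    if (nrow(p))
      writeLines(sprintf("%.5f %.2f", p[, "mz"], p[, "intensity"]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read an external feature table
#'
#' Reads a CSV of MS1 features with columns `mz`, `rt`, `rt_lo`, `rt_hi`,
#' `intensity` (extra columns are kept), as produced by external peak-picking
#' tools, into the feature-table format used by the deconvolution functions.
#'
#' @param path CSV path.
#' @return A `feature_table` data frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "rt", "rt_lo", "rt_hi", "intensity")
  if (!all(need %in% names(tab)))
    stop("feature CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(tab$feature_id)) tab$feature_id <- paste0("F", seq_len(nrow(tab)))
  if (is.null(tab$mz_lo)) tab$mz_lo <- tab$mz * (1 - 1e-5)
  if (is.null(tab$mz_hi)) tab$mz_hi <- tab$mz * (1 + 1e-5)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
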