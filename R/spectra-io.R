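#' Construct a mass spectrum object
#'
#' A `Spectrum` holds one acquisition of an intact-cell MALDI-TOF profile or
#' centroid trace: an m/z axis (Da, singly charged assumed), matched
#' intensities (arbitrary units) and sample/replicate identity. The m/z axis
#' is stored strictly increasing; duplicated m/z values are merged by
#' summing their intensities so total ion signal is preserved.
#'
#' @param mz numeric vector of m/z values (Da), any order.
#' @param intensity numeric vector of non-negative intensities, same length.
#' @param sample_id,replicate_id character scalars identifying the acquisition.
#' @param mode `"profile"` or `"centroid"`.
#' @param meta named list of free-form metadata (instrument, matrix, date).
#' @return an object of class `icm_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, sample_id = "sample",
                         replicate_id = "r1", mode = c("profile", "centroid"),
                         meta = list()) {
  mode <- match.arg(mode)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) < 1L) stop("empty spectrum: need at least one data point")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity value")
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  if (any(mz <= 0)) stop("all m/z values must be positive")
  if (any(intensity < 0)) stop("all intensities must be non-negative")
  structure(
    list(sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         mz = as.numeric(mz), intensity = as.numeric(intensity),
         mode = mode, meta = meta),
    class = "icm_spectrum")
}

#' @export
print.icm_spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum %s/%s: %d points, m/z %.1f-%.1f, %s>\n",
              x$sample_id, x$replicate_id, length(x$mz),
              min(x$mz), max(x$mz), x$mode))
  invisible(x)
}

#' Construct a centroided peak list
#'
#' One replicate acquisition reduced to discrete peaks. Peaks are stored
#' sorted by m/z; `snr` may be `NA` when no noise estimate is available
#' (e.g. simulated peak lists).
#'
#' @param mz,intensity numeric vectors, as in [new_spectrum()].
#' @param snr signal-to-noise ratios (>= 0 or NA), recycled if length 1.
#' @param sample_id,replicate_id identity of the acquisition.
#' @return an object of class `icm_peaklist`.
#' @export
new_peaklist <- function(mz, intensity, snr = NA_real_,
                         sample_id = "sample", replicate_id = "r1") {
  n <- length(mz)
  if (length(intensity) != n) stop("mz and intensity must have equal length")
  snr <- rep_len(as.numeric(snr), n)
  ord <- order(mz)
  mz <- as.numeric(mz[ord]); intensity <- as.numeric(intensity[ord])
  snr <- snr[ord]
  if (n > 0) {
    if (any(mz <= 0)) stop("all m/z values must be positive")
    if (any(diff(mz) <= 0)) stop("peak m/z values must be strictly increasing")
    if (any(intensity < 0)) stop("intensities must be non-negative")
    if (any(!is.na(snr) & snr < 0)) stop("snr must be >= 0")
  }
  structure(
    list(sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         mz = mz, intensity = intensity, snr = snr),
    class = "icm_peaklist")
}

#' @export
print.icm_peaklist <- function(x, ...) {
  cat(sprintf("<PeakList %s/%s: %d peaks>\n",
              x$sample_id, x$replicate_id, length(x$mz)))
  invisible(x)
}

#' Read a two-column TXT spectrum export
#'
#' Parses spectra exported from acquisition software as plain text with two
#' numeric columns (m/z, intensity). Blank lines and lines starting with
#' `#` are skipped; fields may be separated by runs of spaces/tabs or a
#' single comma or semicolon (vendor exports vary). Out-of-order rows are
#' sorted and duplicate m/z values merged by intensity summation.
#'
#' @param path path to the text file.
#' @param sample_id,replicate_id identity to attach.
#' @param mode override the inferred mode; by default a trace with fewer
#'   than 2000 points is taken as centroid, otherwise profile.
#' @return an `icm_spectrum`.
#' @export
read_spectrum_txt <- function(path, sample_id = "sample", replicate_id = "r1",
                              mode = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L)
    stop("empty spectrum file: ", path)
  mz <- numeric(length(keep)); intensity <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[,;[:space:]]+")[[1]]
    if (length(fields) < 2L)
      stop(sprintf("line %d of %s: expected two numeric columns", ln, path))
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals)))
      stop(sprintf("line %d of %s: non-numeric field '%s'", ln, path,
                   fields[which(is.na(vals))[1]]))
    mz[i] <- vals[1]; intensity[i] <- vals[2]
  }
  if (is.null(mode)) mode <- if (length(unique(mz)) < 2000L) "centroid" else "profile"
  new_spectrum(mz, intensity, sample_id = sample_id,
               replicate_id = replicate_id, mode = mode,
               meta = list(source = path))
}

#' Read spectra from an mzML file
#'
#' @param path path to an mzML file with MS1 spectra.
#' @param sample_id sample identity; defaults to the file name sans extension.
#' @return a list of `icm_spectrum`, one per stored spectrum; replicate ids
#'   are the spectrum indices.
#' @export
read_mzml <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  n <- length(handle)
  if (n == 0L) return(list())
  hdr <- mzR::header(handle)
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)
  lapply(seq_len(n), function(i) {
    m <- pks[[i]]
    mode <- if (isTRUE(hdr$centroided[i])) "centroid" else "profile"
    new_spectrum(m[, 1], m[, 2], sample_id = sample_id,
                 replicate_id = as.character(i), mode = mode,
                 meta = list(source = path))
  })
}

#' Write spectra to an mzML file
#'
#' @param spectra a single `icm_spectrum` or a list of them.
#' @param path output path (.mzML).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  if (inherits(spectra, "icm_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L)
  n <- length(spectra)
  pks <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(spectra, function(s) s$mz[which.max(s$intensity)], numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) max(s$intensity), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) min(s$mz), numeric(1)),
    highMZ = vapply(spectra, function(s) max(s$mz), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = vapply(spectra, function(s) s$mode == "centroid", logical(1)),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(object = pks, file = path, header = hdr)
  invisible(path)
}

#' Write a peak list as CSV
#'
#' The on-disk format is a CSV with header `mz,intensity,snr`; the
#' round-trip through [read_peaklist_csv()] is lossless to 4 decimal places.
#'
#' @param pl an `icm_peaklist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(pl, path) {
  stopifnot(inherits(pl, "icm_peaklist"))
  df <- data.frame(mz = round(pl$mz, 4), intensity = round(pl$intensity, 4),
                   snr = round(pl$snr, 4))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak list from CSV
#'
#' @param path CSV file with columns `mz`, `intensity`, `snr`.
#' @param sample_id,replicate_id identity to attach.
#' @return an `icm_peaklist` (rows sorted by m/z on load).
#' @export
read_peaklist_csv <- function(path, sample_id = "sample", replicate_id = "r1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "intensity", "snr")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("peak-list CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  new_peaklist(df$mz, df$intensity, df$snr,
               sample_id = sample_id, replicate_id = replicate_id)
}
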