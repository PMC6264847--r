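#' Consensus (virtual spectrum) parameters
#'
#' Defaults follow the standard construction for intact-cell fingerprint
#' libraries: a consensus peak must be present in at least 70% of the
#' replicate acquisitions, with replicate peaks matched within +/- 2 Da.
#'
#' @param tol_da m/z tolerance in Da (default 2).
#' @param min_fraction minimum fraction of replicates supporting a peak,
#'   in (0, 1] (default 0.70).
#' @param min_replicates minimum absolute replicate support (default 1).
#' @return a list of class `icm_consensus_params`.
#' @export
consensus_params <- function(tol_da = 2, min_fraction = 0.70,
                             min_replicates = 1) {
  stopifnot(tol_da > 0, min_fraction > 0, min_fraction <= 1,
            min_replicates >= 1)
  structure(list(tol_da = tol_da, min_fraction = min_fraction,
                 min_replicates = min_replicates),
            class = "icm_consensus_params")
}

# Recursively split clusters whose span exceeds 2*tol at the largest
# internal gap, so every member sits within +/- tol of the cluster median.
.split_wide <- function(idx, mz, tol) {
  span <- mz[idx[length(idx)]] - mz[idx[1]]
  if (span <= 2 * tol || length(idx) < 2L) return(list(idx))
  gaps <- diff(mz[idx])
  cut <- which.max(gaps)  # ties: first largest gap
  c(.split_wide(idx[seq_len(cut)], mz, tol),
    .split_wide(idx[(cut + 1L):length(idx)], mz, tol))
}

#' Build a virtual reference spectrum from replicate peak lists
#'
#' Pools the peaks of all replicates of one sample, partitions them into
#' clusters by single-linkage with gap threshold `tol_da` (a new cluster
#' starts whenever the gap to the previous pooled peak exceeds the
#' tolerance), keeps at most one peak per replicate per cluster (the most
#' intense), and retains clusters supported by at least
#' `ceiling(min_fraction * n_replicates)` distinct replicates. Clusters
#' whose m/z span exceeds twice the tolerance are split at their largest
#' internal gap and re-tested, so every member lies within `tol_da` of the
#' consensus m/z (the median of member m/z values).
#'
#' @param peaklists list of `icm_peaklist`, all with the same `sample_id`.
#' @param p an `icm_consensus_params`.
#' @return an object of class `icm_virtual_spectrum` with fields
#'   `sample_id`, `n_replicates`, `mz`, `support`, `mean_intensity`,
#'   `params`.
#' @export
build_virtual_spectrum <- function(peaklists, p = consensus_params()) {
  if (length(peaklists) == 0L) stop("no peak lists supplied")
  stopifnot(all(vapply(peaklists, inherits, logical(1), "icm_peaklist")))
  ids <- unique(vapply(peaklists, function(x) x$sample_id, character(1)))
  if (length(ids) != 1L)
    stop("peak lists belong to different samples: ",
         paste(ids, collapse = ", "))
  reps <- vapply(peaklists, function(x) x$replicate_id, character(1))
  if (anyDuplicated(reps))
    stop("duplicate replicate_id among the peak lists")
  n_rep <- length(peaklists)
  need <- max(ceiling(p$min_fraction * n_rep - 1e-9), p$min_replicates)

  pool <- do.call(rbind, lapply(peaklists, function(x)
    if (length(x$mz) > 0)
      data.frame(mz = x$mz, intensity = x$intensity, rep = x$replicate_id,
                 stringsAsFactors = FALSE)
    else NULL))
  empty <- function() structure(
    list(sample_id = ids, n_replicates = n_rep, mz = numeric(0),
         support = integer(0), mean_intensity = numeric(0), params = p),
    class = "icm_virtual_spectrum")
  if (is.null(pool) || nrow(pool) == 0L) return(empty())
  # deterministic pooling order regardless of input list order
  pool <- pool[order(pool$mz, pool$rep, -pool$intensity), , drop = FALSE]

  gap_new <- c(TRUE, diff(pool$mz) > p$tol_da)
  cluster0 <- split(seq_len(nrow(pool)), cumsum(gap_new))
  clusters <- unlist(lapply(cluster0, .split_wide, mz = pool$mz,
                            tol = p$tol_da),
                     recursive = FALSE)

  out_mz <- numeric(0); out_sup <- integer(0); out_int <- numeric(0)
  for (idx in clusters) {
    sub <- pool[idx, , drop = FALSE]
    # one attestation per replicate: keep its most intense member
    # (ties broken toward lower m/z by the pooling order)
    best <- !duplicated(sub$rep[order(-sub$intensity, sub$mz)])
    sub <- sub[order(-sub$intensity, sub$mz)[best], , drop = FALSE]
    support <- nrow(sub)
    if (support < need) next
    out_mz <- c(out_mz, stats::median(sub$mz))
    out_sup <- c(out_sup, support)
    out_int <- c(out_int, mean(sub$intensity))
  }
  ord <- order(out_mz)
  structure(
    list(sample_id = ids, n_replicates = n_rep, mz = out_mz[ord],
         support = as.integer(out_sup[ord]), mean_intensity = out_int[ord],
         params = p),
    class = "icm_virtual_spectrum")
}

#' @export
print.icm_virtual_spectrum <- function(x, ...) {
  cat(sprintf("<VirtualSpectrum %s: %d consensus peaks from %d replicates>\n",
              x$sample_id, length(x$mz), x$n_replicates))
  invisible(x)
}

#' Write a library of virtual spectra as JSON
#'
#' @param specs list of `icm_virtual_spectrum`.
#' @param path output path (.json).
#' @return `path`, invisibly.
#' @export
write_library <- function(specs, path) {
  if (inherits(specs, "icm_virtual_spectrum")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "icm_virtual_spectrum")))
  doc <- list(
    format = "icmaldi-library", version = 1L,
    spectra = lapply(specs, function(v) list(
      sample_id = v$sample_id, n_replicates = v$n_replicates,
      params = list(tol_da = v$params$tol_da,
                    min_fraction = v$params$min_fraction,
                    min_replicates = v$params$min_replicates),
      peaks = list(mz = v$mz, support = v$support,
                   mean_intensity = v$mean_intensity))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a library of virtual spectra from JSON
#'
#' @param path JSON file written by [write_library()].
#' @return list of `icm_virtual_spectrum`.
#' @export
read_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "icmaldi-library"))
    stop("not an icmaldi library file: ", path)
  lapply(doc$spectra, function(s) {
    if (is.null(s$sample_id) || is.null(s$peaks))
      stop("malformed library entry in ", path)
    structure(
      list(sample_id = s$sample_id,
           n_replicates = as.integer(s$n_replicates),
           mz = as.numeric(s$peaks$mz),
           support = as.integer(s$peaks$support),
           mean_intensity = as.numeric(s$peaks$mean_intensity),
           params = consensus_params(s$params$tol_da, s$params$min_fraction,
                                     s$params$min_replicates)),
      class = "icm_virtual_spectrum")
  })
}
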