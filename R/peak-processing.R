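#' Peak-picking parameters
#'
#' @param snr_min minimum signal-to-noise ratio for a peak (default 3).
#' @param window_da half-width in Da of the local-maximum test (default 5).
#' @param baseline_win_da window in Da for baseline estimation (default 200).
#' @param min_mz,max_mz m/z range retained (defaults 1000 and 20000, the
#'   acquisition range of intact-cell fingerprints).
#' @return a list of class `icm_picking_params`.
#' @export
picking_params <- function(snr_min = 3, window_da = 5, baseline_win_da = 200,
                           min_mz = 1000, max_mz = 20000) {
  stopifnot(snr_min > 0, window_da > 0, baseline_win_da > 0,
            min_mz > 0, min_mz < max_mz)
  structure(list(snr_min = snr_min, window_da = window_da,
                 baseline_win_da = baseline_win_da,
                 min_mz = min_mz, max_mz = max_mz),
            class = "icm_picking_params")
}

# Da window -> odd number of grid points, given the spectrum's median spacing.
.window_points <- function(mz, win_da) {
  step <- stats::median(diff(mz))
  k <- max(3L, as.integer(round(win_da / step)))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, length(mz) - (1L - length(mz) %% 2L))
}

#' Estimate the baseline of a profile spectrum
#'
#' Rolling minimum followed by a rolling mean, both over `baseline_win_da`.
#' The rolling minimum tracks the signal floor under peaks; the rolling
#' mean smooths the staircase it produces.
#'
#' @param s a profile-mode `icm_spectrum`.
#' @param baseline_win_da window width in Da (default 200).
#' @return numeric baseline, same length as the spectrum.
#' @export
estimate_baseline <- function(s, baseline_win_da = 200) {
  stopifnot(inherits(s, "icm_spectrum"))
  if (s$mode != "profile")
    stop("baseline estimation requires a profile-mode spectrum")
  k <- .window_points(s$mz, baseline_win_da)
  floorline <- zoo::rollapply(s$intensity, k, min, partial = TRUE)
  zoo::rollapply(floorline, k, mean, partial = TRUE)
}

#' Pick peaks from a spectrum
#'
#' Profile spectra are baseline-corrected ([estimate_baseline()]); noise is
#' the median absolute deviation of the corrected signal (scaled by 1.4826
#' for consistency with a Gaussian standard deviation), so the picked m/z
#' positions are invariant to overall intensity scaling. A peak is emitted
#' at every point that is the strict maximum of corrected intensity within
#' `window_da` on either side and whose SNR reaches `snr_min`; its m/z is
#' the intensity-weighted centroid of the contiguous region above half the
#' local maximum. Centroid-mode input passes through restricted to the m/z
#' range, with SNR taken against a baseline-free noise estimate.
#'
#' @param s an `icm_spectrum`.
#' @param p an `icm_picking_params`.
#' @return an `icm_peaklist`, sorted by m/z.
#' @export
pick_peaks <- function(s, p = picking_params()) {
  stopifnot(inherits(s, "icm_spectrum"), inherits(p, "icm_picking_params"))
  if (s$mode == "centroid") {
    keep <- s$mz >= p$min_mz & s$mz <= p$max_mz
    noise <- stats::mad(s$intensity[keep])
    snr <- if (noise > 0) s$intensity[keep] / noise else rep(Inf, sum(keep))
    return(new_peaklist(s$mz[keep], s$intensity[keep], snr,
                        sample_id = s$sample_id, replicate_id = s$replicate_id))
  }
  base <- estimate_baseline(s, p$baseline_win_da)
  corrected <- s$intensity - base
  # the rolling-minimum baseline sits below the noise floor by a few noise
  # SDs; center the corrected signal on its median so SNR is not inflated
  corrected <- corrected - stats::median(corrected)
  noise <- stats::mad(corrected)
  if (noise <= 0) noise <- .Machine$double.eps
  n <- length(s$mz)
  # candidate indices: strict maximum of corrected signal within +/- window_da
  lo <- findInterval(s$mz - p$window_da, s$mz) + 1L
  hi <- findInterval(s$mz + p$window_da, s$mz)
  out_mz <- numeric(0); out_int <- numeric(0); out_snr <- numeric(0)
  for (i in seq_len(n)) {
    win <- lo[i]:hi[i]
    v <- corrected[i]
    if (v / noise < p$snr_min) next
    others <- win[win != i]
    if (length(others) > 0 && any(corrected[others] >= v)) next
    # centroid over the contiguous region above half the local maximum
    half <- v / 2
    l <- i; while (l > 1L && corrected[l - 1L] > half) l <- l - 1L
    r <- i; while (r < n && corrected[r + 1L] > half) r <- r + 1L
    reg <- l:r
    w <- pmax(corrected[reg], 0)
    cmz <- if (sum(w) > 0) sum(s$mz[reg] * w) / sum(w) else s$mz[i]
    if (cmz < p$min_mz || cmz > p$max_mz) next
    out_mz <- c(out_mz, cmz); out_int <- c(out_int, v)
    out_snr <- c(out_snr, v / noise)
  }
  # half-maximum centroids of neighbouring maxima can invert or coincide
  # on noisy traces; restore strict order, keeping the more intense peak
  if (length(out_mz) > 1) {
    ord <- order(out_mz, -out_int)
    out_mz <- out_mz[ord]; out_int <- out_int[ord]; out_snr <- out_snr[ord]
    keep <- c(TRUE, diff(out_mz) > 0)
    out_mz <- out_mz[keep]; out_int <- out_int[keep]; out_snr <- out_snr[keep]
  }
  new_peaklist(out_mz, out_int, out_snr,
               sample_id = s$sample_id, replicate_id = s$replicate_id)
}
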