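# Run code under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for synthetic strain panels
#'
#' Defaults emulate the acquisition regime of intact-cell MALDI-TOF
#' fingerprinting: 10 replicate spectra per sample over m/z 1000-20000,
#' replicate m/z scatter well inside a +/- 2 Da matching tolerance
#' (Gaussian jitter, sd 0.6 Da keeps ~99.9% of draws within 2 Da), a 10%
#' chance that a true peak is missing from a replicate, about 2 spurious
#' peaks per replicate, and ~30% relative intensity variation. Ground-truth
#' peaks are kept more than twice the consensus tolerance apart so recovery
#' is unambiguous.
#'
#' @param n_clades number of clades (default 3).
#' @param strains_per_clade strains per clade (default 4).
#' @param shared_frac fraction of each strain's peaks drawn from its
#'   clade-level shared pool (default 0.7).
#' @param n_peaks_per_strain true peaks per strain (default 30).
#' @param n_replicates replicate spectra per strain (default 10).
#' @param mz_jitter_sd replicate m/z jitter, Da (default 0.6).
#' @param dropout_p per-replicate probability a true peak is missing
#'   (default 0.1).
#' @param spurious_rate expected spurious peaks per replicate (default 2).
#' @param intensity_cv coefficient of variation of replicate intensity
#'   (log-normal; default 0.3).
#' @param mz_range acquisition range, Da (default c(1000, 20000)).
#' @param min_gap_da minimum gap between ground-truth peaks of a strain
#'   (default 4.1, just above twice the 2 Da consensus tolerance).
#' @param seed integer RNG seed (default 1).
#' @return a list of class `icm_sim_config`.
#' @export
sim_config <- function(n_clades = 3, strains_per_clade = 4, shared_frac = 0.7,
                       n_peaks_per_strain = 30, n_replicates = 10,
                       mz_jitter_sd = 0.6, dropout_p = 0.1, spurious_rate = 2,
                       intensity_cv = 0.3, mz_range = c(1000, 20000),
                       min_gap_da = 4.1, seed = 1) {
  stopifnot(n_clades >= 1, strains_per_clade >= 1,
            shared_frac >= 0, shared_frac <= 1,
            n_peaks_per_strain >= 1, n_replicates >= 1,
            mz_jitter_sd >= 0, dropout_p >= 0, dropout_p <= 1,
            spurious_rate >= 0, intensity_cv >= 0,
            length(mz_range) == 2, mz_range[1] < mz_range[2], min_gap_da > 0)
  structure(as.list(environment()), class = "icm_sim_config")
}

# Rejection-sample n values on [lo, hi], each > gap from `avoid` and from
# one another.
.draw_gapped <- function(n, lo, hi, gap, avoid = numeric(0)) {
  if (n * gap > 0.5 * (hi - lo))
    stop("infeasible gap constraint: too many peaks for the m/z range")
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    x <- stats::runif(1, lo, hi)
    if (all(abs(c(out, avoid) - x) > gap)) out <- c(out, x)
    tries <- tries + 1L
    if (tries > 10000L * n)
      stop("infeasible gap constraint: rejection sampling failed")
  }
  sort(out)
}

#' Generate ground-truth strain fingerprints
#'
#' Per clade, a shared peak pool is drawn uniformly on the m/z range under
#' the minimum-gap constraint; each strain combines `shared_frac` of its
#' peaks from the pool with private peaks. Ground-truth intensities are
#' log-uniform over two decades. Deterministic given `cfg$seed`.
#'
#' @param cfg an `icm_sim_config`.
#' @return a list of fingerprints, each a list with `sample_id`,
#'   `clade_id`, `mz`, `intensity`.
#' @export
generate_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "icm_sim_config"))
  .with_seed(cfg$seed, {
    n_shared <- round(cfg$shared_frac * cfg$n_peaks_per_strain)
    n_priv <- cfg$n_peaks_per_strain - n_shared
    out <- list()
    for (cl in seq_len(cfg$n_clades)) {
      pool <- .draw_gapped(n_shared, cfg$mz_range[1], cfg$mz_range[2],
                           cfg$min_gap_da)
      pool_int <- 10^stats::runif(n_shared, 2, 4)
      for (st in seq_len(cfg$strains_per_clade)) {
        priv <- .draw_gapped(n_priv, cfg$mz_range[1], cfg$mz_range[2],
                             cfg$min_gap_da, avoid = pool)
        mz <- c(pool, priv)
        int <- c(pool_int, 10^stats::runif(n_priv, 2, 4))
        ord <- order(mz)
        out[[length(out) + 1L]] <- structure(
          list(sample_id = sprintf("C%02d_S%02d", cl, st),
               clade_id = sprintf("C%02d", cl),
               mz = mz[ord], intensity = int[ord]),
          class = "icm_fingerprint")
      }
    }
    out
  })
}

#' Simulate replicate peak lists from a fingerprint
#'
#' Each replicate retains each true peak with probability
#' `1 - dropout_p`, perturbs its m/z with centered Gaussian noise
#' (`mz_jitter_sd`) and its intensity with log-normal noise
#' (`intensity_cv`), then adds Poisson(`spurious_rate`) spurious peaks
#' uniform over the m/z range. Deterministic given `(fp, cfg, seed)`.
#'
#' @param fp an `icm_fingerprint` from [generate_fingerprints()].
#' @param cfg an `icm_sim_config`.
#' @param seed RNG seed for this strain's replicates; defaults to
#'   `cfg$seed` offset by a hash of the sample id, so strains differ but
#'   the panel is reproducible.
#' @return list of `icm_peaklist` of length `cfg$n_replicates`.
#' @export
simulate_replicates <- function(fp, cfg, seed = NULL) {
  stopifnot(inherits(fp, "icm_fingerprint"), inherits(cfg, "icm_sim_config"))
  if (is.null(seed))
    seed <- (cfg$seed + sum(utf8ToInt(fp$sample_id)) * 131L) %% .Machine$integer.max
  sdlog <- sqrt(log(1 + cfg$intensity_cv^2))
  .with_seed(seed, {
    lapply(seq_len(cfg$n_replicates), function(r) {
      keep <- stats::runif(length(fp$mz)) > cfg$dropout_p
      mz <- fp$mz[keep] + stats::rnorm(sum(keep), 0, cfg$mz_jitter_sd)
      int <- fp$intensity[keep] * stats::rlnorm(sum(keep), -sdlog^2 / 2, sdlog)
      n_sp <- stats::rpois(1, cfg$spurious_rate)
      if (n_sp > 0) {
        mz <- c(mz, stats::runif(n_sp, cfg$mz_range[1], cfg$mz_range[2]))
        int <- c(int, 10^stats::runif(n_sp, 1.5, 2.5))
      }
      # collapse coincidental exact duplicates (measure zero, but be safe)
      if (anyDuplicated(mz)) {
        ord <- order(mz)
        mz <- mz[ord]; int <- int[ord]
        dup <- duplicated(mz)
        int <- as.numeric(tapply(int, cumsum(!dup), sum))
        mz <- mz[!dup]
      }
      new_peaklist(mz, int, sample_id = fp$sample_id,
                   replicate_id = sprintf("rep%02d", r))
    })
  })
}

#' Render a peak list as a synthetic profile spectrum
#'
#' Sum of Gaussian peak shapes on a uniform m/z grid, plus a constant
#' baseline and i.i.d. Gaussian noise. Used to exercise baseline
#' estimation and peak picking end-to-end.
#'
#' @param pl an `icm_peaklist` (peak heights taken as intensities).
#' @param resolution_fwhm_da full width at half maximum of the peak shape,
#'   Da (default 8, typical of linear-mode intact-protein peaks).
#' @param baseline_level constant baseline intensity (default 0).
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (default 0).
#' @param grid_step m/z grid spacing, Da (default 1).
#' @param mz_range grid range; defaults to the peak range padded by 50 Da.
#' @param seed RNG seed for the noise (default 1).
#' @return a profile-mode `icm_spectrum`.
#' @export
render_profile <- function(pl, resolution_fwhm_da = 8, baseline_level = 0,
                           noise_sd = 0, grid_step = 1, mz_range = NULL,
                           seed = 1) {
  stopifnot(inherits(pl, "icm_peaklist"), resolution_fwhm_da > 0,
            grid_step > 0, noise_sd >= 0)
  if (is.null(mz_range)) {
    if (length(pl$mz) > 0) mz_range <- range(pl$mz) + c(-50, 50)
    else mz_range <- c(1000, 20000)
  }
  grid <- seq(mz_range[1], mz_range[2], by = grid_step)
  sigma <- resolution_fwhm_da / (2 * sqrt(2 * log(2)))
  y <- rep(baseline_level, length(grid))
  for (i in seq_along(pl$mz)) {
    lo <- findInterval(pl$mz[i] - 6 * sigma, grid) + 1L
    hi <- findInterval(pl$mz[i] + 6 * sigma, grid)
    if (hi < lo) next
    idx <- lo:hi
    y[idx] <- y[idx] + pl$intensity[i] *
      exp(-0.5 * ((grid[idx] - pl$mz[i]) / sigma)^2)
  }
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  y <- pmax(y, 0)
  new_spectrum(grid, y, sample_id = pl$sample_id,
               replicate_id = pl$replicate_id, mode = "profile",
               meta = list(synthetic = "TRUE"))
}
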