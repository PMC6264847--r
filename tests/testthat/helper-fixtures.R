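# Shared fixture builders and independent oracles.

mk_pl <- function(mz, intensity = rep(100, length(mz)), sample_id = "s",
                  replicate_id = "r1") {
  new_peaklist(mz, intensity, sample_id = sample_id,
               replicate_id = replicate_id)
}

# Minimal virtual-spectrum stand-in for score tests (only mz is used).
mk_vs <- function(mz, sample_id = "s") {
  structure(list(sample_id = sample_id, n_replicates = 1L, mz = sort(mz),
                 support = rep(1L, length(mz)),
                 mean_intensity = rep(1, length(mz)),
                 params = consensus_params()),
            class = "icm_virtual_spectrum")
}

# Exhaustive maximum-cardinality one-to-one matching between two peak sets
# (recursion over query peaks; feasible for <= 8 peaks per side).
brute_force_match_count <- function(q, r, tol) {
  best <- 0L
  rec <- function(i, used) {
    if (i > length(q)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    rec(i + 1L, used)
    for (j in which(!used & abs(r - q[i]) <= tol)) {
      used[j] <- TRUE
      rec(i + 1L, used)
      used[j] <- FALSE
    }
  }
  rec(1L, logical(length(r)))
  best
}

# Exact optimum over all contiguous tolerance-respecting partitions of a
# pooled peak set: maximize (number of kept clusters, then total support).
# Dynamic programming over prefixes enumerates every admissible partition.
oracle_consensus_kept <- function(pool_mz, pool_rep, n_rep, tol, min_frac) {
  ord <- order(pool_mz)
  mz <- pool_mz[ord]; rp <- pool_rep[ord]
  n <- length(mz)
  need <- ceiling(min_frac * n_rep - 1e-9)
  best <- matrix(-Inf, n + 1L, 2L)
  best[1L, ] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (mz[i] - mz[j] > 2 * tol) next
      sup <- length(unique(rp[j:i]))
      kept <- if (sup >= need) 1L else 0L
      cand <- best[j, ] + c(kept, if (kept > 0L) sup else 0)
      if (cand[1] > best[i + 1L, 1] ||
          (cand[1] == best[i + 1L, 1] && cand[2] > best[i + 1L, 2]))
        best[i + 1L, ] <- cand
    }
  }
  best[n + 1L, 1]
}

# Draw n values on [lo, hi] pairwise (and vs `avoid`) farther than `gap`.
draw_gapped <- function(n, lo, hi, gap, avoid = numeric(0)) {
  x <- numeric(0)
  while (length(x) < n) {
    c0 <- stats::runif(1, lo, hi)
    if (all(abs(c(x, avoid) - c0) > gap)) x <- c(x, c0)
  }
  sort(x)
}

# Random fingerprint-like score instance: a sparse reference peak set, a
# query sharing a subset of its peaks within (or just beyond) tolerance
# plus private peaks, both sides respecting the consensus gap invariant.
random_score_instance <- function(tol = 2) {
  nr <- sample(2:8, 1)
  r <- draw_gapped(nr, 5000, 5500, tol + 0.1)
  nshare <- sample(0:nr, 1)
  q <- numeric(0)
  if (nshare > 0)
    q <- r[sample(nr, nshare)] + stats::runif(nshare, -1.2 * tol, 1.2 * tol)
  npriv <- sample(0:(8 - nshare), 1)
  if (npriv > 0) q <- c(q, draw_gapped(npriv, 5000, 5500, tol + 0.1, avoid = q))
  q <- sort(q)
  if (length(q) > 1) q <- q[c(TRUE, diff(q) > tol + 0.05)]
  list(q = q, r = r)
}

# Gaussian profile rendered directly (independent of render_profile).
gaussian_profile <- function(centers, heights, sigma, grid, baseline = 0,
                             noise = NULL) {
  y <- rep(baseline, length(grid))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-0.5 * ((grid - centers[i]) / sigma)^2)
  if (!is.null(noise)) y <- y + noise
  new_spectrum(grid, pmax(y, 0), mode = "profile")
}
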