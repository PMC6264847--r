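test_that("identical replicates give back the replicate peak list", {
  mz <- c(2000, 5000, 9000)
  pls <- lapply(1:10, function(i) mk_pl(mz, replicate_id = paste0("r", i)))
  v <- build_virtual_spectrum(pls, consensus_params())
  expect_equal(v$mz, mz)
  expect_equal(v$support, rep(10L, 3))
  expect_equal(v$n_replicates, 10)

  # with min_fraction = 1 the consensus still equals any single replicate
  v1 <- build_virtual_spectrum(pls, consensus_params(min_fraction = 1))
  expect_equal(v1$mz, mz)
})

test_that("the 70% support threshold behaves as ceiling(min_fraction * n)", {
  mk_panel <- function(n_present) {
    lapply(1:10, function(i) {
      if (i <= n_present) mk_pl(5000 + (i - 5) * 0.2, replicate_id = paste0("r", i))
      else mk_pl(numeric(0), replicate_id = paste0("r", i))
    })
  }
  v7 <- build_virtual_spectrum(mk_panel(7), consensus_params())
  expect_length(v7$mz, 1)          # ceiling(0.7 * 10) = 7: kept
  expect_equal(v7$support, 7L)
  v6 <- build_virtual_spectrum(mk_panel(6), consensus_params())
  expect_length(v6$mz, 0)          # 6 < 7: dropped

  # 7 of 9 replicates: ceiling(0.7 * 9) = 7, kept
  pls9 <- mk_panel(7)[1:9]
  expect_length(build_virtual_spectrum(pls9, consensus_params())$mz, 1)
})

test_that("single-linkage chains within span 2*tol merge to the median", {
  chain <- list(mk_pl(5000.0, replicate_id = "a"),
                mk_pl(5001.5, replicate_id = "b"),
                mk_pl(5003.0, replicate_id = "c"))
  v <- build_virtual_spectrum(chain, consensus_params(tol_da = 2,
                                                      min_fraction = 0.7))
  expect_length(v$mz, 1)
  expect_equal(v$mz, 5001.5)
  expect_equal(v$support, 3L)
})

test_that("clusters wider than 2*tol are split at the largest gap", {
  # a chain with every gap at 1.8 Da (below tol) but total span 5.4 Da:
  # single linkage keeps one cluster; span repair cuts at the largest gap
  # (ties resolved to the first), leaving {5000} and {5001.8, 5003.6,
  # 5005.4}; only the triplet reaches 2-of-4 support
  pls <- list(mk_pl(5000.0, replicate_id = "a"),
              mk_pl(5001.8, replicate_id = "b"),
              mk_pl(5003.6, replicate_id = "c"),
              mk_pl(5005.4, replicate_id = "d"))
  v <- build_virtual_spectrum(pls, consensus_params(tol_da = 2,
                                                    min_fraction = 0.5))
  expect_equal(v$mz, 5003.6)
  expect_equal(v$support, 3L)

  # distinct largest gap: the cut lands there; hand trace of the pooled
  # chain {5000.0a, 5001.0b, 5002.9c, 5004.7a, 5005.7b, 5006.7c} gives
  # {a,b} (median 5000.5) and, after keeping replicate c's lower-m/z
  # duplicate only once, {c,a,b} (median 5004.7)
  pls2 <- list(mk_pl(c(5000.0, 5004.7), replicate_id = "a"),
               mk_pl(c(5001.0, 5005.7), replicate_id = "b"),
               mk_pl(c(5002.9, 5006.7), replicate_id = "c"))
  v2 <- build_virtual_spectrum(pls2, consensus_params(tol_da = 2,
                                                      min_fraction = 0.5))
  expect_equal(v2$mz, c(5000.5, 5004.7))
  expect_equal(v2$support, c(2L, 3L))
})

test_that("consensus is independent of replicate input order", {
  cfg <- sim_config(n_clades = 1, strains_per_clade = 1, seed = 9)
  fp <- generate_fingerprints(cfg)[[1]]
  pls <- simulate_replicates(fp, cfg)
  v1 <- build_virtual_spectrum(pls)
  set.seed(1)
  for (k in 1:5) {
    v2 <- build_virtual_spectrum(sample(pls))
    expect_identical(v2$mz, v1$mz)
    expect_identical(v2$support, v1$support)
  }
})

test_that("support is monotone in the replicate set", {
  cfg <- sim_config(n_clades = 1, strains_per_clade = 1,
                    n_peaks_per_strain = 10, seed = 5)
  fp <- generate_fingerprints(cfg)[[1]]
  pls <- simulate_replicates(fp, cfg)
  p <- consensus_params(min_fraction = 0.1)   # keep everything, compare support
  v_all <- build_virtual_spectrum(pls, p)
  v_less <- build_virtual_spectrum(pls[-1], p)
  for (i in seq_along(v_less$mz)) {
    j <- which.min(abs(v_all$mz - v_less$mz[i]))
    if (abs(v_all$mz[j] - v_less$mz[i]) <= 2)
      expect_lte(v_less$support[i], v_all$support[j])
  }
})

test_that("greedy consensus agrees with the exhaustive partition oracle", {
  agree <- 0; tot <- 0; disagreements <- c()
  for (s in 1:100) {
    cfg <- sim_config(n_clades = 1, strains_per_clade = 1,
                      n_peaks_per_strain = 3, n_replicates = 5,
                      spurious_rate = 0.5, mz_range = c(5000, 5200), seed = s)
    fp <- generate_fingerprints(cfg)[[1]]
    pls <- simulate_replicates(fp, cfg)
    pool_mz <- unlist(lapply(pls, `[[`, "mz"))
    pool_rep <- rep(seq_along(pls),
                    vapply(pls, function(x) length(x$mz), integer(1)))
    if (length(pool_mz) == 0 || length(pool_mz) > 20) next
    tot <- tot + 1
    v <- build_virtual_spectrum(pls, consensus_params())
    kept_opt <- oracle_consensus_kept(pool_mz, pool_rep, length(pls),
                                      tol = 2, min_frac = 0.7)
    if (length(v$mz) == kept_opt) agree <- agree + 1
    else disagreements <- c(disagreements, s)
  }
  if (length(disagreements) > 0)
    message("consensus/oracle kept-count disagreement at seeds: ",
            paste(disagreements, collapse = ", "))
  expect_gte(agree / tot, 0.95)
})

test_that("library JSON round-trips a 26-sample panel losslessly", {
  cfg <- sim_config(n_clades = 13, strains_per_clade = 2,
                    n_peaks_per_strain = 8, n_replicates = 4, seed = 2)
  fps <- generate_fingerprints(cfg)
  lib <- lapply(fps, function(fp)
    build_virtual_spectrum(simulate_replicates(fp, cfg)))
  f <- withr::local_tempfile(fileext = ".json")
  write_library(lib, f)
  back <- read_library(f)
  expect_length(back, 26)
  expect_identical(vapply(back, function(v) v$sample_id, character(1)),
                   vapply(lib, function(v) v$sample_id, character(1)))
  for (i in seq_along(lib)) {
    # JSON carries ~16 significant digits; round trip is exact to well
    # below any mass tolerance in use
    expect_equal(back[[i]]$mz, lib[[i]]$mz, tolerance = 1e-12)
    expect_identical(back[[i]]$support, lib[[i]]$support)
    expect_equal(back[[i]]$mean_intensity, lib[[i]]$mean_intensity,
                 tolerance = 1e-12)
  }
  # empty library
  write_library(list(), f)
  expect_length(read_library(f), 0)
})

test_that("consensus input errors are caught", {
  expect_error(build_virtual_spectrum(list()), "no peak lists")
  expect_error(build_virtual_spectrum(
    list(mk_pl(1000, sample_id = "a"), mk_pl(1000, sample_id = "b"))),
    "different samples")
  expect_error(consensus_params(min_fraction = 1.2))
  expect_error(consensus_params(tol_da = 0))
})
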