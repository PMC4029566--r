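# Generator determinism, ground-truth bookkeeping, and boundary behaviour.

test_that("generators are deterministic under a seed and leave the RNG stream alone", {
  a <- gen_protein(seed = 12)
  b <- gen_protein(seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$sequence, gen_protein(seed = 13)$sequence))
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(gen_protein(seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
  e1 <- gen_ensemble(n_models = 3, n_residues = 10, seed = 4)
  e2 <- gen_ensemble(n_models = 3, n_residues = 10, seed = 4)
  expect_identical(e1$coords, e2$coords)
  m1 <- gen_msa(a, n_seqs = 5, seed = 4)
  m2 <- gen_msa(a, n_seqs = 5, seed = 4)
  expect_identical(m1$msa, m2$msa)
})

test_that("protein generator honours the framework specification", {
  p <- gen_protein(seed = 21)
  expect_equal(nrow(p$framework), 8L)
  expect_equal(p$framework$ordinal, 1:8)
  gaps <- diff(p$framework$position)
  expect_equal(sum(gaps == 1), 1L)  # exactly one CC doublet
  p2 <- gen_protein(adjacent_doublet = FALSE, seed = 21)
  expect_false(any(diff(p2$framework$position) == 1))
  expect_error(gen_protein(length = 20, n_cys = 8), "too short")
  expect_error(gen_protein(n_cys = 7), "even")
})

test_that("noise-free, dropout-free MS observations equal the predicted species", {
  prot <- gen_protein(seed = 22)
  obs <- gen_ms_dataset(prot, noise_ppm = 0, dropout = 0, seed = 22)
  expect_true(all(!obs$contaminant))
  expect_equal(obs$mass, obs$true_mass)
  tr <- list(enzyme = "chymotrypsin", n_reduced = 0L, alkylated = TRUE)
  tab <- theoretical_species(prot$sequence, prot$framework, prot$pattern, tr)
  sub <- obs[obs$enzyme == "chymotrypsin" & obs$n_reduced == 0, ]
  expect_setequal(round(sub$mass, 6), round(unique(tab$mass), 6))
})

test_that("full dropout yields an empty observation list", {
  prot <- gen_protein(seed = 23)
  obs <- gen_ms_dataset(prot, dropout = 1, seed = 23)
  expect_equal(nrow(obs[!obs$contaminant, ]), 0L)
  expect_error(gen_ms_dataset(prot, treatments = list()), "empty")
})

test_that("dynamics generator hits the closed forms in the rigid limit", {
  f <- field_params()
  d <- gen_dynamics_dataset(s2 = c(1, 1), tau_m = 5e-9, tau_e = 50e-12,
                            snr = Inf, seed = 24)
  j <- function(w) spectral_density_ls(w, 5e-9)
  obs <- forward_relaxation(j, f)
  expect_equal(d$truth$r1, rep(obs$r1, 2), tolerance = 1e-12)
  expect_equal(d$truth$noe, rep(obs$noe, 2), tolerance = 1e-12)
  expect_error(gen_dynamics_dataset(0.8, tau_m = 1e-9, tau_e = 2e-9),
               "tau_e")
})

test_that("noiseless series round-trip through the fitters", {
  d <- gen_dynamics_dataset(s2 = c(0.85, 0.5), snr = Inf, seed = 25)
  for (r in 1:2) {
    s1 <- d$r1_series[d$r1_series$residue == r, ]
    f <- fit_rate(s1$delay_s, s1$intensity)
    expect_equal(f$rate, d$truth$r1[r], tolerance = 1e-3)
    s2s <- d$r2_series[d$r2_series$residue == r, ]
    f2 <- fit_rate(s2s$delay_s, s2s$intensity)
    expect_equal(f2$rate, d$truth$r2[r], tolerance = 1e-3)
  }
})

test_that("low order parameters depress the generated NOE", {
  d <- gen_dynamics_dataset(s2 = c(0.9, 0.35), tau_e = 200e-12, snr = Inf,
                            seed = 26)
  expect_lt(d$truth$noe[2], d$truth$noe[1])
})

test_that("HDX generator exercises both the fit path and the undetectable path", {
  k <- c(slow = 0.02, mid = 0.3, fast = 50)
  d <- gen_hdx_dataset(k, noise = 0, seed = 27)
  by_res <- split(d$series, d$series$residue)
  expect_false("fast" %in% names(by_res))  # gone before 3 points
  hl <- vapply(names(k), function(r) {
    s <- by_res[[r]]
    if (is.null(s) || nrow(s) < 3) NA_real_ else
      fit_hdx_halflife(s$time_h, s$integral)$half_life
  }, numeric(1))
  expect_equal(hl[["slow"]], log(2) / 0.02, tolerance = 1e-6)
  expect_setequal(classify_slow_exchangers(hl, 2.5), c("slow"))
  expect_error(gen_hdx_dataset(c(0, 1)), "positive")
})

test_that("MSA generator keeps the scaffold fixed and the region variable", {
  prot <- gen_protein(seed = 28)
  m0 <- gen_msa(prot, n_seqs = 10, sub_prob = 0, hyper_sub_prob = 0,
                region_lengths = 9, seed = 28)
  prof0 <- entropy_profile(m0$msa)
  expect_true(all(prof0$entropy[!is.na(prof0$entropy)] == 0))
  m <- gen_msa(prot, n_seqs = 40, seed = 28)
  # scaffold columns: all-cysteine
  sc <- m$truth$column[m$truth$scaffold]
  expect_true(all(m$msa[, sc] %in% c("C")))
  # drawn region lengths agree with realised spacings
  ung <- gsub("-", "", apply(m$msa, 1, paste, collapse = ""))
  ss <- spacing_stats(ung, 5)
  expect_lt(abs(ss$mean - mean(m$drawn_lengths)), 0.5)
  # hypervariable region carries most of the entropy
  prof <- entropy_profile(m$msa)
  expect_gt(mean(prof$entropy[m$region_cols], na.rm = TRUE),
            mean(prof$entropy[-c(m$region_cols, sc)], na.rm = TRUE))
})

test_that("zero-amplitude ensembles are bit-identical models", {
  ens <- gen_ensemble(n_models = 5, n_residues = 12, base_amplitude = 0,
                      sidechain_jitter = 0, seed = 29)
  for (k in 2:5)
    expect_identical(ens$coords[, , k], ens$coords[, , 1])
})
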