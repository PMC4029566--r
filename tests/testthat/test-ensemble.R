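# Ensemble superposition, RMSF, RMSD-to-mean, disulfide geometry, H-bond
# screening.

rigid_move <- function(coords, theta, shift) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  coords %*% R + matrix(shift, nrow(coords), 3, byrow = TRUE)
}

test_that("identical models superpose to identity with zero statistics", {
  ens <- gen_ensemble(n_models = 4, n_residues = 20, base_amplitude = 0,
                      seed = 1)
  sup <- superpose_ensemble(ens)
  expect_true(sup$converged)
  expect_equal(avg_rmsd_to_mean(sup)$mean, 0, tolerance = 1e-9)
  rmsf <- per_residue_rmsf(sup)
  expect_true(all(abs(rmsf$rmsf) < 1e-9))
})

test_that("a known rigid motion is inverted to numerical precision", {
  ens <- gen_ensemble(n_models = 2, n_residues = 15, base_amplitude = 0,
                      seed = 2)
  ens$coords[, , 2] <- rigid_move(ens$coords[, , 2], 0.9, c(4, -2, 7))
  sup <- superpose_ensemble(ens)
  expect_true(sup$converged)
  expect_lt(avg_rmsd_to_mean(sup)$mean, 1e-6)
  expect_equal(det(sup$rotations[[2]]), 1, tolerance = 1e-9)
})

test_that("a single model is its own mean with identity transform", {
  ens <- gen_ensemble(n_models = 1, n_residues = 10, seed = 3)
  sup <- superpose_ensemble(ens)
  expect_equal(sup$mean, ens$coords[, , 1])
  expect_equal(sup$rotations[[1]], diag(3))
})

test_that("superposition statistics are invariant to rigid pre-transformations", {
  ens <- gen_ensemble(n_models = 8, n_residues = 25, seed = 4)
  ref <- avg_rmsd_to_mean(superpose_ensemble(ens))
  ens2 <- ens
  set.seed(5)
  for (k in seq_len(ens$n_models))
    ens2$coords[, , k] <- rigid_move(ens2$coords[, , k], runif(1, 0, pi),
                                     runif(3, -20, 20))
  moved <- avg_rmsd_to_mean(superpose_ensemble(ens2))
  expect_equal(moved$per_model, ref$per_model, tolerance = 1e-6)
  rf1 <- per_residue_rmsf(superpose_ensemble(ens))
  rf2 <- per_residue_rmsf(superpose_ensemble(ens2))
  expect_equal(rf1$rmsf, rf2$rmsf, tolerance = 1e-6)
})

test_that("RMSF reproduces hand-geometry on a two-model displacement", {
  # two models, one CA displaced +/- delta/2 about the mean
  atoms <- data.frame(resno = 1:3, resid = "ALA", elety = "CA")
  base <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  delta <- 0.8
  co <- array(c(base, base), c(3, 3, 2))
  co[2, 1, 1] <- base[2, 1] - delta / 2
  co[2, 1, 2] <- base[2, 1] + delta / 2
  ens <- model_ensemble(atoms, co)
  sup <- superpose_ensemble(ens, selection = c(1, 3))  # fit on undisplaced atoms
  rmsf <- per_residue_rmsf(sup, selection = "all")
  expect_equal(rmsf$rmsf[2], delta / 2, tolerance = 1e-6)
})

test_that("region-amplified dispersion shows up as ordered RMSF", {
  ens <- gen_ensemble(n_models = 15, n_residues = 50, base_amplitude = 0.3,
                      regions = list(list(resnos = 20:30, amplitude = 0.9)),
                      seed = 6)
  sup <- superpose_ensemble(ens)
  rmsf <- per_residue_rmsf(sup)
  hot <- rmsf$rmsf[rmsf$resno %in% 20:30]
  cold <- rmsf$rmsf[!rmsf$resno %in% 20:30]
  expect_gt(mean(hot), mean(cold))
})

test_that("heavy-atom RMSD is at least backbone RMSD on generated ensembles", {
  for (s in 1:5) {
    prot <- gen_protein(seed = s)
    ens <- gen_ensemble(protein = prot, seed = s)
    sup <- superpose_ensemble(ens, "backbone")
    expect_gte(avg_rmsd_to_mean(sup, "heavy")$mean,
               avg_rmsd_to_mean(sup, "backbone")$mean)
  }
})

test_that("superposition agrees with an independent fitting implementation", {
  ens <- gen_ensemble(n_models = 6, n_residues = 20, seed = 7)
  sup <- superpose_ensemble(ens, "all")
  # bio3d as external oracle: fit all models onto the package's mean
  xyz <- t(apply(ens$coords, 3, function(m) as.vector(t(m))))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(sup$mean)), mobile = xyz))
  oracle_rmsd <- sqrt(rowMeans((fitted -
    matrix(as.vector(t(sup$mean)), nrow(fitted), ncol(fitted),
           byrow = TRUE))^2) * 3)
  expect_equal(avg_rmsd_to_mean(sup)$per_model, unname(oracle_rmsd),
               tolerance = 1e-4)
})

test_that("disulfide geometry reports distances and flags out-of-range bonds", {
  prot <- gen_protein(seed = 8)
  ens <- gen_ensemble(protein = prot, base_amplitude = 0,
                      sidechain_jitter = 0, seed = 8)
  dg <- disulfide_geometry(ens, prot$framework, prot$pattern)
  expect_true(all(!dg$missing))
  expect_equal(dg$distance, rep(2.02, 4), tolerance = 1e-6)
  expect_true(all(!dg$flagged))
  # stretch one bond beyond range
  sg <- which(ens$atoms$elety == "SG")[1]
  ens$coords[sg, , 1] <- ens$coords[sg, , 1] + c(3, 0, 0)
  dg2 <- disulfide_geometry(ens, prot$framework, prot$pattern)
  expect_true(any(dg2$flagged))
  # missing SG reported per bond
  ens$atoms$elety[sg] <- "CB"
  dg3 <- disulfide_geometry(ens, prot$framework, prot$pattern)
  expect_true(any(dg3$missing))
})

test_that("hbond screening finds placed donors and acceptors within cutoff", {
  atoms <- data.frame(resno = c(1, 1, 2, 2, 55, 55),
                      resid = "ALA",
                      elety = c("N", "O", "N", "O", "N", "H"))
  co <- rbind(c(50, 0, 0), c(10, 0, 0),   # res 1: N and O both far away
              c(20, 0, 0), c(2.0, 0, 0),  # res 2: O placed 2.0 from res55 H
              c(0.5, 0, 0), c(0, 0, 0))   # res 55 donor H at origin
  ens <- model_ensemble(atoms, array(co, c(6, 3, 1)))
  hb <- hbond_candidates(55, ens, cutoff = 2.5)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$acceptor_resno, 2)
  expect_equal(hb$donor_atom, "H")
  expect_equal(hb$distance, 2.0, tolerance = 1e-9)
  # no acceptor within cutoff
  hb0 <- hbond_candidates(1, ens, cutoff = 2.5)
  expect_equal(nrow(hb0), 0L)
  # missing donor atoms: skipped with warning
  expect_warning(hbond_candidates(99, ens), "skipped")
})

test_that("roster mismatches are rejected when building ensembles", {
  atoms <- data.frame(resno = 1, resid = "ALA", elety = "CA")
  expect_error(model_ensemble(atoms, array(0, c(2, 3, 1))), "roster")
})
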