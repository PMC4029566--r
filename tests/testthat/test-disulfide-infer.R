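# Pattern enumeration, species prediction, matching, and candidate
# elimination.

test_that("enumerate_patterns yields every perfect matching exactly once", {
  expect_equal(length(enumerate_patterns(2)), 1L)
  expect_equal(length(enumerate_patterns(4)), 3L)
  for (n in c(2, 4, 6)) {
    keys <- vapply(enumerate_patterns(n), format_pattern, character(1))
    expect_setequal(keys, oracle_matching_keys(n))
  }
  p8 <- enumerate_patterns(8)
  expect_equal(length(p8), 105L)
  expect_equal(anyDuplicated(vapply(p8, format_pattern, character(1))), 0L)
  expect_error(enumerate_patterns(5), "even")
})

test_that("adjacency_filter removes exactly the patterns bonding an adjacent pair", {
  prot <- gen_protein(seed = 5)  # CC doublet at ordinals 6-7
  gaps <- diff(prot$framework$position)
  expect_equal(which(gaps == 1), 6L)
  pats <- enumerate_patterns(8)
  kept <- adjacency_filter(pats, prot$framework)
  expect_equal(length(kept), 105L - 15L)  # matchings containing 6-7: (8-3)!! = 15
  expect_false(any(vapply(kept, function(p)
    any(p[, 1] == 6 & p[, 2] == 7), logical(1))))
  # framework with no adjacent cysteines: identity
  prot2 <- gen_protein(adjacent_doublet = FALSE, seed = 5)
  expect_equal(length(adjacency_filter(pats, prot2$framework)), 105L)
})

test_that("predict_species reproduces a hand-built toy and its boundary cases", {
  # two cysteines in separate tryptic fragments joined by one bond
  seq <- "CAKTTTCR"
  fw <- cys_framework(seq)
  pat <- matrix(c(1, 2), 1, 2)
  sp0 <- predict_species(seq, fw, pat, reduced = matrix(integer(0), 0, 2),
                         enzyme = "trypsin")
  expect_equal(length(sp0), 1L)  # the two fragments fuse through the bond
  expect_equal(nrow(sp0[[1]]$spans), 2L)
  expect_equal(species_mass(sp0[[1]]),
               peptide_mass("CAK") + peptide_mass("TTTCR") - 2 * 1.0078,
               tolerance = 1e-9)
  # reducing the only bond with alkylation: two CAM singleton species
  sp1 <- predict_species(seq, fw, pat, reduced = pat, enzyme = "trypsin",
                         alkylated = TRUE)
  expect_equal(length(sp1), 2L)
  expect_true(all(vapply(sp1, function(s) nrow(s$bonds) == 0, logical(1))))
  masses <- sort(vapply(sp1, species_mass, numeric(1)))
  expect_equal(masses,
               sort(c(peptide_mass("CAK", cam = 1),
                      peptide_mass("TTTCR", cam = 4))), tolerance = 1e-9)
  expect_error(predict_species(seq, fw, pat, reduced = matrix(c(1, 3), 1, 2)),
               "subset")
})

test_that("theoretical_species marginalises over latent reduced-bond subsets", {
  prot <- gen_protein(seed = 2)
  tr <- list(enzyme = "chymotrypsin", n_reduced = 1L, alkylated = TRUE)
  tab <- theoretical_species(prot$sequence, prot$framework, prot$pattern, tr)
  expect_equal(sort(unique(tab$reduced)),
               sort(apply(prot$pattern, 1, paste, collapse = "-")))
  expect_true(all(tab$mass > 0))
  # full reduction with alkylation: every cysteine of every species is CAM
  trf <- list(enzyme = "chymotrypsin", n_reduced = "all", alkylated = TRUE)
  tabf <- theoretical_species(prot$sequence, prot$framework, prot$pattern, trf)
  expect_equal(tabf$cam_ordinals, tabf$ordinals)
})

test_that("match_observations applies the ppm window and flags ambiguity", {
  theo <- c(1000.000, 1000.005, 2000.000)
  m <- match_observations(theo, c(1000.000, 2000.03), tol_ppm = 10)
  expect_true(m$matched[1])
  expect_equal(m$ppm_error[1], 0)
  expect_true(m$ambiguous[1])   # 1000.000 and 1000.005 are both within 10 ppm
  expect_false(m$matched[2])    # 15 ppm away
  empty <- match_observations(numeric(0), c(500))
  expect_false(empty$matched)
  expect_error(match_observations(theo, 1000, tol_ppm = 0), "tol_ppm")
})

test_that("qualitative evidence pins bonds and the candidate set shrinks monotonically", {
  prot <- gen_protein(seed = 5)
  e1 <- ssbond_evidence(ev_bond(c(1, 2)))
  e2 <- ssbond_evidence(ev_bond(c(1, 2)), ev_bond(c(4, 5)))
  r1 <- infer_patterns(prot$sequence, e1, use_adjacency_rule = FALSE)
  r2 <- infer_patterns(prot$sequence, e2, use_adjacency_rule = FALSE)
  k1 <- vapply(r1$candidates, format_pattern, character(1))
  k2 <- vapply(r2$candidates, format_pattern, character(1))
  expect_true(all(k2 %in% k1))
  expect_lt(length(k2), length(k1))
  expect_true(all(grepl("1-2", k1)))
})

test_that("adding mass observations never enlarges the candidate set", {
  prot <- gen_protein(adjacent_doublet = FALSE, seed = 9)
  obs <- gen_ms_dataset(prot, noise_ppm = 0, dropout = 0, seed = 9)
  for (cut in c(5, 15, nrow(obs))) {
    sub <- obs[seq_len(cut), , drop = FALSE]
    r_sub <- infer_patterns(prot$sequence, evidence_from_observations(sub))
    if (cut > 5) {
      k_sub <- vapply(r_sub$candidates, format_pattern, character(1))
      expect_true(all(k_sub %in% k_prev))
    }
    k_prev <- vapply(r_sub$candidates, format_pattern, character(1))
  }
})

test_that("the generating pattern survives noise-free evidence (soundness)", {
  for (s in 1:5) {
    prot <- gen_protein(adjacent_doublet = FALSE, seed = s)
    obs <- gen_ms_dataset(prot, noise_ppm = 0, dropout = 0, seed = s)
    r <- infer_patterns(prot$sequence, evidence_from_observations(obs),
                        tol_ppm = 5)
    keys <- vapply(r$candidates, format_pattern, character(1))
    expect_true(format_pattern(prot$pattern) %in% keys)
  }
})

test_that("with no observations every pattern remains", {
  prot <- gen_protein(adjacent_doublet = FALSE, seed = 3)
  expect_error(infer_patterns(prot$sequence, ssbond_evidence()),
               "at least one")
  # a single vacuous bond constraint consistent with everything containing it
  r <- infer_patterns(prot$sequence, ssbond_evidence(ev_bond(c(1, 2))),
                      use_adjacency_rule = FALSE)
  expect_equal(r$n_patterns_evaluated, 105L)
})

test_that("strict mode eliminates on any unexplained peak, default mode tolerates contaminants", {
  prot <- gen_protein(adjacent_doublet = FALSE, seed = 4)
  obs <- gen_ms_dataset(prot, noise_ppm = 0, dropout = 0, seed = 4)
  # add a contaminant peak matching nothing
  cont <- obs[1, ]; cont$mass <- 1234.5678
  obs2 <- rbind(obs, cont)
  r_tol <- infer_patterns(prot$sequence, evidence_from_observations(obs2))
  expect_true(format_pattern(prot$pattern) %in%
                vapply(r_tol$candidates, format_pattern, character(1)))
  r_strict <- infer_patterns(prot$sequence, evidence_from_observations(obs2),
                             strict = TRUE)
  expect_equal(length(r_strict$candidates), 0L)
})

test_that("pattern strings round-trip through parse and format", {
  for (k in c("1-2,3-6,4-5,7-8", "1-3,2-4,5-6,7-8", "1-2")) {
    expect_equal(format_pattern(parse_pattern(k)), k)
  }
  expect_error(canonical_pattern(matrix(c(1, 2, 2, 3), 2, 2, byrow = TRUE)),
               "matching")
})
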