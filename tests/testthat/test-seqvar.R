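# Alignment entropy, cysteine spacing, motif scanning, net charge,
# region summaries.

test_that("column entropy covers the closed-form landmark cases", {
  m <- as_msa(c("AAC", "AGC"))
  expect_equal(column_entropy(m, 1), 0)
  expect_equal(column_entropy(m, 2), 1.0)  # 50/50 two residues
  # 20 equiprobable residues hit the maximum log2(20)
  m20 <- as_msa(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  expect_equal(column_entropy(m20, 1), log2(20), tolerance = 1e-12)
})

test_that("entropy is row-permutation invariant and bounded", {
  set.seed(41)
  rows <- replicate(12, random_protein_seq(30))
  m1 <- as_msa(rows)
  m2 <- as_msa(sample(rows))
  p1 <- entropy_profile(m1); p2 <- entropy_profile(m2)
  expect_equal(p1$entropy, p2$entropy)
  expect_true(all(p1$entropy >= 0 & p1$entropy <= log2(20)))
})

test_that("gap handling separates gap fraction from residue entropy", {
  m <- as_msa(c("A-", "A-", "AC"))
  p <- entropy_profile(m)
  expect_equal(p$entropy[2], 0)          # only one non-gap residue
  expect_equal(p$gap_fraction[2], 2 / 3)
  mall <- as_msa(c("-A", "-C"))
  expect_true(is.na(column_entropy(mall, 1)))
  expect_equal(column_entropy(mall, 1, gaps = "as_symbol"), 0)
})

test_that("ragged or invalid alignments are rejected with the offending row", {
  expect_error(as_msa(c("AAC", "AA")), "ragged")
  expect_error(as_msa(c("AAC", "AZ-")), "invalid")
})

test_that("cysteine spacings count strictly-between residues and reconstruct positions", {
  expect_equal(cysteine_spacings("CC"), 0L)
  expect_equal(cysteine_spacings("CAAAC"), 3L)
  expect_warning(sp <- cysteine_spacings("ACA"), "fewer than 2")
  expect_length(sp, 0)
  set.seed(43)
  for (i in 1:20) {
    s <- random_protein_seq(50)
    fw <- cys_framework(s)
    if (nrow(fw) >= 2) {
      sp <- cysteine_spacings(s)
      rebuilt <- fw$position[1] + cumsum(sp + 1L)
      expect_equal(rebuilt, fw$position[-1])
    }
  }
})

test_that("spacing_stats summarises a gap across sequences", {
  s <- spacing_stats(c("CAAAAAAAAC", "CAAAAAAAAC"), 1)
  expect_equal(s$mean, 8)
  expect_equal(s$sd, 0)
  expect_equal(s$conservation, 1.0)
  s2 <- spacing_stats(c(paste0("C", strrep("A", 8), "C"),
                        paste0("C", strrep("A", 9), "C"),
                        paste0("C", strrep("A", 10), "C")), 1)
  expect_equal(s2$mean, 9)
  expect_equal(s2$sd, 1)
  # sequences lacking the pair are excluded and counted
  s3 <- spacing_stats(c("CAAAC", "AAAA"), 1)
  expect_equal(s3$n_excluded, 1L)
  expect_error(spacing_stats(c("AAA"), 1), "no sequence")
})

test_that("the TFP cysteine-framework query matches a constructed scaffold", {
  q <- "C-x(5,30)-C-x(2,10)-C-x(10,30)-C-x(2,20)-C-x(5,30)-C-C-x(4)-C-N"
  s <- paste0("C", strrep("A", 6), "C", strrep("G", 3), "C", strrep("A", 12),
              "C", strrep("G", 3), "C", strrep("A", 6), "CC", "GGGG", "C", "N")
  hits <- scan_motif(s, q)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$x_lengths, "6,3,12,3,6,4")
  # violating a literal anchor (terminal N): no match
  expect_equal(nrow(scan_motif(sub("N$", "A", s), q)), 0L)
  # wildcard below its minimum: no match
  s_short <- sub(strrep("A", 12), strrep("A", 8), s, fixed = TRUE)
  expect_equal(nrow(scan_motif(s_short, q)), 0L)
})

test_that("scan_motif agrees with an interval-DP oracle on random inputs", {
  set.seed(47)
  pat <- parse_prosite("C-x(1,5)-C-x(2)-[DE]-C")
  for (i in 1:300) {
    s <- random_protein_seq(sample(8:40, 1))
    chars <- strsplit(s, "")[[1]]
    hit <- scan_motif(s, pat)
    oracle_end <- oracle_motif_match_at(chars, pat$elements,
                                        start = if (nrow(hit)) hit$start[1] else 1L)
    if (nrow(hit)) {
      expect_false(is.na(oracle_end))
    } else {
      # no match anywhere per the oracle either
      any_hit <- any(vapply(seq_along(chars), function(st)
        !is.na(oracle_motif_match_at(chars, pat$elements, st)), logical(1)))
      expect_false(any_hit)
    }
  }
})

test_that("malformed motif patterns are rejected with a position", {
  expect_error(parse_prosite("C--C"), "empty")
  expect_error(parse_prosite("C-x(5,2)-C"), "min exceeds max")
  expect_error(parse_prosite("C-?-C"), "element 2")
  q <- "C-x(2,4)-[DE]-x-C"
  expect_equal(format(parse_prosite(q)), q)
})

test_that("net charge follows the residue-class conventions and is additive", {
  expect_equal(net_charge("GGGG"), 0)
  expect_equal(net_charge("DDKK"), 0)
  expect_equal(net_charge("DEKRH", his = 1), 1)
  expect_equal(net_charge("DEKRH", his = 0), 0)
  set.seed(53)
  for (i in 1:20) {
    a <- random_protein_seq(15); b <- random_protein_seq(20)
    expect_equal(net_charge(paste0(a, b)), net_charge(a) + net_charge(b))
  }
})

test_that("region summaries cross-tabulate conservation with selection classes", {
  # 12-site region: 9 vary, 7 of those under positive selection
  ent <- data.frame(column = 1:20,
                    entropy = c(rep(0, 8), rep(1.5, 9), rep(0, 3)),
                    gap_fraction = 0)
  sel <- c(rep("purifying", 8),
           rep("positive_p01", 4), rep("positive_p05", 3), rep("neutral", 2),
           rep("neutral", 3))
  region <- 6:17  # 3 conserved + 9 variable sites
  rs <- region_selection_summary(ent, sel, region)
  expect_equal(rs$n_nonconserved, 9L)
  expect_equal(rs$n_positive_nonconserved, 7L)
  # all-conserved region
  rs0 <- region_selection_summary(ent, sel, 1:5)
  expect_equal(rs0$n_nonconserved, 0L)
  # empty annotation: conservation counts only
  rs_na <- region_selection_summary(ent, NULL, region)
  expect_true(is.na(rs_na$n_positive_nonconserved))
  expect_error(region_selection_summary(ent, sel, 15:25), "outside")
})
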