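# Independent oracles used across test files; deliberately implemented
# differently from the package internals.

# brute-force peptide mass: per-character lookup and explicit summation
oracle_peptide_mass <- function(seq, scale = "mono") {
  tab <- residue_mass_table()
  chars <- strsplit(seq, "")[[1]]
  total <- tab$water[[scale]]
  for (ch in chars) total <- total + tab[[scale]][[ch]]
  total
}

# perfect matchings counted through permutations: pair up positions
# (1,2), (3,4), ... of each permutation of 1..n and de-duplicate
oracle_matching_keys <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  keys <- vapply(perms(seq_len(n)), function(p) {
    m <- matrix(p, ncol = 2, byrow = TRUE)
    m <- t(apply(m, 1, sort))
    m <- m[order(m[, 1]), , drop = FALSE]
    paste(apply(m, 1, paste, collapse = "-"), collapse = ",")
  }, character(1))
  unique(keys)
}

double_factorial <- function(n) prod(seq(n, 1, by = -2))

# regex-free interval-DP motif matcher: reach[i, p] = TRUE when elements
# 1..i can consume exactly characters start..p-1
oracle_motif_match_at <- function(chars, elements, start) {
  n <- length(chars); k <- length(elements)
  reach <- matrix(FALSE, k + 1L, n + 2L)
  reach[1L, start] <- TRUE
  for (i in seq_len(k)) {
    el <- elements[[i]]
    for (p in which(reach[i, ])) {
      if (el$kind %in% c("literal", "class")) {
        if (p <= n && chars[p] %in% el$residues) reach[i + 1L, p + 1L] <- TRUE
      } else {
        for (L in el$min:el$max)
          if (p + L <= n + 1L) reach[i + 1L, p + L] <- TRUE
      }
    }
  }
  ends <- which(reach[k + 1L, ]) - 1L
  if (length(ends)) min(ends) else NA_integer_
}

random_protein_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                               "K", "L", "R", "S", "T", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
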