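# Candidate-elimination inference of disulfide connectivity from
# partial-reduction / alkylation mass-spectral evidence.

#' Cysteine framework of a sequence
#'
#' @param sequence Ungapped amino-acid string.
#' @return data.frame with `ordinal` (1..k in sequence order) and `position`
#'   (1-based sequence position) of every cysteine.
#' @export
cys_framework <- function(sequence) {
  chars <- .check_sequence(sequence)
  pos <- which(chars == "C")
  data.frame(ordinal = seq_along(pos), position = pos)
}

#' Enumerate all disulfide patterns
#'
#' All perfect matchings of `n` cysteine ordinals; there are
#' (n - 1)!! of them.
#'
#' @param n_cysteines Even number of cysteines (>= 2).
#' @return List of patterns, each a two-column matrix of ordinal pairs with
#'   rows sorted and each row ordered.
#' @export
enumerate_patterns <- function(n_cysteines) {
  n <- as.integer(n_cysteines)
  if (n < 2 || n %% 2 != 0)
    stop("n_cysteines must be even and >= 2")
  rec <- function(free) {
    if (!length(free)) return(list(matrix(integer(0), 0, 2)))
    a <- free[1]
    out <- list()
    for (b in free[-1]) {
      rest <- setdiff(free, c(a, b))
      for (m in rec(rest))
        out[[length(out) + 1L]] <- rbind(c(a, b), m)
    }
    out
  }
  lapply(rec(seq_len(n)), canonical_pattern)
}

#' Canonicalise a disulfide pattern
#'
#' @param pattern Two-column matrix (or list of pairs) of cysteine ordinals.
#' @return Matrix with each row ordered low-high and rows sorted by first
#'   ordinal.
#' @export
canonical_pattern <- function(pattern) {
  m <- matrix(as.integer(pattern), ncol = 2)
  m <- t(apply(m, 1, sort))
  m <- m[order(m[, 1]), , drop = FALSE]
  ords <- as.vector(m)
  if (anyDuplicated(ords))
    stop("pattern is not a matching: repeated ordinal")
  m
}

pattern_key <- function(pattern) {
  paste(apply(pattern, 1, paste, collapse = "-"), collapse = ",")
}

#' Format a pattern as "1-2,3-6,4-5,7-8"
#' @param pattern Two-column ordinal matrix.
#' @return Character scalar.
#' @export
format_pattern <- function(pattern) pattern_key(canonical_pattern(pattern))

#' Parse a pattern string like "1-2,3-6,4-5,7-8"
#' @param x Character scalar.
#' @return Two-column ordinal matrix.
#' @export
parse_pattern <- function(x) {
  pairs <- strsplit(strsplit(x, ",")[[1]], "-")
  canonical_pattern(do.call(rbind, lapply(pairs, as.integer)))
}

#' Remove patterns bonding sequence-adjacent cysteines
#'
#' Disulfides between cysteines adjacent in sequence are extremely rare; this
#' filter drops every pattern containing a bond whose two cysteines are within
#' `min_sequence_gap` residues of each other.
#'
#' @param patterns List of ordinal-pair matrices.
#' @param framework [cys_framework()] of the sequence.
#' @param min_sequence_gap Bonds with position difference <= this are
#'   disallowed (default 1: only directly adjacent pairs).
#' @return Filtered pattern list.
#' @export
adjacency_filter <- function(patterns, framework, min_sequence_gap = 1L) {
  pos <- framework$position[order(framework$ordinal)]
  keep <- vapply(patterns, function(p) {
    d <- abs(pos[p[, 1]] - pos[p[, 2]])
    all(d > min_sequence_gap)
  }, logical(1))
  patterns[keep]
}

#' Predict disulfide-linked species under a treatment
#'
#' Digests the sequence, removes the reduced bonds, joins the remaining
#' fragments into connected species through the intact bonds, and assigns
#' modification states: cysteines of reduced bonds become CAM if the treatment
#' alkylates, otherwise free thiols.
#'
#' @param sequence Parent sequence.
#' @param framework [cys_framework()] of the sequence.
#' @param pattern Ordinal-pair matrix (perfect matching).
#' @param reduced Ordinal-pair matrix of the bonds reduced in this species
#'   (subset of `pattern`); 0-row matrix for the untouched protein.
#' @param enzyme Protease passed to [digest()].
#' @param alkylated Logical: were freed thiols CAM-alkylated?
#' @param max_missed Missed cleavages allowed when forming species.
#' @return List of [linked_species()].
#' @export
predict_species <- function(sequence, framework, pattern, reduced,
                            enzyme = "chymotrypsin", alkylated = TRUE,
                            max_missed = 0L) {
  pattern <- canonical_pattern(pattern)
  if (length(unique(as.vector(pattern))) != nrow(framework))
    stop("pattern is not a perfect matching over the framework")
  reduced <- matrix(as.integer(reduced), ncol = 2)
  if (nrow(reduced)) {
    rk <- apply(t(apply(reduced, 1, sort)), 1, paste, collapse = "-")
    pk <- apply(pattern, 1, paste, collapse = "-")
    if (!all(rk %in% pk)) stop("reduced bonds must be a subset of the pattern")
    intact <- pattern[!pk %in% rk, , drop = FALSE]
  } else intact <- pattern
  pos <- framework$position[order(framework$ordinal)]
  frags <- digest(sequence, enzyme, max_missed = 0L)
  nf <- nrow(frags)
  frag_of <- function(p) which(frags$start <= p & frags$end >= p)[1]
  # union-find over base fragments via intact bonds
  comp <- seq_len(nf)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(intact)) {
    for (b in seq_len(nrow(intact))) {
      i <- find(frag_of(pos[intact[b, 1]]))
      j <- find(frag_of(pos[intact[b, 2]]))
      if (i != j) comp[j] <- i
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  groups <- split(seq_len(nf), roots)
  cam_pos <- if (alkylated) pos[as.vector(reduced)] else integer(0)
  build <- function(frag_idx) {
    spans <- frags[frag_idx, c("start", "end"), drop = FALSE]
    inside <- function(p) any(spans$start <= p & spans$end >= p)
    bonds <- intact[apply(intact, 1, function(b) inside(pos[b[1]])),
                    , drop = FALSE]
    bmat <- if (nrow(bonds))
      cbind(pos[bonds[, 1]], pos[bonds[, 2]]) else matrix(integer(0), 0, 2)
    linked_species(sequence, spans, bonds = bmat,
                   cam = cam_pos[vapply(cam_pos, inside, logical(1))])
  }
  species <- lapply(groups, build)
  if (max_missed > 0L) {
    # components adjacent through consecutive base fragments can merge via
    # uncut sites; enumerate connected unions of <= max_missed + 1 components
    gids <- seq_along(groups)
    adj <- matrix(FALSE, length(gids), length(gids))
    memb <- rep(NA_integer_, nf)
    for (g in gids) memb[groups[[g]]] <- g
    for (i in seq_len(nf - 1L))
      if (memb[i] != memb[i + 1L])
        adj[memb[i], memb[i + 1L]] <- adj[memb[i + 1L], memb[i]] <- TRUE
    seen <- character(0)
    grow <- function(set, budget) {
      if (budget == 0L) return()
      nb <- which(apply(adj[set, , drop = FALSE], 2, any))
      for (g in setdiff(nb, set)) {
        ns <- sort(c(set, g))
        key <- paste(ns, collapse = "+")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          species[[length(species) + 1L]] <<-
            build(sort(unlist(groups[ns])))
          grow(ns, budget - 1L)
        }
      }
    }
    for (g in gids) grow(g, as.integer(max_missed))
  }
  unname(species)
}

#' Theoretical species table for one treatment
#'
#' Enumerates every species mass predicted under a pattern for a treatment,
#' marginalising over which bonds were reduced: all subsets of the stated
#' cardinality are tried (the partial-reduction experiment does not reveal
#' which bonds were cleaved).
#'
#' @param sequence,framework,pattern As in [predict_species()].
#' @param treatment List with `enzyme`, `n_reduced` (0..n bonds, or `"all"`
#'   for full DTT reduction), `alkylated` (logical).
#' @param max_missed Missed cleavages.
#' @param scale Mass scale.
#' @return data.frame with `mass`, `n_reduced`, `reduced` (bond string),
#'   `cam_ordinals`, `ordinals` (cysteine ordinals in the species).
#' @export
theoretical_species <- function(sequence, framework, pattern, treatment,
                                max_missed = 0L, scale = "mono") {
  pattern <- canonical_pattern(pattern)
  nb <- nrow(pattern)
  n_red <- treatment$n_reduced
  if (identical(n_red, "all")) n_red <- nb
  if (n_red > nb) stop("cannot reduce more bonds than the pattern holds")
  subsets <- utils::combn(nb, n_red, simplify = FALSE)
  if (n_red == 0L) subsets <- list(integer(0))
  if (max_missed == 0L) {
    ctx <- .seq_context(sequence, framework, scale)
    rows <- lapply(subsets, function(ss) {
      red <- pattern[ss, , drop = FALSE]
      intact <- pattern[setdiff(seq_len(nb), ss), , drop = FALSE]
      sp <- .species_masses(ctx, treatment$enzyme, intact, as.vector(red),
                            isTRUE(treatment$alkylated))
      sp$n_reduced <- length(ss)
      sp$reduced <- pattern_key(red)
      sp[, c("mass", "n_reduced", "reduced", "cam_ordinals", "ordinals")]
    })
    return(unique(do.call(rbind, rows)))
  }
  pos <- framework$position[order(framework$ordinal)]
  ord_of <- stats::setNames(framework$ordinal, framework$position)
  rows <- list()
  for (ss in subsets) {
    red <- pattern[ss, , drop = FALSE]
    sp <- predict_species(sequence, framework, pattern, red,
                          enzyme = treatment$enzyme,
                          alkylated = isTRUE(treatment$alkylated),
                          max_missed = max_missed)
    for (s in sp) {
      cys_in <- framework$position[vapply(framework$position, function(p)
        any(s$spans$start <= p & s$spans$end >= p), logical(1))]
      rows[[length(rows) + 1L]] <- data.frame(
        mass = species_mass(s, scale = scale),
        n_reduced = length(ss),
        reduced = pattern_key(if (nrow(red)) red else
          matrix(integer(0), 0, 2)),
        cam_ordinals = paste(sort(ord_of[as.character(s$cam)]),
                             collapse = ","),
        ordinals = paste(sort(ord_of[as.character(cys_in)]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  unique(out)
}

#' Match observed masses against theoretical species
#'
#' @param theoretical Numeric vector (or data.frame with `mass`) of predicted
#'   neutral masses.
#' @param observations Numeric vector of observed neutral masses.
#' @param tol_ppm Relative tolerance in parts per million.
#' @return data.frame with one row per observation: `observed`, `n_matches`,
#'   `best_theoretical`, `ppm_error`, `matched`, `ambiguous`.
#' @export
match_observations <- function(theoretical, observations, tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  theo <- if (is.data.frame(theoretical)) theoretical$mass else theoretical
  out <- lapply(observations, function(obs) {
    if (!length(theo)) {
      return(data.frame(observed = obs, n_matches = 0L,
                        best_theoretical = NA_real_, ppm_error = NA_real_,
                        matched = FALSE, ambiguous = FALSE))
    }
    ppm <- abs(obs - theo) / theo * 1e6
    hits <- which(ppm <= tol_ppm)
    best <- if (length(hits)) hits[which.min(ppm[hits])] else NA_integer_
    data.frame(observed = obs, n_matches = length(hits),
               best_theoretical = if (length(hits)) theo[best] else NA_real_,
               ppm_error = if (length(hits)) ppm[best] else NA_real_,
               matched = length(hits) > 0L,
               ambiguous = length(unique(round(theo[hits], 6))) > 1L)
  })
  do.call(rbind, out)
}

#' Assemble an evidence set for pattern inference
#'
#' Evidence items are lists with a `type` field:
#' \describe{
#'   \item{`mass`}{`mass` (Da), optional `tol_ppm`, `enzyme`, `n_reduced`,
#'     `alkylated`; optional `no_cam` / `require_ordinals` fragment-level
#'     annotations restricting which species may explain the peak.}
#'   \item{`bond`}{`pair = c(i, j)`: the pattern must contain bond i-j
#'     (a peptide pair directly observed to be disulfide-linked).}
#'   \item{`no_cam`}{`ordinals_present`, `ordinal`, `enzyme`, `n_reduced`,
#'     `alkylated`: some reduced-bond assignment must predict a species
#'     containing all `ordinals_present` with `ordinal` not alkylated.}
#' }
#'
#' @param ... Evidence items (lists as above).
#' @return Object of class `ssbond_evidence`.
#' @export
ssbond_evidence <- function(...) {
  items <- list(...)
  for (it in items) {
    if (!is.list(it) || is.null(it$type) ||
        !it$type %in% c("mass", "bond", "no_cam"))
      stop("evidence items must be lists with type mass/bond/no_cam")
  }
  structure(items, class = "ssbond_evidence")
}

#' Shorthand constructors for evidence items
#' @param pair Ordinal pair for a directly observed bond.
#' @rdname ssbond_evidence
#' @export
ev_bond <- function(pair) list(type = "bond", pair = sort(as.integer(pair)))

#' @param mass Observed neutral mass (Da).
#' @param enzyme,n_reduced,alkylated Treatment under which it was observed.
#' @param tol_ppm Per-observation tolerance override.
#' @param no_cam Ordinals that must not carry CAM in the explaining species.
#' @param require_ordinals Ordinals the explaining species must contain.
#' @rdname ssbond_evidence
#' @export
ev_mass <- function(mass, enzyme, n_reduced, alkylated = TRUE,
                    tol_ppm = NULL, no_cam = NULL, require_ordinals = NULL) {
  list(type = "mass", mass = mass, enzyme = enzyme, n_reduced = n_reduced,
       alkylated = alkylated, tol_ppm = tol_ppm, no_cam = no_cam,
       require_ordinals = require_ordinals)
}

#' @param ordinals_present Cysteine ordinals observed together in one species.
#' @param ordinal The ordinal observed unalkylated.
#' @rdname ssbond_evidence
#' @export
ev_no_cam <- function(ordinals_present, ordinal, enzyme,
                      n_reduced = 1L, alkylated = TRUE) {
  list(type = "no_cam", ordinals_present = as.integer(ordinals_present),
       ordinal = as.integer(ordinal), enzyme = enzyme,
       n_reduced = n_reduced, alkylated = alkylated)
}

.species_cache_key <- function(pattern, treatment, max_missed) {
  paste(pattern_key(pattern), treatment$enzyme, treatment$n_reduced,
        isTRUE(treatment$alkylated), max_missed, sep = "|")
}

# Precomputed per-sequence state for fast species-mass enumeration:
# cumulative residue masses, digest fragments per enzyme, cysteine
# position -> fragment maps.
.seq_context <- function(sequence, framework, scale) {
  chars <- .check_sequence(sequence)
  tab <- residue_mass_table()
  cum <- c(0, cumsum(tab[[scale]][chars]))
  ctx <- new.env(parent = emptyenv())
  ctx$water <- tab$water[[scale]]
  ctx$cam <- tab$cam[[scale]]
  ctx$ssloss <- tab$ss_h_loss[[scale]]
  ctx$cum <- cum
  ctx$sequence <- sequence
  ctx$pos <- framework$position[order(framework$ordinal)]
  ctx$enzymes <- list()
  ctx
}

.ctx_frags <- function(ctx, enzyme) {
  if (is.null(ctx$enzymes[[enzyme]])) {
    fr <- digest(ctx$sequence, enzyme, max_missed = 0L)
    frag_of_cys <- vapply(ctx$pos, function(p)
      which(fr$start <= p & fr$end >= p)[1], integer(1))
    ctx$enzymes[[enzyme]] <- list(start = fr$start, end = fr$end,
                                  frag_of_cys = frag_of_cys)
  }
  ctx$enzymes[[enzyme]]
}

# species masses for one pattern under one (enzyme, reduced subset,
# alkylated) condition; returns data.frame(mass, cam_ordinals, ordinals)
.species_masses <- function(ctx, enzyme, intact, reduced_ords, alkylated) {
  fr <- .ctx_frags(ctx, enzyme)
  nf <- length(fr$start)
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(intact)) {
    for (b in seq_len(nrow(intact))) {
      i <- find(fr$frag_of_cys[intact[b, 1]])
      j <- find(fr$frag_of_cys[intact[b, 2]])
      if (i != j) parent[j] <- i
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  frag_mass <- ctx$cum[fr$end + 1L] - ctx$cum[fr$start] + ctx$water
  comp_mass <- tapply(frag_mass, roots, sum)
  cys_root <- roots[fr$frag_of_cys]
  n_ord <- length(ctx$pos)
  bonded <- rep(FALSE, n_ord)
  if (nrow(intact)) bonded[as.vector(intact)] <- TRUE
  cammed <- rep(FALSE, n_ord)
  if (alkylated && length(reduced_ords)) cammed[reduced_ords] <- TRUE
  keys <- names(comp_mass)
  mass <- as.numeric(comp_mass)
  cam_s <- character(length(keys)); ord_s <- character(length(keys))
  for (ci in seq_along(keys)) {
    ords <- which(cys_root == as.integer(keys[ci]))
    mass[ci] <- mass[ci] + ctx$cam * sum(cammed[ords]) -
      ctx$ssloss * sum(bonded[ords])
    cam_s[ci] <- paste(ords[cammed[ords]], collapse = ",")
    ord_s[ci] <- paste(ords, collapse = ",")
  }
  data.frame(mass = mass, cam_ordinals = cam_s, ordinals = ord_s,
             stringsAsFactors = FALSE)
}

# all species for one pattern under a treatment, marginalised over the
# latent reduced-bond subset (fast path, 0 missed cleavages)
.treatment_species <- function(ctx, pattern, treatment) {
  nb <- nrow(pattern)
  n_red <- treatment$n_reduced
  if (identical(n_red, "all")) n_red <- nb
  subsets <- if (n_red == 0L) list(integer(0)) else
    utils::combn(nb, n_red, simplify = FALSE)
  out <- lapply(subsets, function(ss) {
    intact <- pattern[setdiff(seq_len(nb), ss), , drop = FALSE]
    .species_masses(ctx, treatment$enzyme, intact,
                    as.vector(pattern[ss, , drop = FALSE]),
                    isTRUE(treatment$alkylated))
  })
  unique(do.call(rbind, out))
}

#' Infer disulfide patterns from partial-reduction evidence
#'
#' Enumerates all perfect matchings over the cysteine framework (optionally
#' pre-filtered by the adjacency rule), predicts the mass-spectral species
#' each pattern would produce under each treatment, and eliminates patterns
#' contradicted by the evidence. By default an unexplained mass eliminates a
#' pattern only if some other pattern explains it (guarding against
#' contaminant peaks); `strict = TRUE` makes any unexplained mass fatal.
#'
#' @param sequence Protein sequence (ungapped).
#' @param evidence [ssbond_evidence()] object.
#' @param tol_ppm Default mass tolerance (ppm).
#' @param use_adjacency_rule Drop patterns bonding sequence-adjacent
#'   cysteines before evaluation.
#' @param strict Elimination semantics for unexplained masses.
#' @param max_missed Missed cleavages allowed in species prediction.
#' @param scale Mass scale for theoretical species.
#' @return Object of class `ssbond_inference`: `candidates` (list of
#'   patterns), `table` (per-pattern diagnostics), `n_patterns_evaluated`.
#' @export
infer_patterns <- function(sequence, evidence, tol_ppm = 10,
                           use_adjacency_rule = TRUE, strict = FALSE,
                           max_missed = 0L, scale = "mono") {
  if (!length(evidence)) stop("at least one evidence item is required")
  framework <- cys_framework(sequence)
  n <- nrow(framework)
  patterns <- enumerate_patterns(n)
  if (use_adjacency_rule)
    patterns <- adjacency_filter(patterns, framework)
  cache <- new.env(parent = emptyenv())
  ctx <- if (max_missed == 0L) .seq_context(sequence, framework, scale)
  theo <- function(pattern, treatment) {
    key <- .species_cache_key(pattern, treatment, max_missed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- if (max_missed == 0L)
        .treatment_species(ctx, pattern, treatment)
      else theoretical_species(sequence, framework, pattern, treatment,
                               max_missed, scale)
    }
    cache[[key]]
  }
  mass_items <- Filter(function(it) it$type == "mass", evidence)
  # explained[p, m]: pattern p explains mass item m
  explained <- matrix(TRUE, length(patterns), length(mass_items))
  logical_ok <- matrix(TRUE, length(patterns),
                       sum(vapply(evidence, function(it)
                         it$type != "mass", logical(1))))
  for (pi in seq_along(patterns)) {
    p <- patterns[[pi]]
    pk <- apply(p, 1, paste, collapse = "-")
    mi <- 0L; li <- 0L
    for (it in evidence) {
      if (it$type == "bond") {
        li <- li + 1L
        logical_ok[pi, li] <- paste(it$pair, collapse = "-") %in% pk
      } else if (it$type == "no_cam") {
        li <- li + 1L
        tab <- theo(p, list(enzyme = it$enzyme, n_reduced = it$n_reduced,
                            alkylated = it$alkylated))
        has_all <- vapply(strsplit(tab$ordinals, ","), function(o)
          all(it$ordinals_present %in% as.integer(o)), logical(1))
        cand <- tab[has_all, , drop = FALSE]
        ok <- FALSE
        if (nrow(cand)) {
          for (r in seq_len(nrow(cand))) {
            cams <- as.integer(strsplit(cand$cam_ordinals[r], ",")[[1]])
            if (!it$ordinal %in% cams) { ok <- TRUE; break }
          }
        }
        logical_ok[pi, li] <- ok
      } else {
        mi <- mi + 1L
        tab <- theo(p, list(enzyme = it$enzyme, n_reduced = it$n_reduced,
                            alkylated = it$alkylated))
        if (!is.null(it$require_ordinals)) {
          need <- as.integer(it$require_ordinals)
          keep <- vapply(strsplit(tab$ordinals, ","), function(o)
            all(need %in% as.integer(o)), logical(1))
          tab <- tab[keep, , drop = FALSE]
        }
        if (!is.null(it$no_cam) && nrow(tab)) {
          keep <- vapply(strsplit(tab$cam_ordinals, ","), function(cm)
            !any(as.integer(it$no_cam) %in% suppressWarnings(as.integer(cm))),
            logical(1))
          tab <- tab[keep, , drop = FALSE]
        }
        tol <- if (is.null(it$tol_ppm)) tol_ppm else it$tol_ppm
        explained[pi, mi] <- nrow(tab) > 0 &&
          any(abs(it$mass - tab$mass) / tab$mass * 1e6 <= tol)
      }
    }
  }
  # non-strict: an unexplained mass counts against a pattern only when some
  # other pattern explains it (otherwise it is treated as a contaminant)
  informative <- if (ncol(explained))
    apply(explained, 2, any) else logical(0)
  contradictions <- integer(length(patterns))
  for (pi in seq_along(patterns)) {
    cm <- if (strict) sum(!explained[pi, ]) else
      sum(!explained[pi, ] & informative)
    contradictions[pi] <- cm + sum(!logical_ok[pi, ])
  }
  n_expl <- if (ncol(explained)) rowSums(explained) else
    integer(length(patterns))
  tab <- data.frame(
    pattern = vapply(patterns, pattern_key, character(1)),
    explained = n_expl,
    contradictions = contradictions,
    consistent = contradictions == 0L,
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$consistent, -tab$explained, tab$pattern), ]
  rownames(tab) <- NULL
  structure(list(candidates = patterns[contradictions == 0L],
                 table = tab,
                 n_patterns_evaluated = length(patterns),
                 framework = framework,
                 tol_ppm = tol_ppm, strict = strict,
                 use_adjacency_rule = use_adjacency_rule),
            class = "ssbond_inference")
}

#' @export
print.ssbond_inference <- function(x, ...) {
  cat(sprintf(
    "<ssbond_inference> %d pattern(s) evaluated, %d candidate(s) remain\n",
    x$n_patterns_evaluated, length(x$candidates)))
  for (p in x$candidates) cat("  ", pattern_key(p), "\n")
  invisible(x)
}

#' @export
summary.ssbond_inference <- function(object, ...) {
  cat(sprintf("Patterns evaluated: %d (adjacency rule %s, %s matching, %g ppm)\n",
              object$n_patterns_evaluated,
              if (object$use_adjacency_rule) "on" else "off",
              if (object$strict) "strict" else "contaminant-tolerant",
              object$tol_ppm))
  print(utils::head(object$table, 10))
  invisible(object)
}
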