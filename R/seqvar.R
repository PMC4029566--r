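# Alignment variability, cysteine-framework geometry, ProSite-style motif
# scanning, net charge, and per-region selection summaries.

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build an MSA object from aligned sequences
#'
#' @param sequences Character vector of equal-length aligned rows (gap `-`).
#' @param ids Sequence ids (default seq_along).
#' @return Character matrix (rows = sequences) of class `msa`.
#' @export
as_msa <- function(sequences, ids = NULL) {
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop(sprintf("ragged alignment: row %d has length %d (expected %d)",
                 which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]))
  m <- do.call(rbind, strsplit(sequences, ""))
  bad <- !(m %in% c(.aa20, "-", "."))
  if (any(bad))
    stop(sprintf("invalid alignment character '%s'", m[bad][1]))
  m[m == "."] <- "-"
  rownames(m) <- if (is.null(ids)) as.character(seq_along(sequences)) else ids
  class(m) <- c("msa", class(m))
  m
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum p_a log2 p_a` over residue frequencies. Gaps are excluded from
#' the frequencies by default and reported separately via
#' [entropy_profile()]; an all-gap column has no defined entropy.
#'
#' @param msa An [as_msa()] matrix.
#' @param column Column index.
#' @param gaps `"exclude"` (default) or `"as_symbol"` (count the gap as a
#'   21st symbol).
#' @return Entropy in bits, or `NA` for an all-gap column.
#' @export
column_entropy <- function(msa, column, gaps = c("exclude", "as_symbol")) {
  gaps <- match.arg(gaps)
  if (column < 1 || column > ncol(msa)) stop("invalid column index")
  col <- msa[, column]
  if (gaps == "exclude") col <- col[col != "-"]
  if (!length(col)) return(NA_real_)
  p <- table(col) / length(col)
  -sum(p * log2(p))
}

#' Per-column entropy and gap-fraction profile
#'
#' @param msa An [as_msa()] matrix.
#' @param gaps Gap handling, see [column_entropy()].
#' @return data.frame with `column`, `entropy` (bits; `NA` where all-gap),
#'   `gap_fraction`.
#' @export
entropy_profile <- function(msa, gaps = "exclude") {
  data.frame(
    column = seq_len(ncol(msa)),
    entropy = vapply(seq_len(ncol(msa)),
                     function(j) column_entropy(msa, j, gaps), numeric(1)),
    gap_fraction = colMeans(msa == "-"))
}

#' Inter-cysteine spacing profile
#'
#' Number of residues strictly between consecutive cysteines, in order.
#'
#' @param sequence Ungapped amino-acid string.
#' @return Integer vector of length (number of cysteines - 1); empty with a
#'   warning when the sequence has fewer than 2 cysteines.
#' @export
cysteine_spacings <- function(sequence) {
  fw <- cys_framework(sequence)
  if (nrow(fw) < 2) {
    warning("fewer than 2 cysteines: empty spacing profile")
    return(integer(0))
  }
  diff(fw$position) - 1L
}

#' Spacing statistics for one inter-cysteine gap across sequences
#'
#' @param sequences Character vector of ungapped sequences.
#' @param gap_index Which gap (1 = between Cys1 and Cys2, ...).
#' @return List: `mean`, `sd`, `conservation` (fraction of usable sequences
#'   sharing the modal gap), `n_used`, `n_excluded` (sequences lacking the
#'   cysteine pair), `values`.
#' @export
spacing_stats <- function(sequences, gap_index) {
  vals <- vapply(sequences, function(s) {
    sp <- suppressWarnings(cysteine_spacings(s))
    if (length(sp) >= gap_index) sp[gap_index] else NA_integer_
  }, integer(1))
  used <- vals[!is.na(vals)]
  if (!length(used)) stop("no sequence has the requested cysteine pair")
  modal <- as.integer(names(which.max(table(used))))
  list(mean = mean(used), sd = stats::sd(used),
       conservation = mean(used == modal),
       n_used = length(used), n_excluded = sum(is.na(vals)),
       values = unname(used))
}

#' Parse a ProSite-style pattern
#'
#' Supports literal residues, bracketed classes `[ABC]`, and wildcards `x`,
#' `x(n)`, `x(min,max)`, with `-` separators.
#'
#' @param pattern Pattern string, e.g.
#'   `"C-x(5,30)-C-x(2,10)-C-x(10,30)-C-x(2,20)-C-x(5,30)-C-C-x(4)-C-N"`.
#' @return Object of class `motif_pattern`: list of elements, each
#'   `list(kind = "literal"/"class"/"x", residues =, min =, max =)`.
#' @export
parse_prosite <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(toks) || any(!nzchar(toks)))
    stop("malformed pattern: empty element")
  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[i]
    if (grepl("^[A-WYZ]$", tk) && tk != "X") {
      elements[[i]] <- list(kind = "literal", residues = tk, min = 1L, max = 1L)
    } else if (grepl("^\\[[A-Z]+\\]$", tk)) {
      elements[[i]] <- list(kind = "class",
                            residues = strsplit(gsub("\\[|\\]", "", tk),
                                                "")[[1]],
                            min = 1L, max = 1L)
    } else if (tk == "x" || tk == "X") {
      elements[[i]] <- list(kind = "x", residues = NULL, min = 1L, max = 1L)
    } else if (grepl("^[xX]\\(\\d+\\)$", tk)) {
      n <- as.integer(gsub("[xX()]", "", tk))
      elements[[i]] <- list(kind = "x", residues = NULL, min = n, max = n)
    } else if (grepl("^[xX]\\(\\d+,\\d+\\)$", tk)) {
      mm <- as.integer(strsplit(gsub("[xX()]", "", tk), ",")[[1]])
      if (mm[1] > mm[2]) stop(sprintf("element %d: min exceeds max", i))
      elements[[i]] <- list(kind = "x", residues = NULL,
                            min = mm[1], max = mm[2])
    } else {
      stop(sprintf("malformed pattern element %d: '%s'", i, tk))
    }
  }
  structure(list(pattern = pattern, elements = elements),
            class = "motif_pattern")
}

#' @export
format.motif_pattern <- function(x, ...) {
  vapply(x$elements, function(el) {
    if (el$kind == "literal") el$residues
    else if (el$kind == "class") paste0("[", paste(el$residues, collapse = ""), "]")
    else if (el$min == 1 && el$max == 1) "x"
    else if (el$min == el$max) sprintf("x(%d)", el$min)
    else sprintf("x(%d,%d)", el$min, el$max)
  }, character(1)) |> paste(collapse = "-")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", format(x), "\n")
  invisible(x)
}

#' Scan a sequence for a ProSite-style motif
#'
#' Finds non-overlapping matches left to right (leftmost match wins, scanning
#' resumes after its end); each wildcard element is matched lazily (shortest
#' realisation first). Per-match wildcard lengths are reported: for the
#' cysteine-framework query these are exactly the inter-cysteine spacings.
#'
#' @param sequence Ungapped amino-acid string.
#' @param pattern A pattern string or [parse_prosite()] object.
#' @return data.frame with `start`, `end` and `x_lengths` (comma-joined
#'   realised lengths of the variable-length elements); zero rows when the
#'   sequence does not match.
#' @export
scan_motif <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- .check_sequence(sequence)
  n <- length(chars)
  els <- pattern$elements
  # depth-first lazy match of elements starting at position pos
  match_from <- function(pos) {
    lens <- integer(0)
    rec <- function(ei, p) {
      if (ei > length(els)) return(p - 1L)  # end position
      el <- els[[ei]]
      if (el$kind %in% c("literal", "class")) {
        if (p > n || !chars[p] %in% el$residues) return(NA_integer_)
        return(rec(ei + 1L, p + 1L))
      }
      for (L in el$min:el$max) {
        if (p + L - 1L > n) break
        res <- rec(ei + 1L, p + L)
        if (!is.na(res)) {
          lens <<- c(L, lens)
          return(res)
        }
      }
      NA_integer_
    }
    end <- rec(1L, pos)
    if (is.na(end)) NULL else list(start = pos, end = end, lens = lens)
  }
  var_idx <- which(vapply(els, function(e)
    e$kind == "x" && (e$min != e$max || e$max != 1L), logical(1)))
  out <- list(); pos <- 1L
  while (pos <= n) {
    m <- match_from(pos)
    if (!is.null(m)) {
      # lens accumulate outermost-first during unwinding: element order
      all_x <- which(vapply(els, function(e) e$kind == "x", logical(1)))
      lens_by_el <- stats::setNames(m$lens, all_x)
      out[[length(out) + 1L]] <- data.frame(
        start = m$start, end = m$end,
        x_lengths = paste(lens_by_el[as.character(var_idx)], collapse = ","),
        stringsAsFactors = FALSE)
      pos <- m$end + 1L
    } else pos <- pos + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      x_lengths = character(0)))
  do.call(rbind, out)
}

#' Net charge of a sequence
#'
#' Counts basic minus acidic residues: Asp/Glu -1, Lys/Arg +1, histidine
#' contribution configurable (default +1, matching the basic-residue class
#' Lys/Arg/His).
#'
#' @param sequence Ungapped amino-acid string.
#' @param his Charge assigned to histidine (typically +1 or 0).
#' @return Integer (or non-integer if `his` is fractional).
#' @export
net_charge <- function(sequence, his = 1) {
  chars <- .check_sequence(sequence)
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E")) +
    his * sum(chars == "H")
}

#' Cross-tabulate conservation with selection classes over a region
#'
#' Splits the region's sites into conserved vs non-conserved by an entropy
#' threshold and counts selection classes within each group; the headline
#' quantity is how many non-conserved sites carry positive-selection
#' signatures.
#'
#' @param entropy_profile data.frame from [entropy_profile()] (reference
#'   coordinates).
#' @param selection Optional factor/character vector per site with levels
#'   among `purifying`, `neutral`, `positive_p05`, `positive_p01`; `NULL`
#'   counts by conservation only.
#' @param region Integer vector of site indices (reference coordinates),
#'   e.g. the residues strictly between Cys5 and Cys6.
#' @param entropy_threshold Sites with entropy strictly above this are
#'   non-conserved (default 0: any variation).
#' @return List: `n_sites`, `n_conserved`, `n_nonconserved`,
#'   `n_positive_nonconserved`, `table` (counts by conservation x class).
#' @export
region_selection_summary <- function(entropy_profile, selection = NULL,
                                     region, entropy_threshold = 0) {
  if (any(region < 1 | region > nrow(entropy_profile)))
    stop("region outside the reference profile")
  h <- entropy_profile$entropy[region]
  noncons <- !is.na(h) & h > entropy_threshold
  res <- list(n_sites = length(region),
              n_conserved = sum(!noncons),
              n_nonconserved = sum(noncons))
  if (is.null(selection)) {
    res$n_positive_nonconserved <- NA_integer_
    res$table <- table(conserved = !noncons)
    return(res)
  }
  cls <- as.character(selection[region])
  positive <- cls %in% c("positive_p05", "positive_p01")
  res$n_positive_nonconserved <- sum(noncons & positive)
  res$table <- table(conserved = ifelse(noncons, "non-conserved",
                                        "conserved"),
                     class = cls)
  res
}
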