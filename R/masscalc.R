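# Residue-level mass arithmetic and in-silico proteolysis for
# disulfide-linked peptide species.

# Monoisotopic / average residue masses (Da) for the 20 standard amino acids,
# plus water and hydrogen. Residue mass = mass of the amino acid minus water.
.residue_masses <- local({
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
          "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
  mono <- c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841,
            101.04768, 103.00919, 113.08406, 113.08406, 114.04293,
            115.02694, 128.05858, 128.09496, 129.04259, 131.04049,
            137.05891, 147.06841, 156.10111, 163.06333, 186.07931)
  avg <- c(57.0519, 71.0788, 87.0782, 97.1167, 99.1326,
           101.1051, 103.1388, 113.1594, 113.1594, 114.1038,
           115.0886, 128.1307, 128.1741, 129.1155, 131.1926,
           137.1411, 147.1766, 156.1875, 163.1760, 186.2132)
  list(mono = stats::setNames(mono, aa), avg = stats::setNames(avg, aa))
})

# CAM = carboxyamidomethyl adduct left by iodoacetamide on a free thiol.
.mass_constants <- list(
  water    = c(mono = 18.010565, avg = 18.01528),
  hydrogen = c(mono = 1.007825, avg = 1.00794),
  cam      = c(mono = 57.02146, avg = 57.0513),
  # per-cysteine mass lost when the thiol enters a disulfide; applied at the
  # same printed value on both mass scales
  ss_h_loss = c(mono = 1.0078, avg = 1.0078)
)

#' Residue mass table
#'
#' Returns the built-in monoisotopic and average residue masses (Da) used by
#' all mass computations, or a table read from a user TSV with columns
#' `residue`, `mono`, `avg`.
#'
#' @param path Optional TSV file overriding the built-in table.
#' @return A list with named numeric vectors `mono` and `avg` (residue masses,
#'   Da), plus `water`, `hydrogen`, `cam` and `ss_h_loss` constants.
#' @export
residue_mass_table <- function(path = NULL) {
  tab <- .residue_masses
  if (!is.null(path)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("residue", "mono", "avg") %in% names(df)))
    tab <- list(mono = stats::setNames(df$mono, df$residue),
                avg  = stats::setNames(df$avg, df$residue))
  }
  if (any(tab$mono <= 0) || any(tab$avg <= 0))
    stop("residue masses must be positive")
  if (any(tab$mono > tab$avg[names(tab$mono)]))
    stop("monoisotopic residue mass exceeds average mass")
  c(tab, .mass_constants)
}

.check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(.residue_masses$mono))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", chars[bad[1]], bad[1]))
  chars
}

#' Peptide mass with cysteine modifications
#'
#' Mass of a linear peptide: sum of residue masses plus one water, plus the
#' CAM addition for each alkylated cysteine, minus the per-cysteine hydrogen
#' loss (1.0078 Da) for each disulfide-bonded cysteine.
#'
#' @param sequence Amino-acid string (20 standard residues).
#' @param scale `"mono"` or `"avg"`.
#' @param cam Positions (1-based within `sequence`) of CAM-alkylated cysteines.
#' @param bonded Positions of disulfide-bonded cysteines.
#' @param table Mass table from [residue_mass_table()].
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, scale = c("mono", "avg"),
                         cam = integer(0), bonded = integer(0),
                         table = residue_mass_table()) {
  scale <- match.arg(scale)
  chars <- if (nzchar(sequence)) .check_sequence(sequence) else character(0)
  mods <- c(cam, bonded)
  if (length(mods)) {
    if (any(mods < 1 | mods > length(chars)))
      stop("modification position outside sequence")
    if (any(chars[mods] != "C"))
      stop(sprintf("modification at non-cysteine position %d",
                   mods[which(chars[mods] != "C")[1]]))
    if (length(intersect(cam, bonded)))
      stop("a cysteine cannot be both CAM-alkylated and disulfide-bonded")
  }
  sum(table[[scale]][chars]) + table$water[[scale]] +
    length(cam) * table$cam[[scale]] -
    length(bonded) * table$ss_h_loss[[scale]]
}

#' Disulfide mass correction
#'
#' Mass delta for `n` disulfide-bonded cysteines: -1.0078 Da per cysteine,
#' accounting for the protons displaced when thiols form S-S bonds.
#'
#' @param n_bonded Number of bonded cysteines (not bonds).
#' @param scale `"mono"` or `"avg"`.
#' @return Signed mass delta in Da (<= 0).
#' @export
disulfide_correction <- function(n_bonded, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  if (n_bonded < 0) stop("n_bonded must be non-negative")
  -.mass_constants$ss_h_loss[[scale]] * n_bonded
}

.enzyme_rules <- list(
  # cleave C-terminal to these residues, suppressed before proline
  trypsin      = list(after = c("K", "R"), not_before = "P"),
  chymotrypsin = list(after = c("F", "Y", "W", "L"), not_before = "P"),
  # AspN cleaves N-terminal to aspartate
  AspN         = list(before = "D")
)

#' In-silico proteolytic digestion
#'
#' Cleaves a sequence by the named protease rule and returns peptide spans.
#' At `max_missed = 0` the spans tile the sequence; with `k` missed cleavages
#' every union of up to `k + 1` adjacent fragments is also returned.
#'
#' @param sequence Amino-acid string.
#' @param enzyme `"trypsin"` (after K/R, not before P), `"chymotrypsin"`
#'   (after F/Y/W/L, not before P) or `"AspN"` (before D).
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `missed`, `peptide`.
#' @export
digest <- function(sequence, enzyme = c("trypsin", "chymotrypsin", "AspN"),
                   max_missed = 0L) {
  enzyme <- match.arg(enzyme)
  chars <- .check_sequence(sequence)
  n <- length(chars)
  if (n == 0) stop("empty sequence")
  if (max_missed < 0) stop("max_missed must be >= 0")
  rule <- .enzyme_rules[[enzyme]]
  # cut after position i (between i and i+1)?
  cut <- rep(FALSE, n - 1L)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      if (!is.null(rule$after)) {
        cut[i] <- chars[i] %in% rule$after &&
          !(identical(rule$not_before, chars[i + 1L]))
      } else {
        cut[i] <- chars[i + 1L] %in% rule$before
      }
    }
  }
  starts <- c(1L, which(cut) + 1L)
  ends <- c(which(cut), n)
  out <- list()
  nf <- length(starts)
  for (k in 0:max_missed) {
    for (i in seq_len(nf - k)) {
      s <- starts[i]; e <- ends[i + k]
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, missed = k,
        peptide = substr(sequence, s, e), stringsAsFactors = FALSE)
    }
    if (nf - k <= 0) break
  }
  do.call(rbind, out)
}

#' Construct a disulfide-linked species
#'
#' A species is a set of peptide spans joined into one connected unit by
#' intact disulfide bonds, with a modification state over its cysteines.
#'
#' @param parent Parent amino-acid sequence.
#' @param spans data.frame with `start`, `end` (1-based inclusive).
#' @param bonds Two-column matrix of parent cysteine positions joined by
#'   intact disulfides (possibly 0 rows).
#' @param cam Parent positions of CAM-alkylated cysteines inside the spans.
#' @return An object of class `linked_species`.
#' @export
linked_species <- function(parent, spans, bonds = matrix(integer(0), 0, 2),
                           cam = integer(0)) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  spans <- spans[order(spans$start), , drop = FALSE]
  chars <- .check_sequence(parent)
  in_span <- function(pos) {
    w <- which(spans$start <= pos & spans$end >= pos)
    if (!length(w)) stop(sprintf("position %d outside all spans", pos))
    w[1]
  }
  if (nrow(bonds)) {
    for (p in as.vector(bonds))
      if (chars[p] != "C") stop(sprintf("bond at non-cysteine position %d", p))
  }
  # connectivity: spans as nodes, bonds as edges
  if (nrow(spans) > 1) {
    comp <- seq_len(nrow(spans))
    if (nrow(bonds)) {
      for (b in seq_len(nrow(bonds))) {
        i <- in_span(bonds[b, 1]); j <- in_span(bonds[b, 2])
        comp[comp == comp[j]] <- comp[i]
      }
    }
    if (length(unique(comp)) > 1)
      stop("spans and bonds do not form a connected species")
  } else if (nrow(bonds)) {
    vapply(as.vector(bonds), in_span, integer(1))
  }
  structure(list(parent = parent, spans = spans, bonds = bonds,
                 cam = as.integer(cam)),
            class = "linked_species")
}

#' Mass of a disulfide-linked species
#'
#' Sum of the member peptide masses (each with its own water), minus the
#' per-cysteine hydrogen loss for every bonded cysteine, plus the CAM delta
#' for every alkylated cysteine.
#'
#' @param species A [linked_species()] object.
#' @param scale `"mono"` or `"avg"`.
#' @param table Mass table from [residue_mass_table()].
#' @return Mass in Da.
#' @export
species_mass <- function(species, scale = c("mono", "avg"),
                         table = residue_mass_table()) {
  scale <- match.arg(scale)
  stopifnot(inherits(species, "linked_species"))
  total <- 0
  bonded <- unique(as.vector(species$bonds))
  for (i in seq_len(nrow(species$spans))) {
    s <- species$spans$start[i]; e <- species$spans$end[i]
    loc <- function(pos) pos[pos >= s & pos <= e] - s + 1L
    total <- total + peptide_mass(substr(species$parent, s, e), scale,
                                  cam = loc(species$cam),
                                  bonded = loc(bonded), table = table)
  }
  total
}

#' @export
print.linked_species <- function(x, ...) {
  cat(sprintf("<linked_species> %d span(s), %d intact bond(s), %d CAM site(s)\n",
              nrow(x$spans), nrow(x$bonds), length(x$cam)))
  for (i in seq_len(nrow(x$spans)))
    cat(sprintf("  [%d-%d] %s\n", x$spans$start[i], x$spans$end[i],
                substr(x$parent, x$spans$start[i], x$spans$end[i])))
  invisible(x)
}
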