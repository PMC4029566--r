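# Multi-model coordinate-ensemble statistics: iterative-mean Kabsch
# superposition, per-residue RMSF, RMSD-to-mean, disulfide geometry, and
# hydrogen-bond candidate screening.

#' Construct a model ensemble
#'
#' @param atoms data.frame with one row per atom: `resno` (residue number),
#'   `resid` (residue type, 3-letter or 1-letter), `elety` (atom name, e.g.
#'   `N`, `CA`, `C`, `O`, `SG`).
#' @param coords Numeric array `n_atoms x 3 x n_models`; every model shares
#'   the identical atom roster.
#' @return Object of class `model_ensemble`.
#' @export
model_ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resid", "elety") %in% names(atoms)))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3)
    stop("coords must be n_atoms x 3 x n_models matching the atom roster")
  structure(list(atoms = atoms, coords = coords,
                 n_models = dim(coords)[3]),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d model(s), %d atoms, %d residues\n",
              x$n_models, nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses MODEL/ENDMDL blocks via bio3d; altloc A is preferred when present.
#'
#' @param path PDB file path.
#' @return A [model_ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  idx <- which(keep)
  m <- nrow(xyz)
  coords <- array(NA_real_, c(length(idx), 3, m))
  for (k in seq_len(m))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)[idx, ]
  atoms <- data.frame(resno = at$resno[idx], resid = at$resid[idx],
                      elety = at$elety[idx], stringsAsFactors = FALSE)
  model_ensemble(atoms, coords)
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param ensemble A [model_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  xyz <- t(apply(ensemble$coords, 3, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ensemble$atoms$resno,
                   resid = ensemble$atoms$resid,
                   elety = ensemble$atoms$elety)
  invisible(path)
}

#' Resolve an atom selection to roster indices
#'
#' @param ensemble A [model_ensemble()].
#' @param selection `"backbone"` (N, CA, C, O), `"backbone3"` (N, CA, C),
#'   `"heavy"` (all non-hydrogen atoms), `"all"`, a character vector of atom
#'   names, or an integer index vector.
#' @return Integer atom indices.
#' @export
select_atoms <- function(ensemble, selection = "backbone") {
  at <- ensemble$atoms
  if (is.numeric(selection)) return(as.integer(selection))
  if (length(selection) == 1 && selection %in%
      c("backbone", "backbone3", "heavy", "all")) {
    idx <- switch(selection,
      backbone  = which(at$elety %in% c("N", "CA", "C", "O")),
      backbone3 = which(at$elety %in% c("N", "CA", "C")),
      heavy     = which(!grepl("^H", at$elety)),
      all       = seq_len(nrow(at)))
  } else idx <- which(at$elety %in% selection)
  if (!length(idx)) stop("selection matches no atoms")
  idx
}

# Kabsch: proper rotation (det +1) and translation mapping P onto Q
# (n x 3 matrices); returns list(R, t) with fitted = P %*% R + t.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)  # right-multiplication: P %*% R
  t <- cq - cp %*% R
  list(R = R, t = as.vector(t))
}

#' Superpose an ensemble onto its iterative mean structure
#'
#' Each model is least-squares fitted (Kabsch, proper rotations only) onto
#' the mean structure over the selected atoms; the mean is re-estimated and
#' the cycle repeats until it shifts by less than `tol` Angstrom (RMS).
#'
#' @param ensemble A [model_ensemble()].
#' @param selection Atom selection for the fit (see [select_atoms()]); the
#'   transform is applied to all atoms.
#' @param tol Convergence tolerance on the mean-structure shift (Angstrom).
#' @param max_iter Iteration cap.
#' @return Object of class `superposition`: `ensemble` (transformed),
#'   `mean` (n_atoms x 3), `rotations`, `translations`, `iterations`,
#'   `converged`, `selection` (indices used).
#' @export
superpose_ensemble <- function(ensemble, selection = "backbone",
                               tol = 1e-6, max_iter = 100) {
  idx <- select_atoms(ensemble, selection)
  coords <- ensemble$coords
  m <- ensemble$n_models
  rots <- vector("list", m); trans <- vector("list", m)
  for (k in seq_len(m)) { rots[[k]] <- diag(3); trans[[k]] <- numeric(3) }
  if (m == 1) {
    return(structure(list(ensemble = ensemble, mean = coords[, , 1],
                          rotations = rots, translations = trans,
                          iterations = 0L, converged = TRUE,
                          selection = idx),
                     class = "superposition"))
  }
  ref <- coords[, , 1]
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (k in seq_len(m)) {
      f <- kabsch(coords[idx, , k], ref[idx, , drop = FALSE])
      coords[, , k] <- coords[, , k] %*% f$R +
        matrix(f$t, nrow(ensemble$atoms), 3, byrow = TRUE)
      rots[[k]] <- rots[[k]] %*% f$R
      trans[[k]] <- as.vector(trans[[k]] %*% f$R) + f$t
    }
    new_mean <- apply(coords, c(1, 2), mean)
    shift <- sqrt(mean((new_mean[idx, ] - ref[idx, ])^2))
    ref <- new_mean
    if (shift < tol) { converged <- TRUE; break }
  }
  out <- ensemble
  out$coords <- coords
  structure(list(ensemble = out, mean = ref, rotations = rots,
                 translations = trans, iterations = it,
                 converged = converged, selection = idx),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d model(s), %d fit atoms, %d iteration(s), %s\n",
              x$ensemble$n_models, length(x$selection), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-residue RMSF of a superposed ensemble
#'
#' `RMSF_r = sqrt(mean over models and selected atoms of residue r of the
#' squared deviation from the mean structure)`.
#'
#' @param sup A [superpose_ensemble()] result.
#' @param selection Atom selection (defaults to the fit selection).
#' @return data.frame with `resno` and `rmsf` (Angstrom); residues absent
#'   from the selection are reported with `NA`.
#' @export
per_residue_rmsf <- function(sup, selection = NULL) {
  stopifnot(inherits(sup, "superposition"))
  idx <- if (is.null(selection)) sup$selection else
    select_atoms(sup$ensemble, selection)
  at <- sup$ensemble$atoms
  coords <- sup$ensemble$coords
  resnos <- sort(unique(at$resno))
  rmsf <- vapply(resnos, function(r) {
    ai <- intersect(which(at$resno == r), idx)
    if (!length(ai)) return(NA_real_)
    dev2 <- 0
    for (k in seq_len(sup$ensemble$n_models)) {
      co_k <- coords[, , k]
      dev2 <- dev2 + sum((co_k[ai, , drop = FALSE] -
                            sup$mean[ai, , drop = FALSE])^2)
    }
    sqrt(dev2 / (length(ai) * sup$ensemble$n_models))
  }, numeric(1))
  data.frame(resno = resnos, rmsf = rmsf)
}

#' Average RMSD of ensemble members to the mean structure
#'
#' @param sup A [superpose_ensemble()] result.
#' @param selection Atom selection (defaults to the fit selection).
#' @return List: `mean`, `sd`, `per_model` (Angstrom).
#' @export
avg_rmsd_to_mean <- function(sup, selection = NULL) {
  stopifnot(inherits(sup, "superposition"))
  idx <- if (is.null(selection)) sup$selection else
    select_atoms(sup$ensemble, selection)
  coords <- sup$ensemble$coords
  per_model <- vapply(seq_len(sup$ensemble$n_models), function(k) {
    co_k <- coords[, , k]
    sqrt(mean(rowSums((co_k[idx, , drop = FALSE] -
                         sup$mean[idx, , drop = FALSE])^2)))
  }, numeric(1))
  list(mean = mean(per_model), sd = stats::sd(per_model),
       per_model = per_model)
}

#' Disulfide Sgamma-Sgamma distances in one model
#'
#' @param ensemble A [model_ensemble()].
#' @param framework [cys_framework()] giving cysteine positions (residue
#'   numbers).
#' @param pattern Ordinal-pair matrix of disulfide bonds.
#' @param model Model index.
#' @param range Acceptable S-S distance range (Angstrom).
#' @return data.frame with `bond`, `distance`, `flagged`, `missing`.
#' @export
disulfide_geometry <- function(ensemble, framework, pattern, model = 1L,
                               range = c(1.8, 2.5)) {
  pattern <- canonical_pattern(pattern)
  at <- ensemble$atoms
  co <- ensemble$coords[, , model]
  pos <- framework$position[order(framework$ordinal)]
  sg_of <- function(resno) {
    w <- which(at$resno == resno & at$elety == "SG")
    if (!length(w)) NA_integer_ else w[1]
  }
  rows <- lapply(seq_len(nrow(pattern)), function(b) {
    i <- sg_of(pos[pattern[b, 1]]); j <- sg_of(pos[pattern[b, 2]])
    if (is.na(i) || is.na(j)) {
      return(data.frame(bond = pattern_key(pattern[b, , drop = FALSE]),
                        distance = NA_real_, flagged = NA, missing = TRUE))
    }
    d <- sqrt(sum((co[i, ] - co[j, ])^2))
    data.frame(bond = pattern_key(pattern[b, , drop = FALSE]),
               distance = d, flagged = d < range[1] || d > range[2],
               missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Hydrogen-bond candidates for slow-exchanging amides
#'
#' For each slow-exchanging residue, reports every backbone carbonyl oxygen
#' within the donor-acceptor cutoff of the residue's amide proton (atom `H`;
#' the amide `N` is used as a proxy when no proton is present, as in
#' heavy-atom-only models).
#'
#' @param residues Residue numbers of slow exchangers.
#' @param ensemble A [model_ensemble()].
#' @param model Model index.
#' @param cutoff Donor-acceptor distance cutoff (Angstrom), default 2.5.
#' @return data.frame with `donor_resno`, `acceptor_resno`, `distance`,
#'   `donor_atom`; residues whose donor atom is missing are skipped with a
#'   warning.
#' @export
hbond_candidates <- function(residues, ensemble, model = 1L, cutoff = 2.5) {
  at <- ensemble$atoms
  co <- ensemble$coords[, , model]
  acc <- which(at$elety == "O")
  rows <- list()
  for (r in residues) {
    di <- which(at$resno == r & at$elety == "H")
    datom <- "H"
    if (!length(di)) { di <- which(at$resno == r & at$elety == "N"); datom <- "N" }
    if (!length(di)) {
      warning(sprintf("residue %s: no amide donor atom; skipped", r))
      next
    }
    di <- di[1]
    for (a in acc) {
      if (at$resno[a] == r) next
      d <- sqrt(sum((co[di, ] - co[a, ])^2))
      if (d < cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          donor_resno = r, acceptor_resno = at$resno[a],
          distance = d, donor_atom = datom, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor_resno = integer(0), acceptor_resno = integer(0),
                      distance = numeric(0), donor_atom = character(0)))
  do.call(rbind, rows)
}
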