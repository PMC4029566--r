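# Seedable generators emulating the statistical structure of each input:
# 8-cysteine proteins with a hidden disulfide pattern, partial-reduction MS
# observations, Lipari-Szabo relaxation series, H/D exchange decays,
# cysteine-scaffold MSAs with a hypervariable region, and coordinate
# ensembles with region-dependent dispersion.

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# per-generator substreams from one master seed
.substream <- function(seed, offset) (as.integer(seed) * 7L + offset) %% 2147483629L

#' Generate a synthetic disulfide-rich protein
#'
#' Draws a random sequence carrying `n_cys` cysteines (optionally with one
#' adjacent CC doublet, mirroring the three-finger-protein scaffold) and
#' attaches a ground-truth disulfide pattern.
#'
#' @param length Sequence length (default 60, typical of mature three-finger
#'   proteins).
#' @param n_cys Number of cysteines (even, default 8).
#' @param pattern Ground-truth pattern (ordinal pairs); default the shuffled
#'   pattern 1-2,3-6,4-5,7-8; use [parse_pattern()] for others.
#' @param adjacent_doublet Place exactly one CC doublet (at ordinals
#'   `n_cys - 2`, `n_cys - 1` as in the TFP C-C-x(4)-C motif).
#' @param seed Integer seed; same seed gives identical output.
#' @return List of class `synthetic_protein`: `sequence`, `framework`,
#'   `pattern`.
#' @export
gen_protein <- function(length = 60L, n_cys = 8L,
                        pattern = parse_pattern("1-2,3-6,4-5,7-8"),
                        adjacent_doublet = TRUE, seed = 1L) {
  if (n_cys %% 2 != 0) stop("n_cys must be even")
  if (length < 3L * n_cys) stop("sequence too short for this many cysteines")
  pattern <- canonical_pattern(pattern)
  if (length(unique(as.vector(pattern))) != n_cys)
    stop("pattern must be a perfect matching over n_cys ordinals")
  aa_no_c <- setdiff(.aa20, "C")
  with_seed(.substream(seed, 1L), {
    repeat {
      pos <- sort(sample(2:(length - 1L), n_cys))
      gaps <- diff(pos)
      n_adj <- sum(gaps == 1)
      ok <- if (adjacent_doublet)
        n_adj == 1 && gaps[n_cys - 2L] == 1 && all(gaps[-(n_cys - 2L)] >= 3)
      else n_adj == 0 && all(gaps >= 3)
      if (ok) break
    }
    chars <- sample(aa_no_c, length, replace = TRUE)
    chars[pos] <- "C"
    # the partial-reduction design relies on proteolysis separating the
    # cysteines: seed every inter-cysteine segment (and the termini) with a
    # chymotrypsin site (L) and an AspN site (D), as in protease choice for
    # a real mapping experiment
    bounds <- c(1L, pos, length)
    for (si in seq_len(base::length(bounds) - 1L)) {
      lo <- bounds[si]; hi <- bounds[si + 1L]
      if (hi - lo < 2L) next
      seg <- setdiff((lo + 1L):(hi - 1L), pos)
      if (base::length(seg) >= 2) {
        pick <- sample(seg, 2)
        chars[pick[1]] <- "L"
        chars[pick[2]] <- "D"
      }
    }
    seq <- paste(chars, collapse = "")
    structure(list(sequence = seq, framework = cys_framework(seq),
                   pattern = pattern),
              class = "synthetic_protein")
  })
}

#' @export
print.synthetic_protein <- function(x, ...) {
  cat(sprintf("<synthetic_protein> %d aa, %d cysteines, pattern %s\n",
              nchar(x$sequence), nrow(x$framework), pattern_key(x$pattern)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Default partial-reduction treatment grid
#'
#' Chymotrypsin and AspN digests of the intact protein (0 bonds reduced) and
#' of the singly-reduced, alkylated species.
#'
#' @param enzymes Protease names.
#' @param n_reduced Reduction cardinalities to include.
#' @return List of treatment lists (`enzyme`, `n_reduced`, `alkylated`).
#' @export
default_treatments <- function(enzymes = c("chymotrypsin", "AspN"),
                               n_reduced = c(0L, 1L)) {
  out <- list()
  for (e in enzymes) for (k in n_reduced)
    out[[length(out) + 1L]] <- list(enzyme = e, n_reduced = k,
                                    alkylated = TRUE)
  out
}

#' Simulate partial-reduction mass-spectral observations
#'
#' Predicts every species mass under the protein's true pattern for each
#' treatment (marginalising over which bonds were reduced), perturbs masses
#' with ppm-scale Gaussian noise, thins peaks by a dropout probability, and
#' adds contaminant peaks drawn uniformly in log-mass over the observed
#' range.
#'
#' @param protein A [gen_protein()] result (or list with `sequence`,
#'   `framework`, `pattern`).
#' @param treatments Treatment list, e.g. [default_treatments()].
#' @param noise_ppm Gaussian mass noise (ppm standard deviation).
#' @param dropout Probability a true peak is not observed.
#' @param n_contaminants Contaminant peaks per treatment.
#' @param scale Mass scale.
#' @param seed Integer seed.
#' @return data.frame of class `ms_dataset`: `mass`, `enzyme`, `n_reduced`,
#'   `alkylated`, `contaminant` plus the ground-truth `true_mass`.
#' @export
gen_ms_dataset <- function(protein, treatments = default_treatments(),
                           noise_ppm = 5, dropout = 0.2,
                           n_contaminants = 0L, scale = "mono", seed = 1L) {
  if (!length(treatments)) stop("empty treatment list")
  with_seed(.substream(seed, 2L), {
    rows <- list()
    for (tr in treatments) {
      tab <- theoretical_species(protein$sequence, protein$framework,
                                 protein$pattern, tr, scale = scale)
      masses <- unique(tab$mass)
      keep <- stats::runif(length(masses)) >= dropout
      masses <- masses[keep]
      if (length(masses)) {
        obs <- masses * (1 + stats::rnorm(length(masses)) * noise_ppm * 1e-6)
        rows[[length(rows) + 1L]] <- data.frame(
          mass = obs, enzyme = tr$enzyme, n_reduced = tr$n_reduced,
          alkylated = isTRUE(tr$alkylated), contaminant = FALSE,
          true_mass = masses, stringsAsFactors = FALSE)
      }
      if (n_contaminants > 0L && length(tab$mass)) {
        lm <- range(log(tab$mass))
        cm <- exp(stats::runif(n_contaminants, lm[1], lm[2]))
        rows[[length(rows) + 1L]] <- data.frame(
          mass = cm, enzyme = tr$enzyme, n_reduced = tr$n_reduced,
          alkylated = isTRUE(tr$alkylated), contaminant = TRUE,
          true_mass = NA_real_, stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(mass = numeric(0), enzyme = character(0),
                 n_reduced = integer(0), alkylated = logical(0),
                 contaminant = logical(0), true_mass = numeric(0))
    class(out) <- c("ms_dataset", class(out))
    out
  })
}

#' Evidence set from simulated (or imported) observations
#'
#' Converts an observation table into [ssbond_evidence()] mass items.
#'
#' @param observations data.frame with `mass`, `enzyme`, `n_reduced`,
#'   `alkylated` (and optionally `tol_ppm`, `annotation` of the form
#'   `"no_cam:<ordinal>"`).
#' @return An [ssbond_evidence()] object.
#' @export
evidence_from_observations <- function(observations) {
  items <- lapply(seq_len(nrow(observations)), function(i) {
    r <- observations[i, ]
    no_cam <- NULL
    if (!is.null(r$annotation) && !is.na(r$annotation) &&
        nzchar(r$annotation) && startsWith(r$annotation, "no_cam:"))
      no_cam <- as.integer(sub("no_cam:", "", r$annotation))
    ev_mass(r$mass, enzyme = r$enzyme, n_reduced = r$n_reduced,
            alkylated = isTRUE(r$alkylated),
            tol_ppm = if (!is.null(r$tol_ppm) && !is.na(r$tol_ppm))
              r$tol_ppm else NULL,
            no_cam = no_cam)
  })
  do.call(ssbond_evidence, items)
}

#' Simulate 15N relaxation and NOE data from a Lipari-Szabo model
#'
#' Per-residue R1/R2/NOE are computed from the Lipari-Szabo spectral density
#' at the given field (reduced-mapping forward relations, see
#' [forward_relaxation()]); intensity decays are built on the delay grids
#' with Gaussian noise of standard deviation `1/snr` relative to the
#' amplitude.
#'
#' @param s2 Per-residue order parameters (vector in \[0, 1\]).
#' @param tau_m Overall tumbling time (s), default 5 ns.
#' @param tau_e Internal correlation time (s), must be < `tau_m`.
#' @param field [field_params()].
#' @param r1_delays,r2_delays Delay grids in seconds (defaults: the standard
#'   10-1000 ms R1 and 10-210 ms R2 series).
#' @param snr Signal-to-noise ratio; `Inf` for noiseless data.
#' @param seed Integer seed.
#' @return List of class `dynamics_dataset`: `truth` (per-residue r1, r2,
#'   noe, j0, jn, jh, s2), `r1_series`/`r2_series` (long data.frames:
#'   residue, delay_s, intensity), `noe_pairs` (residue, vol_sat,
#'   vol_unsat), `field`.
#' @export
gen_dynamics_dataset <- function(s2, tau_m = 5e-9, tau_e = 50e-12,
                                 field = field_params(),
                                 r1_delays = c(10, 80, 150, 300, 500, 750,
                                               1000) / 1000,
                                 r2_delays = c(10, 30, 50, 90, 130, 170,
                                               210) / 1000,
                                 snr = 50, seed = 1L) {
  if (tau_e >= tau_m) stop("tau_e must be smaller than tau_m")
  n <- length(s2)
  with_seed(.substream(seed, 3L), {
    truth <- do.call(rbind, lapply(seq_len(n), function(i) {
      j <- function(w) spectral_density_ls(w, tau_m, s2[i], tau_e)
      obs <- forward_relaxation(j, field, approx = "reduced")
      data.frame(residue = i, s2 = s2[i], r1 = obs$r1, r2 = obs$r2,
                 noe = obs$noe, j0 = j(0), jn = j(abs(field$omega_n)),
                 jh = j(0.87 * abs(field$omega_h)))
    }))
    noise <- function(m) if (is.finite(snr)) stats::rnorm(m, 0, 1 / snr) else 0
    series <- function(rates, delays) {
      do.call(rbind, lapply(seq_len(n), function(i) {
        data.frame(residue = i, delay_s = delays,
                   intensity = exp(-rates[i] * delays) +
                     noise(length(delays)))
      }))
    }
    noe_pairs <- data.frame(
      residue = seq_len(n),
      vol_sat = truth$noe + noise(n),
      vol_unsat = 1 + noise(n))
    structure(list(truth = truth,
                   r1_series = series(truth$r1, r1_delays),
                   r2_series = series(truth$r2, r2_delays),
                   noe_pairs = noe_pairs, field = field),
              class = "dynamics_dataset")
  })
}

#' Simulate H/D-exchange peak-integral time series
#'
#' Integrals follow `exp(-k t)` plus Gaussian noise; time points where the
#' true signal has decayed below the detection limit are dropped, so fast
#' exchangers are emitted with fewer than 3 points and downstream fitting
#' classifies them as undetectable.
#'
#' @param k Per-residue exchange rate constants (h^-1), named or unnamed.
#' @param times Sampling times (h), default hourly for 24 h.
#' @param noise Gaussian noise standard deviation on the integrals.
#' @param lod Detection limit on the true signal.
#' @param seed Integer seed.
#' @return List of class `hdx_dataset`: `series` (long data.frame: residue,
#'   time_h, integral), `truth` (residue, k, half_life).
#' @export
gen_hdx_dataset <- function(k, times = 1:24, noise = 0.03, lod = 0.05,
                            seed = 1L) {
  if (any(k <= 0)) stop("exchange rate constants must be positive")
  ids <- if (is.null(names(k))) as.character(seq_along(k)) else names(k)
  with_seed(.substream(seed, 4L), {
    rows <- list()
    for (i in seq_along(k)) {
      sig <- exp(-k[i] * times)
      keep <- sig >= lod
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          residue = ids[i], time_h = times[keep],
          integral = sig[keep] + stats::rnorm(sum(keep), 0, noise),
          stringsAsFactors = FALSE)
      }
    }
    series <- if (length(rows)) do.call(rbind, rows) else
      data.frame(residue = character(0), time_h = numeric(0),
                 integral = numeric(0))
    structure(list(series = series,
                   truth = data.frame(residue = ids, k = unname(k),
                                      half_life = log(2) / unname(k))),
              class = "hdx_dataset")
  })
}

#' Simulate an MSA with a conserved cysteine scaffold and a hypervariable
#' region
#'
#' Rows share the reference cysteine scaffold (never mutated); columns in
#' the designated hypervariable region (between two chosen cysteines) carry
#' an elevated substitution rate and per-sequence indels realised as gap
#' characters, so the region length varies across rows.
#'
#' @param reference A [gen_protein()] result used as the consensus.
#' @param n_seqs Number of sequences (default 69, a typical pheromone-family
#'   isoform panel).
#' @param sub_prob Baseline per-column substitution probability.
#' @param hyper_sub_prob Substitution probability inside the hypervariable
#'   region.
#' @param hyper_gap Ordinal gap index defining the region (default 5:
#'   between Cys5 and Cys6, "finger 3").
#' @param region_lengths Integer vector the per-sequence region lengths are
#'   drawn from (region widened with gap columns to `max(region_lengths)`).
#' @param seed Integer seed.
#' @return List of class `synthetic_msa`: `msa` ([as_msa()] matrix), `truth`
#'   (per-column `scaffold`, `hyper` flags; `drawn_lengths`), `region_cols`.
#' @export
gen_msa <- function(reference, n_seqs = 69L, sub_prob = 0.05,
                    hyper_sub_prob = 0.5, hyper_gap = 5L,
                    region_lengths = 13:18, seed = 1L) {
  fw <- reference$framework
  if (nrow(fw) < hyper_gap + 1L) stop("reference lacks the cysteine pair")
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  c_lo <- fw$position[hyper_gap]; c_hi <- fw$position[hyper_gap + 1L]
  pre <- ref_chars[1:c_lo]
  post <- ref_chars[c_hi:length(ref_chars)]
  wmax <- max(region_lengths)
  aa_no_c <- setdiff(.aa20, "C")
  with_seed(.substream(seed, 5L), {
    drawn <- sample(region_lengths, n_seqs, replace = TRUE)
    # shared consensus for the hypervariable core, drawn once
    core_ref <- sample(aa_no_c, wmax, replace = TRUE)
    rows <- character(n_seqs)
    for (s in seq_len(n_seqs)) {
      mut <- function(chars, p) {
        hit <- stats::runif(length(chars)) < p & chars != "C"
        chars[hit] <- sample(aa_no_c, sum(hit), replace = TRUE)
        chars
      }
      a <- mut(pre, sub_prob)
      b <- mut(post, sub_prob)
      core <- mut(core_ref[seq_len(drawn[s])], hyper_sub_prob)
      core <- c(core, rep("-", wmax - drawn[s]))
      rows[s] <- paste(c(a, core, b), collapse = "")
    }
    msa <- as_msa(rows, ids = sprintf("seq%03d", seq_len(n_seqs)))
    region_cols <- (c_lo + 1L):(c_lo + wmax)
    scaffold_cols <- c(fw$position[fw$position <= c_lo],
                       fw$position[fw$position >= c_hi] - (c_hi - c_lo - 1L) +
                         wmax)
    truth <- data.frame(column = seq_len(ncol(msa)),
                        scaffold = seq_len(ncol(msa)) %in% scaffold_cols,
                        hyper = seq_len(ncol(msa)) %in% region_cols)
    structure(list(msa = msa, truth = truth, region_cols = region_cols,
                   drawn_lengths = drawn),
              class = "synthetic_msa")
  })
}

#' Simulate a multi-model coordinate ensemble
#'
#' Builds a smooth backbone template (N, CA, C, O per residue; SG atoms for
#' cysteines placed so each true disulfide spans 2.02 Angstrom) and adds
#' chain-correlated Gaussian backbone perturbations whose amplitude varies
#' by region, giving region-dependent dispersion with a known ordering.
#'
#' @param n_models Number of models (default 20, a typical NMR ensemble).
#' @param protein A [gen_protein()] result supplying length, cysteines and
#'   the disulfide pattern (SG atoms); `NULL` for a plain backbone of
#'   `n_residues`.
#' @param n_residues Residue count when `protein` is `NULL`.
#' @param base_amplitude Baseline displacement amplitude (Angstrom RMS).
#' @param regions Optional list of `list(resnos =, amplitude =)` overriding
#'   the baseline inside given residue ranges.
#' @param sidechain_jitter Extra independent Gaussian displacement (Angstrom
#'   RMS) on side-chain (SG) atoms, emulating the additional side-chain
#'   mobility that makes heavy-atom dispersion exceed backbone dispersion.
#' @param seed Integer seed.
#' @return A [model_ensemble()] with attribute `amplitudes` (per-residue
#'   ground-truth displacement amplitude).
#' @export
gen_ensemble <- function(n_models = 20L, protein = NULL, n_residues = 60L,
                         base_amplitude = 0.3, regions = NULL,
                         sidechain_jitter = 0.3, seed = 1L) {
  nr <- if (!is.null(protein)) nchar(protein$sequence) else n_residues
  # gently curved template: CA trace on a loose helix, ~3.8 A CA-CA
  t <- seq_len(nr)
  ca <- cbind(8 * cos(0.42 * t), 8 * sin(0.42 * t), 1.9 * t)
  atoms <- list(); coords <- list()
  for (i in t) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      resno = i, resid = "ALA", elety = c("N", "CA", "C", "O"),
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- rbind(
      ca[i, ] + c(-1.2, 0.5, -0.4), ca[i, ],
      ca[i, ] + c(1.2, 0.5, 0.4), ca[i, ] + c(1.7, 1.6, 0.5))
  }
  atoms <- do.call(rbind, atoms)
  template <- do.call(rbind, coords)
  if (!is.null(protein)) {
    pos <- protein$framework$position
    atoms$resid[atoms$resno %in% pos] <- "CYS"
    pat <- canonical_pattern(protein$pattern)
    for (b in seq_len(nrow(pat))) {
      i <- pos[pat[b, 1]]; j <- pos[pat[b, 2]]
      mid <- (ca[i, ] + ca[j, ]) / 2
      u <- ca[j, ] - ca[i, ]; u <- u / sqrt(sum(u^2))
      for (rp in list(list(r = i, x = mid - 1.01 * u),
                      list(r = j, x = mid + 1.01 * u))) {
        atoms <- rbind(atoms, data.frame(resno = rp$r, resid = "CYS",
                                         elety = "SG",
                                         stringsAsFactors = FALSE))
        template <- rbind(template, rp$x)
      }
    }
    ord <- order(atoms$resno, match(atoms$elety, c("N", "CA", "C", "O", "SG")))
    atoms <- atoms[ord, ]; template <- template[ord, , drop = FALSE]
  }
  amp <- rep(base_amplitude, nr)
  if (!is.null(regions))
    for (rg in regions) amp[rg$resnos] <- rg$amplitude
  with_seed(.substream(seed, 6L), {
    arr <- array(NA_real_, c(nrow(atoms), 3, n_models))
    for (m in seq_len(n_models)) {
      raw <- matrix(stats::rnorm(nr * 3), nr, 3)
      # smooth along the chain for spatially correlated displacements
      sm <- apply(raw, 2, function(v)
        stats::filter(v, rep(1 / 3, 3), sides = 2) |>
          (\(x) { x[is.na(x)] <- v[is.na(x)]; x })())
      sm <- sm / sqrt(mean(sm^2))
      disp <- sm * amp
      arr[, , m] <- template + disp[atoms$resno, ]
      sg <- which(atoms$elety == "SG")
      if (length(sg) && sidechain_jitter > 0)
        arr[sg, , m] <- arr[sg, , m] +
          matrix(stats::rnorm(length(sg) * 3, 0, sidechain_jitter),
                 length(sg), 3)
    }
    ens <- model_ensemble(atoms, arr)
    attr(ens, "amplitudes") <- amp
    ens
  })
}
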