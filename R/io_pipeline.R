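# File IO and pipeline orchestration: FASTA/CSV/PDB readers with
# validation, TSV/JSON reports, and one run() entry point per analysis
# stage (mirrored by the command-line wrapper in inst/cli).

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  stats::setNames(toupper(unlist(seqs)), names(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)),
                      names = names(sequences), file.out = path)
  invisible(path)
}

#' Read an aligned FASTA file as an MSA
#'
#' @param path FASTA alignment (equal-length rows, `-` gaps).
#' @return An [as_msa()] matrix.
#' @export
read_msa_fasta <- function(path) {
  seqs <- read_fasta(path)
  as_msa(unname(seqs), ids = names(seqs))
}

#' Read a partial-reduction observation table
#'
#' CSV with header and columns `mass`, `enzyme`, `n_reduced`, `alkylated`
#' (logical or 0/1); optional `tol_ppm`, `annotation`.
#'
#' @param path CSV file.
#' @return Validated data.frame.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mass", "enzyme", "n_reduced", "alkylated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("observation file lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(!is.finite(df$mass) | df$mass <= 0)) {
    bad <- which(!is.finite(df$mass) | df$mass <= 0)[1]
    stop(sprintf("row %d: non-positive mass", bad))
  }
  df$alkylated <- as.logical(df$alkylated)
  df
}

#' Read a relaxation (or HDX) intensity series table
#'
#' CSV with header and columns `residue`, plus either `delay_s`/`intensity`
#' (relaxation) or `time_h`/`integral` (HDX).
#'
#' @param path CSV file.
#' @param kind `"relaxation"` or `"hdx"`.
#' @return Validated data.frame.
#' @export
read_series_csv <- function(path, kind = c("relaxation", "hdx")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (kind == "relaxation") c("residue", "delay_s", "intensity")
  else c("residue", "time_h", "integral")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s file lacks column(s): %s", kind,
                 paste(miss, collapse = ", ")))
  df
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.report <- function(stage, params, summary) {
  list(schema_version = "1.0", stage = stage, params = params,
       summary = summary)
}

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the disulfide-inference stage on files
#'
#' @param fasta Protein FASTA (first sequence used).
#' @param observations Observation CSV (see [read_observations_csv()]).
#' @param out_dir Output directory (created if needed).
#' @param tol_ppm,use_adjacency_rule,strict,max_missed Passed to
#'   [infer_patterns()].
#' @return The [infer_patterns()] result, invisibly; writes
#'   `ssbond_candidates.tsv` and `ssbond_report.json`.
#' @export
run_infer_ssbonds <- function(fasta, observations, out_dir,
                              tol_ppm = 10, use_adjacency_rule = TRUE,
                              strict = FALSE, max_missed = 0L) {
  seqs <- read_fasta(fasta)
  obs <- read_observations_csv(observations)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- evidence_from_observations(obs)
  res <- infer_patterns(seqs[[1]], ev, tol_ppm = tol_ppm,
                        use_adjacency_rule = use_adjacency_rule,
                        strict = strict, max_missed = max_missed)
  write_tsv(res$table, file.path(out_dir, "ssbond_candidates.tsv"))
  write_report_json(.report(
    "infer-ssbonds",
    list(tol_ppm = tol_ppm, adjacency_rule = use_adjacency_rule,
         strict = strict, max_missed = max_missed,
         n_observations = nrow(obs)),
    list(n_patterns_evaluated = res$n_patterns_evaluated,
         n_candidates = length(res$candidates),
         candidates = vapply(res$candidates, pattern_key, character(1)))),
    file.path(out_dir, "ssbond_report.json"))
  invisible(res)
}

#' Run the NMR dynamics stage on files
#'
#' @param r1_csv,r2_csv Relaxation series CSVs (residue, delay_s, intensity).
#' @param noe_csv NOE pair CSV (residue, vol_sat, vol_unsat).
#' @param hdx_csv Optional HDX CSV (residue, time_h, integral).
#' @param out_dir Output directory.
#' @param field [field_params()].
#' @param hdx_threshold_h Slow-exchanger half-life threshold (h).
#' @return data.frame of per-residue results, invisibly; writes
#'   `dynamics.tsv` and `dynamics_report.json`.
#' @export
run_dynamics <- function(r1_csv, r2_csv, noe_csv, out_dir, hdx_csv = NULL,
                         field = field_params(), hdx_threshold_h = 2.5) {
  r1d <- read_series_csv(r1_csv, "relaxation")
  r2d <- read_series_csv(r2_csv, "relaxation")
  noe <- utils::read.csv(noe_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "vol_sat", "vol_unsat") %in% names(noe)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit_all <- function(df) {
    res <- lapply(split(df, df$residue), function(d)
      fit_rate(d$delay_s, d$intensity))
    data.frame(residue = names(res),
               rate = vapply(res, function(f) f$rate, numeric(1)),
               sd = vapply(res, function(f) f$sd, numeric(1)),
               ok = vapply(res, function(f) f$ok, logical(1)),
               stringsAsFactors = FALSE)
  }
  r1 <- fit_all(r1d); r2 <- fit_all(r2d)
  noe$noe <- het_noe(noe$vol_sat, noe$vol_unsat)
  tab <- merge(merge(stats::setNames(r1[, c("residue", "rate", "ok")],
                                     c("residue", "r1", "r1_ok")),
                     stats::setNames(r2[, c("residue", "rate", "ok")],
                                     c("residue", "r2", "r2_ok"))),
               noe[, c("residue", "noe")])
  usable <- tab$r1_ok & tab$r2_ok & tab$r1 > 0 & tab$r2 > 0
  jmap <- data.frame(j0 = NA_real_, jn = NA_real_, jh = NA_real_,
                     flagged = NA)[rep(1, nrow(tab)), ]
  if (any(usable))
    jmap[usable, ] <- map_spectral_density(tab$r1[usable], tab$r2[usable],
                                           tab$noe[usable], field)
  tab <- cbind(tab, jmap)
  tab$rex <- NA_real_
  if (sum(usable) >= 3)
    tab$rex[usable] <- estimate_rex(tab$j0[usable], field)
  slow <- character(0)
  if (!is.null(hdx_csv)) {
    hd <- read_series_csv(hdx_csv, "hdx")
    hl <- vapply(split(hd, hd$residue), function(d)
      fit_hdx_halflife(d$time_h, d$integral)$half_life, numeric(1))
    tab <- merge(tab, data.frame(residue = names(hl),
                                 hdx_half_life_h = unname(hl),
                                 stringsAsFactors = FALSE), all.x = TRUE)
    slow <- classify_slow_exchangers(hl, hdx_threshold_h)
  }
  rownames(tab) <- NULL
  write_tsv(tab, file.path(out_dir, "dynamics.tsv"))
  write_report_json(.report(
    "dynamics",
    list(freq_h_mhz = field$omega_h / (2 * pi * 1e6),
         hdx_threshold_h = hdx_threshold_h),
    list(n_residues = nrow(tab), n_fit_failures = sum(!usable),
         slow_exchangers = slow)),
    file.path(out_dir, "dynamics_report.json"))
  invisible(tab)
}

#' Run the sequence-variability stage on files
#'
#' @param msa_fasta Aligned FASTA.
#' @param out_dir Output directory.
#' @param selection_tsv Optional TSV (site, class) of selection annotations.
#' @param reference_row Row of the MSA used as reference coordinates.
#' @param hyper_gap Cysteine gap index for the region summary (default 5).
#' @param his Histidine charge convention for net charge.
#' @return List with `profile`, `spacing`, `region`, invisibly; writes
#'   `entropy.tsv` and `variability_report.json`.
#' @export
run_variability <- function(msa_fasta, out_dir, selection_tsv = NULL,
                            reference_row = 1L, hyper_gap = 5L, his = 1) {
  msa <- read_msa_fasta(msa_fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- entropy_profile(msa)
  ungapped <- gsub("-", "", apply(msa, 1, paste, collapse = ""))
  spacing <- tryCatch(spacing_stats(ungapped, hyper_gap),
                      error = function(e) NULL)
  ref <- ungapped[reference_row]
  charge <- net_charge(ref, his = his)
  sel <- NULL
  if (!is.null(selection_tsv)) {
    sd <- utils::read.delim(selection_tsv, stringsAsFactors = FALSE)
    sel <- sd$class[order(sd$site)]
  }
  region <- NULL
  fw <- cys_framework(ref)
  if (nrow(fw) >= hyper_gap + 1L) {
    # region in reference coordinates: strictly between the cysteine pair
    rc <- (fw$position[hyper_gap] + 1L):(fw$position[hyper_gap + 1L] - 1L)
    # map to alignment columns through the reference row
    notgap <- which(msa[reference_row, ] != "-")
    prof_ref <- prof[notgap, ]
    region <- region_selection_summary(prof_ref, sel, rc)
  }
  write_tsv(prof, file.path(out_dir, "entropy.tsv"))
  write_report_json(.report(
    "variability",
    list(hyper_gap = hyper_gap, his_charge = his,
         n_sequences = nrow(msa)),
    list(mean_entropy = mean(prof$entropy, na.rm = TRUE),
         spacing = spacing[c("mean", "sd", "conservation")],
         reference_net_charge = charge,
         region = region[c("n_sites", "n_nonconserved",
                           "n_positive_nonconserved")])),
    file.path(out_dir, "variability_report.json"))
  invisible(list(profile = prof, spacing = spacing, region = region,
                 net_charge = charge))
}

#' Run the ensemble-statistics stage on files
#'
#' @param pdb Multi-model PDB file.
#' @param out_dir Output directory.
#' @param selection Fit/statistics selection (see [select_atoms()]).
#' @return List with `rmsf`, `rmsd`, invisibly; writes `rmsf.tsv` and
#'   `ensemble_report.json`.
#' @export
run_ensemble <- function(pdb, out_dir, selection = "backbone") {
  ens <- read_ensemble_pdb(pdb)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sup <- superpose_ensemble(ens, selection)
  rmsf <- per_residue_rmsf(sup)
  rmsd <- avg_rmsd_to_mean(sup)
  write_tsv(rmsf, file.path(out_dir, "rmsf.tsv"))
  write_report_json(.report(
    "ensemble",
    list(selection = if (is.character(selection)) selection else "custom",
         n_models = ens$n_models),
    list(rmsd_to_mean = rmsd$mean, rmsd_sd = rmsd$sd,
         converged = sup$converged)),
    file.path(out_dir, "ensemble_report.json"))
  invisible(list(rmsf = rmsf, rmsd = rmsd, superposition = sup))
}

#' Run the simulation stage: write a complete synthetic input bundle
#'
#' @param out_dir Output directory.
#' @param seed Master seed fanned out to every generator.
#' @param length,n_cys Protein spec.
#' @param noise_ppm,dropout,n_contaminants MS spec.
#' @return List with the generated objects, invisibly; writes
#'   `protein.fasta`, `observations.csv`, `r1.csv`, `r2.csv`, `noe.csv`,
#'   `hdx.csv`, `msa.fasta`, `ensemble.pdb`, `ground_truth.json`.
#' @export
run_simulate <- function(out_dir, seed = 1L, length = 60L, n_cys = 8L,
                         noise_ppm = 5, dropout = 0.2, n_contaminants = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- gen_protein(length = length, n_cys = n_cys, seed = seed)
  obs <- gen_ms_dataset(prot, noise_ppm = noise_ppm, dropout = dropout,
                        n_contaminants = n_contaminants, seed = seed)
  s2 <- rep(0.85, 54); s2[35:45] <- 0.4
  dyn <- gen_dynamics_dataset(s2, seed = seed)
  k <- c(0.05, 0.1, 0.2, 0.018, 5, 50, 0.4, 0.25)
  names(k) <- sprintf("res%02d", seq_along(k))
  hdx <- gen_hdx_dataset(k, seed = seed)
  msa <- gen_msa(prot, seed = seed)
  ens <- gen_ensemble(protein = prot, seed = seed,
                      regions = list(list(resnos = 35:45, amplitude = 0.9)))
  write_fasta(stats::setNames(prot$sequence, "synthetic_protein"),
              file.path(out_dir, "protein.fasta"))
  utils::write.csv(as.data.frame(obs)[, c("mass", "enzyme", "n_reduced",
                                          "alkylated")],
                   file.path(out_dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(dyn$r1_series, file.path(out_dir, "r1.csv"),
                   row.names = FALSE)
  utils::write.csv(dyn$r2_series, file.path(out_dir, "r2.csv"),
                   row.names = FALSE)
  utils::write.csv(dyn$noe_pairs, file.path(out_dir, "noe.csv"),
                   row.names = FALSE)
  utils::write.csv(hdx$series, file.path(out_dir, "hdx.csv"),
                   row.names = FALSE)
  rows <- apply(msa$msa, 1, paste, collapse = "")
  write_fasta(rows, file.path(out_dir, "msa.fasta"))
  write_ensemble_pdb(ens, file.path(out_dir, "ensemble.pdb"))
  write_report_json(list(
    seed = seed, pattern = pattern_key(prot$pattern),
    cys_positions = prot$framework$position,
    hdx_half_lives = stats::setNames(as.list(log(2) / k), names(k)),
    msa_region_cols = msa$region_cols),
    file.path(out_dir, "ground_truth.json"))
  invisible(list(protein = prot, observations = obs, dynamics = dyn,
                 hdx = hdx, msa = msa, ensemble = ens))
}

#' Pipeline entry point
#'
#' Dispatches to the per-stage `run_*` functions; the thin command-line
#' wrapper in `inst/cli/tfptools.R` calls this.
#'
#' @param subcommand One of `simulate`, `infer-ssbonds`, `dynamics`,
#'   `variability`, `ensemble`.
#' @param config Named list of arguments for the stage function.
#' @return The stage result, invisibly.
#' @export
run_pipeline <- function(subcommand, config = list()) {
  fn <- switch(subcommand,
               "simulate" = run_simulate,
               "infer-ssbonds" = run_infer_ssbonds,
               "dynamics" = run_dynamics,
               "variability" = run_variability,
               "ensemble" = run_ensemble,
               stop(sprintf(
                 "unknown subcommand '%s' (use simulate, infer-ssbonds, dynamics, variability, ensemble)",
                 subcommand)))
  do.call(fn, config)
}
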