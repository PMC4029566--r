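---
title: "Methods: disulfide inference, backbone dynamics and variability analysis for three-finger proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disulfide inference, backbone dynamics and variability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfptools)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, the design choices made where several defensible
options existed, and what the synthetic-data generators do and do not
emulate.

## 1. Mass arithmetic and species prediction

A peptide's mass is the sum of its residue masses plus one water; the
package carries built-in monoisotopic and average tables for the 20
standard residues (overridable via TSV for non-standard isotope labelling).
Two modifications are modelled, because they are the two the
partial-reduction experiment produces:

* **disulfide hydrogen loss** — every bonded cysteine is lighter by
  1.0078 Da, the proton displaced when the thiol enters an S–S bond. The
  same per-cysteine value is used on both mass scales: intact-protein
  matching is done on average masses and peptide matching on monoisotopic
  masses, and the sub-millidalton difference between the scales' hydrogen
  masses is far below either measurement's accuracy.
* **CAM alkylation** — iodoacetamide adds a carboxyamidomethyl group
  (+57.02146 Da mono / +57.0513 avg) to each *free* thiol, which is what
  makes reduction observable: the cysteines of a reduced bond carry CAM,
  bonded cysteines cannot.

Proteolysis rules: trypsin cleaves after K/R, chymotrypsin after F/Y/W/L
(the common "low-specificity sites excluded" convention), both suppressed
before proline; AspN cleaves before D. All three are table-driven and a
digest at `k` missed cleavages returns every union of up to `k + 1`
adjacent fragments. A *linked species* is a set of fragments made
connected by intact disulfides; its mass is the sum of member peptide
masses (each with its own water) plus the modification deltas. Species
prediction at missed-cleavage levels above 0 merges bond-closed components
through adjacent fragments, counting one uncut site per merge; the default
pipeline runs at 0 missed cleavages, where the construction is exact.

## 2. Candidate-elimination inference

The search space is all perfect matchings of the cysteine ordinals —
(2k−1)!! patterns, enumerated exactly. Evidence items are:

* **mass observations** under a treatment (enzyme × number of bonds
  reduced × alkylation flag). Which bonds were reduced is latent, so the
  predictor tries every subset of the stated cardinality — the experiment
  separates species by *how many* disulfides were cleaved, never which.
* **bond assertions** (a peptide pair directly observed disulfide-linked),
* **negative alkylation annotations**: a species containing a stated set
  of cysteines was observed with one of them unalkylated. A pattern is
  consistent with such an item if *some* latent reduced-bond subset
  predicts a matching species without CAM at that ordinal. This
  existential reading is deliberately weak: fragmentation spectra localise
  the absence of a modification but do not reveal which bond was reduced,
  so stronger readings would over-eliminate.

**Elimination semantics.** By default an observed mass counts against a
pattern only if that pattern cannot explain it *and* at least one other
pattern can. A peak unexplained by every pattern is treated as a
contaminant and eliminates nothing. `strict = TRUE` makes any unexplained
peak fatal; it is appropriate only for contaminant-free simulated data.
This tolerance matters: at 5 ppm mass noise roughly 5% of peaks fall
outside a 2-standard-deviation matching window, and strict semantics would
eliminate the true pattern from most realistic runs.

**Adjacency rule.** Disulfides between sequence-adjacent cysteines are
extremely rare (the strained eight-membered ring), so patterns bonding a
cysteine pair at sequence distance ≤ 1 can be excluded up front. For an
8-cysteine framework with one CC doublet this removes (2k−3)!! = 15 of the
105 matchings. The rule is a flag, never silently applied.

**Tolerance.** The default matching tolerance is 10 ppm — ordinary
high-resolution instrument accuracy; it is a parameter everywhere.

When the evidence cannot separate two patterns — typically when the
cysteines of a doublet or an unseparated triplet never appear in distinct
species — the full surviving set is reported. Ranking by explained-peak
count is provided for diagnosis, but the candidate set, not the top
pattern, is the result.

## 3. Relaxation, spectral density mapping, and H/D exchange

R₁ and R₂ series are two-parameter mono-exponential decays fitted by
Levenberg–Marquardt least squares, started from a log-linear regression.
The rate's standard deviation comes from the curvature (inverse-Hessian)
matrix and the 95% interval uses the t quantile at n − 2 degrees of
freedom. Constant, non-decaying or non-finite series are flagged as fit
failures and surfaced, never dropped silently; fewer than three distinct
delays is a failure by construction.

Reduced spectral density mapping uses the standard constants for an amide
¹⁵N: N–H bond length 1.02 Å, CSA −160 ppm, and the single effective
high-frequency point 0.87ωH. Field defaults are 18.8 T with ¹H at
800.13 MHz (configurable; deriving ωH from the field and the gyromagnetic
ratio instead gives 800.4 MHz and changes mapped J values by well under a
percent). The forward model used by the simulator evaluates the
high-frequency spectral density at 0.87ωH with coefficients 7 (R₁), 13
(R₂) and 5 (σ_NH) — the same approximation the inverse mapping assumes —
so the noiseless round trip is exact to machine precision and any mapping
defect is attributable to the mapping itself, not to approximation
mismatch. A `full` forward variant evaluating J at ωH ± ωN separately is
available for studying the approximation error; for a 5 ns Lorentzian at
18.8 T it is of order 5% at J(0.87ωH) and far smaller at J(0) and J(ωN).

The per-residue exchange contribution R_ex is reported as the excess of
J(0) over a 10%-trimmed-mean baseline, converted back to R₂ units through
the J(0) coefficient. This is a labelled heuristic, not a model fit: it
assumes most residues are exchange-free and under-corrects when more than
the trim fraction of residues is genuinely flexible or exchanging. Use it
to rank residues, not to quantify exchange.

H/D exchange decays are fitted with the same machinery on hourly
integrals; a residue needs at least three observed points, otherwise it is
classified as exchanging too fast to measure (undetectable), which is a
result, not a missing value. Slow exchangers are those with fitted
t½ strictly greater than 2.5 h — the boundary value itself is excluded —
and these are screened for hydrogen-bond partners among backbone carbonyl
oxygens within 2.5 Å of the amide proton (the nitrogen stands in, flagged,
when models carry no protons).

## 4. Sequence variability

Column entropy is Shannon's −Σp·log₂p over residue frequencies. Gaps are
excluded from the frequencies and reported as a separate per-column gap
fraction, because a deletion and a substitution are different evolutionary
events; counting gaps as a 21st symbol is available by option. All-gap
columns have no entropy (NA, flagged). "Non-conserved" defaults to any
entropy above 0 — with ~70-sequence panels even a single substitution is
worth counting — and the threshold is a parameter.

Cysteine spacing profiles count residues strictly between consecutive
cysteines; per-gap statistics across a family report mean, SD and the
fraction of sequences sharing the modal value. The ProSite-style scanner
supports literals, `[..]` classes and `x(min,max)` wildcards, matches
lazily (shortest wildcard realisation first, leftmost match, scanning
resumes after each match), and reports realised wildcard lengths, which
for the TFP framework query are exactly the inter-cysteine spacings. Net
charge counts Lys/Arg − Asp/Glu with histidine's contribution configurable
(default +1, consistent with grouping His among the basic residues;
classifications driven by that grouping should be checked at His = 0 too).

## 5. Ensemble statistics

Superposition fits every model onto the mean structure over a selected
atom set (default backbone N, CA, C, O; N, CA, C and heavy-atom
selections available), re-estimates the mean, and iterates until the mean
shifts less than 1e−6 Å RMS — with the mean initialised on model 1 the
procedure is deterministic. Rotations are proper Kabsch rotations with the
reflection guard, so chirality is preserved. RMSF is per residue over
models and selected atoms; RMSD-to-mean is per model with ensemble mean ±
SD. Both are computed after the fit, so they are invariant to arbitrary
rigid pre-transformations of the input models (verified to 1e−6 Å).
Disulfide geometry flags Sγ–Sγ distances outside 1.8–2.5 Å.

## 6. What the generators emulate — and what they do not

All generators are deterministic under an integer seed (one master seed
fans out to fixed per-generator substreams; the caller's RNG state is
restored afterwards) and always emit ground truth next to the data.

* `gen_protein` draws a 60-residue sequence with 8 cysteines, optionally
  one adjacent CC doublet at ordinals 6–7 (the TFP `C-C-x(4)-C` motif),
  minimum inter-cysteine gap of 3 otherwise, and seeds every
  inter-cysteine segment with a chymotrypsin site and an AspN site. The
  seeding reflects a real design constraint of partial-reduction mapping —
  proteases are chosen *because* they separate the cysteines; without
  this, fragments carrying three or more cysteines make whole blocks of
  patterns mass-equivalent and no method could distinguish them.
* `gen_ms_dataset` applies ppm-scale Gaussian noise (default 5 ppm), peak
  dropout (default 20%), and optional contaminants uniform in log-mass. It
  does not model isotope envelopes, charge states, retention times, or
  disulfide scrambling during reduction.
* `gen_dynamics_dataset` builds R₁/R₂/NOE from a Lipari–Szabo spectral
  density (defaults: τm = 5 ns, appropriate for a ~7 kDa monomer at 20 °C;
  τe = 50 ps; rigid S² ≈ 0.85) on the measurement delay grids
  (R₁ 10–1000 ms, R₂ 10–210 ms, seven points each) with Gaussian noise at
  1/SNR. It does not simulate spectra, peak overlap, or anisotropic
  tumbling.
* `gen_hdx_dataset` emits hourly integrals over 24 h; points whose true
  signal is below the detection limit are dropped, so fast exchangers
  arrive with fewer than three points and exercise the undetectable path.
* `gen_msa` mutates a shared consensus: scaffold cysteine columns are
  never touched, the region between Cys5 and Cys6 carries an elevated
  substitution rate and per-sequence lengths drawn from 13–18 residues
  (realised as gap columns; alignment itself is out of scope), defaults
  sized to a ~69-sequence isoform panel. There is no phylogenetic
  structure: rows are independent draws, so entropy estimates are slightly
  higher than a tree-correlated family of the same divergence would give.
* `gen_ensemble` perturbs a smooth backbone template with
  chain-smoothed Gaussian displacements, region-scalable amplitude
  (default 0.3 Å baseline), independent side-chain jitter on Sγ atoms
  (which is why heavy-atom dispersion exceeds backbone dispersion, as in
  real ensembles), and Sγ pairs placed 2.02 Å apart for true bonds. The
  template is not a folded protein; tests on it validate the estimators,
  not protein geometry.

Consequently, green tests demonstrate that the estimators recover known
ground truth under the stated noise models — they do not certify
performance on real spectra with correlated noise, overlapping peaks, or
alignment error.

## 7. Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen to give
stable statistics in a few minutes: 100 simulated partial-reduction
experiments for pattern recovery, 2 × 250 replicates for
confidence-interval coverage (binomial error band at z = 2.807 around the
nominal 95%), 1000 random peptides against the brute-force mass oracle,
300 random sequences against the interval-DP motif oracle, 20-model
ensembles. Ties in mass matching are retained and flagged ambiguous rather
than broken; candidate patterns are reported in canonical sorted form;
all file outputs are deterministic given inputs and seed (no timestamps).

## 8. Known limitations

* Inference treats digestion as exact at the configured missed-cleavage
  level; semi-specific cleavage and in-source fragmentation are not
  modelled.
* The two-candidate ambiguity arising from an unseparated cysteine
  triplet/doublet is fundamental to mass-only evidence; the package
  reports it rather than resolving it, and structural restraints (e.g.
  comparative structure calculations under both patterns) are the
  documented route to a unique answer.
* MS/MS fragment-ion scoring, model-free (S², τe, τm) optimisation,
  diffusion-tensor anisotropy, alignment computation and selection-model
  fitting are out of scope; selection classes are consumed as annotations.
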