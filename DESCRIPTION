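Package: tfptools
Title: Disulfide Connectivity, Backbone Dynamics and Sequence Variability of Three-Finger Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for small disulfide-rich proteins of the three-finger
    (TFP) fold. Infers disulfide bonding patterns from partial-reduction /
    alkylation mass-spectrometry experiments (in-silico proteolysis, linked-species
    mass prediction, ppm matching, candidate-pattern elimination over all perfect
    matchings); fits 15N R1/R2 relaxation and hydrogen-deuterium exchange decays
    and maps reduced spectral densities J(0), J(wN), J(0.87wH); profiles alignment
    variability (Shannon entropy), cysteine-framework spacing and ProSite-style
    motifs; computes structural-ensemble statistics (iterative-mean Kabsch
    superposition, per-residue RMSF, RMSD-to-mean, disulfide geometry, H-bond
    candidate screening). Includes seedable synthetic-data generators so every
    stage is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    seqinr,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
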