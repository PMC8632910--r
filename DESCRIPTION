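Package: ommatidyn
Title: Quantification of Ommatidial Rotation Dynamics and Epithelial Tissue Fluidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for live-imaging studies of ommatidial
    rotation in the Drosophila pupal eye. Builds per-frame cell geometry and
    adjacency graphs from tracked label-image movies; quantifies cluster
    rotation and apical constriction kinetics with three-parameter logistic
    fits, pulse segmentation and cross-correlation; scores interommatidial
    cell divisions, delaminations and neighbor exchanges, and cell motility
    displacement fields; computes cell shape-index (jamming) statistics; and
    fits FRAP recovery and laser-ablation recoil traces. A synthetic tissue
    generator with genotype presets (wild type, low- and high-fluidity)
    produces tracked movies, event ledgers and kinetic traces with known
    ground truth so the full pipeline runs without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
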