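Package: nprrquant
Title: Quantification of Neuropeptide Release Reporter Imaging and
    Immunogold Stereology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify stimulation-evoked neuropeptide release from
    fluorescence imaging of genetically encoded neuropeptide release
    reporters (NPRRs) at the Drosophila larval neuromuscular junction, and
    to estimate immunogold labelling densities from electron-microscopy
    annotations by stereological point counting. Provides delta-F/F
    computation with pre-stimulation baselines and per-trial baseline
    correction, per-trial peak/latency/integral metrics including the
    inter-stimulation undershoot, tri-phasic response segmentation,
    frequency-response normalisation, bouton versus inter-bouton contrast
    ratios, compartment assignment of gold particles (dense-core-vesicle
    discs, membrane band, cytoplasm), grid-intersection area estimation,
    labelling-density reports with background estimation, the
    nonparametric and one-sample tests used for group comparison, and a
    synthetic-data generator (pool-depletion trace model, compartmental
    Poisson gold placement) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
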