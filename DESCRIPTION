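Package: ezloc
Title: Noninvasive Epileptogenic-Zone Localization from Ictal SPECT and EEG
Version: 0.1.0
Authors@R:
    person("EZ", "Localization Contributors", email = "ezloc@example.org",
           role = c("aut", "cre"))
Description: Tools for presurgical localization of the epileptogenic zone in
    drug-resistant non-lesional epilepsy from noninvasive functional imaging.
    Implements SISCOM (subtraction of ictal and interictal SPECT co-registered
    to MRI): mutual-information rigid registration, global-count
    normalization, subtraction, Gaussian smoothing, z-scoring and
    connected-component cluster extraction; EEG source imaging on a cortical
    source space with an analytic three-shell spherical forward model (and an
    optional boundary-element solver) inverted by a multiple-sparse-priors
    scheme (restricted maximum likelihood over covariance components with
    automatic relevance determination); injection of SISCOM hyperperfusion
    clusters as additional spatial priors into the inverse solution; and a
    voxelwise coincidence analysis (sensitivity/specificity against a
    resection mask) with optional atlas labeling. A synthetic-data module
    generates phantom MRI/SPECT pairs, cortical source spaces, leadfields and
    ictal EEG with known ground truth so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
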