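Package: nkgate
Title: NKp80-Based Identification of CD56-Negative NK Cells in Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated hierarchical gating for the identification of
    CD56-negative natural killer (NK) cells in multi-parameter flow
    cytometry data, built around an NKp80-based strategy and its classical
    CD16-based and alternative (CD7, CD300a, 2B4) counterparts. Includes a
    synthetic PBMC cohort generator with ground-truth population labels,
    disease-condition presets (healthy, untreated HIV, HIV under cART,
    multiple myeloma), perturbation models for cryopreservation and
    stimulation-induced CD16 shedding, mixture-model threshold estimation
    with a quantile fallback, per-donor subset statistics (frequencies,
    Eomes purity, CD123 contamination, median fluorescence intensities,
    functional readouts), paired and unpaired nonparametric comparisons,
    figure-analog reports, and FCS 3.1 reading and writing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
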