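Package: mzbin
Title: Mass-Bin Fingerprinting and Differential Profiling of Full-Scan LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reads full-scan LC-MS runs (mzML, mzXML, ANDI-MS netCDF), computes
    total-ion, base-peak and extracted-ion chromatograms and time-averaged mass
    spectra, converts the mass dimension into fixed-width intensity bins
    ("mass-bin fingerprints"), and runs a two-group differential-profiling
    chain over multi-sample bin matrices: interquartile-range filtering, sum
    normalization, log2 transformation, autoscaling, principal component
    analysis with loadings, volcano analysis (Welch t-test plus fold change),
    and hierarchical clustering on Pearson dissimilarities with Ward linkage.
    Includes a synthetic LC-MS study generator with known ground truth and a
    command-line interface; all results export as CSV and PNG.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mzR,
    ncdf4,
    zip,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
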