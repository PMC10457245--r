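Package: camap
Title: Calcium-Carbon Association Mapping from X-Ray Spectromicroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing and statistical analysis of X-ray absorption
    near-edge structure (XANES) spectra and scanning transmission X-ray
    microscopy (STXM) image stacks for studying calcium-organic carbon
    association in soils. Provides edge-step normalization and energy
    calibration of XANES spectra, optical-density analysis of STXM stacks
    with Boolean pixel co-localization classes, non-negative linear
    combination fitting with combinatorial standard search, target-transform
    factor analysis with SPOIL screening of candidate standards, per-pixel
    species mapping of multi-energy micro-X-ray-fluorescence maps, and
    cation-exchange bulk soil statistics. A synthetic-data generator
    produces endmember spectra, particle-scene stacks, and bulk tables with
    known ground truth so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pracma,
    png
Config/testthat/edition: 3
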