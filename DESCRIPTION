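Package: fluxproc
Title: Post-Processing Pipeline for Eddy-Covariance Flux Tower Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Standardized post-processing of half-hourly (or hourly)
    eddy-covariance tower data in FLUXNET2015 conventions: automated
    quality control with median-absolute-deviation despiking, potential
    top-of-atmosphere radiation, marginal distribution sampling (MDS)
    gap-filling, debiased linear downscaling of a coarse reference
    meteorological series, friction-velocity (USTAR) threshold
    estimation by the moving-point and change-point methods with
    bootstrap uncertainty, 40-member NEE ensembles with percentile,
    MEAN, USTAR50 and model-efficiency REF products, energy-balance
    closure corrected H and LE, random and joint uncertainties,
    nighttime and daytime partitioning of NEE into GPP and RECO, and
    daily-to-yearly aggregation.  Includes a synthetic-site generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
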