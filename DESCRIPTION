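Package: halotype
Title: Salt-Tolerance Phenotyping of Wheat from Canopy Hyperspectral
    Reflectance and Grain Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening spring wheat genotypes for salinity
    tolerance from field data. Computes 20 canopy spectral reflectance
    indices (10 vegetation, 10 water) on full-range (350-2500 nm)
    spectroradiometer spectra with atmospheric-band masking, derives five
    yield-based stress tolerance indices (YSI, SSI, STI, TOL, GMP) from
    control and saline-irrigation grain yields, clusters genotypes into
    tolerance groups by Ward's minimum-variance method, screens
    index-yield correlations with a fixed-alpha critical-r threshold,
    selects predictive indices by partial-F stepwise regression, and fits
    per-year split-plot analyses of variance. A synthetic field-trial
    generator emulating group-structured yields and canopy spectra makes
    the whole analysis testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
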