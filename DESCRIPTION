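Package: stripsow
Title: Efficacy, Recovery and Cost Analysis of Strip-Sown Aerial Pest Baiting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing field trials that compare strip-sown and
    broadcast aerial application of toxic bait for rabbit control. Converts
    spotlight transect counts into per-replicate kill estimates and
    treatment-level comparisons, computes bait-deployment geometry (coverage,
    within-strip bait density, toxin loading per hectare), fits a beta
    distribution to operation efficacy by the method of moments, simulates
    post-control population recovery under density-dependent growth by Monte
    Carlo, and converts recovery times into per-hectare control costs over a
    farm-management horizon. Includes a synthetic trial generator with the
    sampling structure of a replicated before-after spotlight-count design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
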