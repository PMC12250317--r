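Package: anthroagree
Title: Anthropometric Body-Composition Equations and Method-Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compendium of anthropometric prediction equations for body
    density, fat percentage, fat mass, lean percentage and lean mass
    (skinfold-, circumference- and BMI-based), together with the
    method-comparison statistical battery used to validate such equations
    against a reference method such as dual-energy X-ray absorptiometry:
    normality-gated paired tests with Bonferroni families, bias with standard
    error of the difference and confidence intervals, Bland-Altman limits of
    agreement, reduced major axis regression, correlation bands, intraclass
    correlation coefficients (absolute agreement and consistency), technical
    error of measurement, and a paired-design sample-size formula. Includes a
    seeded generator of synthetic cohorts with correlated adiposity and frame
    structure so the whole pipeline can be exercised and calibrated without
    access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
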