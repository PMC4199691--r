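Package: sazd
Title: Process-of-Elimination Screen for Sexually Antagonistic Zygotic Drive
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect sexually antagonistic zygotic drive (SA-ZD), a
    paternal-effect son-killing phenotype, in sex-ratio count data from
    genetic crosses. Provides closed-form sex-ratio expectations at the
    embryo and subadult stages under segregation distortion, endosymbiont
    son-killing, constitutive male viability, feminization, asexuality and
    suppressor genetics; a seeded forward simulator of multi-generation
    cross designs producing per-vial brood counts with beta-binomial
    overdispersion; gametic and zygotic survival estimators with
    beta-binomial confidence intervals; an automated six-step dichotomous
    decision key that classifies the etiology of a female-biased sex ratio;
    and a two-point recombination assay with grandson follow-up and an
    exact map-distance bound.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB,
    optparse
Config/testthat/edition: 3
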