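Package: castguild
Title: Growth, Mortality and Reproductive Allocation in Parasitic
    Castrator Guilds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative life-history analysis of guilds of
    parasitic castrators (such as the larval trematodes of the California
    horn snail) and their uninfected hosts.  Converts mark-recapture shell
    measurements to growth volumes, fits overdispersed Poisson (quasi-
    Poisson) growth models with size-by-species interactions and nested
    site effects, estimates differential extrinsic mortality from a
    within-host dominance hierarchy and site-level infection prevalences,
    computes gonadosomatic and relative reproductive allocation indices,
    and tests growth-mortality and reproduction-mortality associations
    with randomization tests, standard major axis lines, regression
    through the origin and phylogenetically independent contrasts.
    Includes a synthetic-data generator with latent ground truth for
    estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
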