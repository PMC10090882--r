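Package: nasallom
Title: Comparative Allometry of the Amniote Nasal Cavity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether nasal-cavity size scales differently
    with head size and body size between endothermic and ectothermic amniotes,
    and for placing fossil taxa relative to the two groups' allometric lines.
    Provides ordinary least-squares, standardized major axis, and phylogenetic
    generalized least-squares (Brownian-motion) line fitting with a conditional
    slope-then-intercept group comparison scheme; voxel and mesh morphometry of
    labelled head volumes (region volumes, isosurface areas, minimum convex
    hull head models); an osteologically constrained reconstruction of the
    main nasal airway in fossil skulls with a soft-tissue volume correction;
    and a synthetic-data generator (ultrametric trees, phylogenetically
    correlated allometric traits, voxel skull phantoms with analytically known
    geometry) so the whole pipeline is testable without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
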