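Package: chirace
Title: Two-Helicase Race Model of RecBCD Cutting Under Small-Molecule Sensitization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses DNA cutting by the bacterial RecBCD
    helicase-nuclease as a race between its two motor subunits. Provides
    competitive-inhibition kinetics for the RecB and RecD motors with a
    closed-form Cheng-Prusoff IC50 and a two-condition Ki/Km solver, an
    event-driven simulator of Chi-hotspot-triggered versus end-stop-triggered
    cuts on end-labeled linear substrates, a forward model of the agarose-gel
    readout (migration, marker ladders, lane densitometry) with band detection
    and log-linear length interpolation, inference of the RecB:RecD velocity
    ratio and the nuclease swing delay from product-length versus
    substrate-length fits, four-parameter logistic dose-response fitting, and
    seeded generators of complete in-silico cutting and nuclease-solubilization
    experiments for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
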