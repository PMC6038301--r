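Package: aoaflux
Title: Stoichiometric Energy Yields and Flux Balance Analysis for
    Ammonia-Oxidizing Archaea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of chemolithoautotrophic energy
    metabolism in marine ammonia-oxidizing archaea. Encodes the proposed
    ammonia-oxidation electron-transport pathways of Nitrosopumilus
    maritimus SCM1 and derives their net reactions and theoretical
    ATP/NH4+ yields by linear programming; provides a small flux balance
    analysis engine (with a loopless option and lexicographic source-flux
    minimization), biomass mass-balance normalization, the
    artificial-input procedure for the ATP and reducing-equivalent cost
    of biomass synthesis from CO2, and a yield ledger converting
    published growth measurements into biomass and ATP yields per mole of
    ammonium, including the global carbon-fixation extrapolation.
    Includes SBML and tabular model input/output and synthetic model
    generators with planted ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
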