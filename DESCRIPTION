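Package: odfpbpk
Title: Mechanistic Oral-Cavity and Gastrointestinal Absorption Modeling for
    Orodispersible Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physiologically based absorption modeling of orodispersible film
    (ODF) formulations in the beagle dog, built around a coupled oral-cavity
    compartmental absorption-and-transit model (six mucosal sites sharing a
    saliva pool, with a hold-and-swallow transit option) and a nine-compartment
    gastrointestinal absorption-and-transit model, driving a three-compartment
    systemic disposition model. Includes z-factor dissolution kinetics with
    pH-dependent solubility for ionizable bases, non-compartmental analysis of
    plasma concentration-time curves, fold-error model validation, residence-time
    sensitivity analysis, and a synthetic-data generator for crossover
    pharmacokinetic studies and dissolution profiles. Ships a fully parameterized
    risperidone/beagle fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
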