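Package: transitpk
Title: Exact Multi-Dose Solutions and Dosing Regimen Regions for Transit
    Compartment Pharmacokinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form transient and periodic steady-state drug level
    solutions for one-compartment, two-compartment, and n-transit-compartment
    pharmacokinetic models under repeated bolus and infusion dosing, built on
    numerically robust evaluation of the lower incomplete gamma function
    (including negative arguments) and exact Stirling numbers of the second
    kind. Includes the Stirling-approximation baseline model for error
    comparison, least-squares parameter estimation with a transit-compartment
    number sweep and flip-flop identifiability diagnostics, synthetic
    observation generators, and construction of equi-dosing regimen regions
    (EDRRs): the sets of dose, interval, loading-dose and infusion parameters
    whose periodic steady-state trajectories stay within a prescribed
    therapeutic range.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
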