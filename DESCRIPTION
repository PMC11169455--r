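Package: thiamsim
Title: Kinetic Modelling and In Silico Enzyme Overexpression Scanning of
    Thiamin Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic simulation of small metabolic networks,
    built around the vitamin B1 (thiamin) biosynthesis pathway of rice.
    Provides declarative reaction/parameter tables and SBML Level 3 exchange,
    Michaelis-Menten (one- and two-substrate), mass-action and constant-flux
    rate laws, stiff ODE time-course simulation with plateau and peak
    annotation, an in-silico enzyme overexpression/knockout scanner that
    scales Vmax values and ranks biofortification strategies, a stoichiometric
    flux-balance fallback to gap-fill reactions lacking kinetic constants,
    growth-curve analysis (exponential-phase growth rates, ANOVA with Tukey
    post-hoc comparison), and synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
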