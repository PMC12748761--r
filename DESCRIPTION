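Package: cassavabc
Title: Tri-Trophic Demographic Simulation and Bioeconomic Analysis of
    Cassava Biological Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weather-driven physiologically based demographic models (PBDMs)
    of the African cassava system: a metabolic-pool cassava canopy model,
    distributed-maturation-time cohort dynamics for the cassava mealybug
    (Phenacoccus manihoti), the cassava green mite (Mononychellus tanajoa),
    their introduced parasitoids (Anagyrus lopezi, A. diversicornis) and
    predatory mites (Typhlodromalus aripo, Amblydromalus manihoti), and
    endemic fungal pathogens (Neozygites spp.).  Includes a synthetic
    tropical daily-weather generator, factorial absence/presence scenario
    experiments, and marginal bioeconomic regression analysis of the
    resulting yield and pest-density tables, with the published regression
    equations shipped as fixtures for exact reproduction of their marginal
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
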