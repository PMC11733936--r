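Package: offrate
Title: Ligand Dissociation Rates from Temperature-Scaled Unbinding Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts relative ligand dissociation rates (k_off) from short
    replicated high-temperature molecular dynamics simulations. Unbinding
    events are detected from ligand RMSD after protein superposition, the
    median first-unbinding time across replicas (with censoring) is converted
    to a rate, and the rate is reweighted to room temperature through a
    population-based temperature-scaling relation. Includes thermodynamic
    conversions between k_off, K_d and binding free energy, virtual-screening
    enrichment metrics, benchmark statistics, and a built-in overdamped
    Langevin toy simulator whose closed-form Kramers escape rates make the
    whole pipeline testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
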