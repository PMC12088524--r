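Package: larvaCPG
Title: Conductance-Based Model of the Drosophila Larval Locomotor CPG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the central pattern generating network underlying
    fictive locomotion in the isolated Drosophila larval CNS. Hemisegmental
    excitor/inhibitor oscillators built from identical non-spiking
    single-compartment neurons with voltage-gated calcium channels and graded,
    calcium-dependent synapses are assembled into abdominal, thoracic, and
    full bilateral circuits with command, initiation-detector, wave-detector,
    and head-sweep-detector motifs. Includes Poisson pulse-train and ramp
    stimulus protocols, simulated optogenetic disinhibition via a blockable
    chloride conductance, a fixed-step exponential-Euler integrator, and an
    analysis layer that classifies fictive motor programs (metachronal waves,
    bursts, head sweeps) from multichannel traces and computes wave metrics,
    overlap, transition matrices, and bilateral-asymmetry density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
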