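Package: pavnet
Title: Enumeration and Combination of Robust Regulatory Network Topologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates signed three-node transcription-regulation network
    topologies, screens each one for its ability to perform conditioning-type
    biological functions (a learning module with persistent memory and a
    recall module) under Hill-function ordinary differential equation
    dynamics with log-scale Latin hypercube parameter sampling, and merges
    robust sub-networks into whole Pavlovian-like circuits under
    sign-consistency and node-role constraints. The robustness of a topology
    is summarised by its Q-value, the fraction of sampled parameter sets
    under which the network performs the target function. Also provides
    regulation-entropy scoring, random-network baselines, hierarchical
    clustering of topology pools, plain-text result formats, and fully
    seedable, deterministic screening pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    parallel,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
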