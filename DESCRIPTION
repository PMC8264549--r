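Package: stigmergy
Title: Active-Inference Simulation of Stigmergic Ant Colony Foraging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-agent simulator of ant colony foraging in an alternating
    T-maze, where each forager is a discrete-state active-inference agent.
    Foragers sense the pheromone field in their 3x3 neighborhood through a
    likelihood re-cut from an environment-level reallocation matrix, score
    one-step relocation policies by expected free energy, and sample actions
    from a softmax over policies. Food-laden foragers deposit attractant
    trail pheromone on their way back to the nest, closing the stigmergic
    loop. The package records per-agent trajectories, pheromone-field
    snapshots, and colony-level phenotypes (cumulative round trips and a
    swarm distance coefficient), and ships plotting helpers, tidy()/glance()
    methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
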