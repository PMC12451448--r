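Package: holosim
Title: Agent-Based Simulation of Host-Microbiome (Holobiont) Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of a holobiont: a constant-sized
    Wright-Fisher population of haploid hosts whose fitness derives from the
    mean trait value of their microbiome, with microbial communities under
    direct Gaussian stabilizing selection both within hosts and in an
    environmental pool. Supports multiple microbial generations per host
    generation, mixed-mode (vertical and horizontal) microbial transmission,
    environmental-pool renewal from persistence, host shedding and a fixed
    source, and six environmental-change scenarios (autocorrelated or
    independent fluctuations, increasing mean, increasing variance). Records
    tidy per-generation tables of host fitness, within-host microbial fitness
    and scaled Shannon alpha diversity, with ggplot2 plotting and broom-style
    tidiers.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
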