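Package: semeco
Title: Plasmid Segregation Dynamics and Composition of Self-Establishing
    Metabolically Cooperating Yeast Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the progressive loss of complementation plasmids in a
    yeast population growing from a single prototrophic founder, and the
    community of cross-feeding auxotrophs (a self-establishing metabolically
    cooperating community, SeMeCo) that results. Provides the metabotype
    state space over k segregating markers, deterministic and stochastic
    (branching-process) segregation simulators under neutral,
    no-cooperation, cooperation and fitness-weighted growth regimes,
    estimation of per-division segregation rates from replica-plating
    counts, summarisation and comparison of observed versus predicted
    community compositions, nearest-prototroph proximity analysis of
    multi-channel fluorescence colony images, Richards growth-curve fitting,
    and seeded synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
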