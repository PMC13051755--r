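Package: phyllokbs
Title: Phyllosphere Community Assembly, Keystone and Beneficial-Specialist Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An ecology pipeline for phyllosphere microbiome OTU tables:
    community-assembly partitioning with the beta nearest taxon index (betaNTI)
    and Raup-Crick (Bray-Curtis) null models, Sloan neutral community model
    fitting, Levins niche-breadth specialist classification with a fixed-fixed
    permutation null, signed Spearman co-occurrence networks with Zi-Pi keystone
    roles, a three-criterion keystone-beneficial-specialist (KBS) screen, and
    maximum-likelihood path analysis (SEM) linking soil, community structure,
    keystones and crop yield. Includes a synthetic-data generator with known
    ground truth so every stage supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    permute,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite,
    MASS
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
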