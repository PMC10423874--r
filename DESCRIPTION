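Package: oildrop
Title: Fuzzy Oil Drop Analysis of Protein Hydrophobic Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how closely the hydrophobicity distribution of a
    protein structure follows the idealized micelle-like pattern of the
    fuzzy oil drop (FOD) model and its environment-modified FOD-M variant.
    Computes the theoretical (T) profile from a 3D Gaussian encapsulating
    the structure, the observed (O) profile from distance-damped pairwise
    hydrophobic interactions, the uniform reference (R) profile, the
    relative-distance statistic RD based on Kullback-Leibler divergence,
    and the optimal environment parameter K of the modified target
    distribution M(K). Supports whole complexes, individual chains, chains
    in the context of a complex, protein-protein interfaces, domains,
    disulfide-delimited fragments and arbitrary residue selections, with a
    seeded generator of synthetic micelle-like structures for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
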