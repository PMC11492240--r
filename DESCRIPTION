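Package: reinet
Title: Physics-Based Residue Interaction Energy Networks from Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue-level protein networks from molecular dynamics
    trajectories and compares them across structures. Edges are weighted either
    by inter-residue distances (centre-of-mass or atom-contact counts) or by the
    trajectory mean of the absolute nonbonded interaction energy
    (Lennard-Jones plus Coulomb with CHARMM-style switching and cutoffs)
    computed per residue pair from topology charges and van der Waals
    parameters. Per-residue connectivity is summarised as the average
    shortest-path length (Dijkstra), normalised, mapped onto structures via the
    B-factor column, and compared between homologous proteins through gapped
    global sequence alignment. Includes a synthetic-system generator with exact
    brute-force energy sidecars so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
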