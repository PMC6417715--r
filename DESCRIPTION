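Package: lipidsites
Title: Protein-Lipid Contacts, Helix Tilt and Lipid Site-Transition
    Networks for Coarse-Grained Membrane Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained molecular dynamics
    trajectories of membrane proteins in lipid bilayers. Reads bead-level
    structures (PDB/GRO) and trajectories (DCD/GRO), assigns bilayer
    leaflets from phosphate positions, superposes frames by least-squares
    (Kabsch) rotation and reports whole-protein and per-helix RMSD,
    measures helix tilt with sliding-window local axes including
    kink-split sub-segments, counts protein-lipid bead contacts under
    periodic minimum-image distance criteria with cutoff-sensitivity
    checks, normalises per-residue contact-frequency maps, and builds
    leaflet-separated lipid site-transition networks (nodes are
    helix-combination labels, edges are collapsed-path transitions)
    clustered by Louvain community detection. A seeded synthetic-bilayer
    generator with planted ground truth (leaflets, residence affinities,
    tilts, kinks) supports validation of every stage without external
    trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    tools,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, xml2, yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
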