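Package: NetRewire
Title: Evolution of Domain-Peptide Interaction Networks Across Species
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how peptide-recognition-module (e.g. SH3) and
    kinase interaction networks rewire over evolutionary time. Predicts
    domain-target interactions by scanning proteomes with position weight
    matrices gated on disorder and surface accessibility, assembles per-species
    networks with a top-N selection rule, maps networks between species through
    gene-tree-constrained orthology, quantifies interaction-rewiring versus
    protein-change rates with saturation and randomization analyses, builds
    phylogenies from binary interaction profiles, detects overlapping
    binding-site clusters, and scores divergence-weighted binding-site
    conservation. Includes a forward simulator of network evolution along a
    species tree that provides ground-truthed fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: NetworkInference, Network, Phylogenetics, SequenceMatching
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'NetRewire-package.R'
    'orthology.R'
    'network.R'
    'rewiring.R'
    'pwm.R'
    'conservation.R'
    'phylo.R'
    'simulate.R'
    'utils.R'
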