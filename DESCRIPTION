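Package: TuSCmorph
Title: Segment-Wise Conformational Analysis of Gamma-Tubulin Complexes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative structural comparison of multi-spoke gamma-tubulin
    complexes (gamma-TuSC/gamma-TuRC). Implements rigid-body least-squares
    superposition, a segment-wise morph-compare procedure that places the
    segments of a query model into a reference conformation and measures
    per-segment displacement, per-residue displacement fields and
    inter-gamma-tubulin centroid geometry, Gaussian density-map simulation
    with masked cross-correlation and local rigid-body fitting, zone masking
    and nucleotide-site density scoring, straight/curved tubulin
    classification, and protein-protein interface contact and
    hydrophobicity/salt-bridge characterization. A synthetic two-spoke
    assembly generator with analytic ground truth makes every stage
    verifiable without external depositions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TuSCmorph-package.R'
    'conformation.R'
    'density.R'
    'displacement.R'
    'interfaces.R'
    'pipeline.R'
    'structures.R'
    'superpose.R'
    'synthetic.R'
    'utils.R'
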