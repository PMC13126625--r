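Package: posefrag
Title: Template-Based Ligand Pose Prediction and 3D-Annotated Fragment Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding poses for bioactive ligands by Gaussian
    molecular-field superposition onto crystallographic template ligands,
    refines them by MCS-tethered minimization inside a rigid pocket, fuses
    four normalized pose metrics (2D similarity, 3D field similarity,
    empirical docking score, interaction-feature affinity) into a confidence
    score with F1-optimized weights, deconstructs high-confidence poses into
    exhaustive BRICS fragments with inherited coordinates, and supports
    interaction-fingerprint bioisostere search and attachment-vector scaffold
    hopping over the resulting fragment library. Molecule standardization,
    format handling and force-field minimization are delegated to Open Babel;
    protein structures are read with bio3d.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    bio3d,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'obabel.R'
    'geometry.R'
    'molecule.R'
    'embed3d.R'
    'chemprep.R'
    'fingerprint.R'
    'templates.R'
    'fieldalign.R'
    'refine.R'
    'scoring.R'
    'fragmenter.R'
    'library.R'
    'queries.R'
    'validation.R'
    'pipeline.R'
    'fixtures.R'
RoxygenNote: 7.3.3
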