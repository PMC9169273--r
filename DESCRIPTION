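Package: chemdepict
Title: Randomised Chemical Structure Depiction Generation for OCSR Training Data
Version: 0.1.0
Authors@R: person("chemdepict", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Generates diverse, reproducible raster depictions of chemical
    structures from SMILES input for training and benchmarking optical
    chemical structure recognition (OCSR) systems. Depiction parameters
    (bond length, line thickness, kekulisation, fonts, rotation, superatom
    abbreviation, atom numbering, chirality labels, ...) are drawn
    pseudo-randomly per style profile and summarised as one-hot
    depiction-feature fingerprints whose valid combinations can be
    enumerated exactly and sampled diversely with MaxMin (farthest-point)
    picking. Ships non-structural annotation generators (identity, rest
    group and reaction-condition labels, curved and straight arrows), an
    image-augmentation stack (rotation, shear, salt-and-pepper noise,
    brightness and colour jitter, JPEG-style compression, pixelation), a
    distort-then-resize step, seeded batch generation with replayable
    manifests, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
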