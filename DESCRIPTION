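Package: gpcrdimer
Title: GPCR Homodimer Interface Energetics, Helix Sampling and FRET Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing G-protein-coupled receptor homodimer
    interfaces at residue resolution. Provides a molecular data model over
    PDB coordinates with user-supplied nonbonded parameters (partial
    charges and 12-6 Lennard-Jones coefficients), residue-level pairwise
    Coulomb/van der Waals interface-energy decomposition with a
    distance-cutoff residue selection rule, a two-phase Conformational
    Memories Monte-Carlo/simulated-annealing sampler for single
    transmembrane helices, kinked-helix bend/wobble/face-shift geometry
    descriptors, sensitized-emission FRET normalization with bleed-through
    correction and pixel colocalization statistics, synthetic-data
    generators for all of the above, and table renderers that follow the
    rounding conventions of published interaction-energy tables.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
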