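Package: trem2map
Title: Mapping TREM2 Ligand-Binding Surfaces from Hydropathy Screens and
    Biolayer Interferometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for sequence-based prediction and biophysical mapping of
    ligand-binding surfaces on the microglial receptor TREM2. Implements a
    hydropathy-complementarity screen (binary Kyte-Doolittle hydrophobicity
    maps, bidirectional motif scanning, percent match and a normalized
    complementarity statistic, and clustering of good hits into candidate
    binding regions), a 1:1 Langmuir model for biolayer interferometry
    sensorgrams with steady-state and global kinetic dissociation-constant
    fitting, quantification of sequential competition-binding experiments,
    a structured TREM2 point-variant library with per-ligand affinities,
    and seeded synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
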