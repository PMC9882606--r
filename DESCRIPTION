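Package: hotphore
Title: Hotspot Pharmacophores from Protein-RNA Complexes and Ligand Shape Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distills protein-RNA complex structures into minimal "hotspot
    pharmacophores": deeply buried RNA bases are detected by solvent-accessible
    surface area burial, intermolecular hydrogen-bond atoms are collected,
    non-bonding polar atoms are reverted to carbon, and neighbouring moieties
    are clustered into compact templates. Small molecules are embedded into
    low-energy conformers, aligned rigidly to a pharmacophore under a Gaussian
    shape plus typed-feature overlap objective, scored with shape/color
    Tanimoto coefficients, and placed back into the receptor frame for clash
    filtering and simple interaction scoring. A pharmacophore library built
    from many complexes supports compound selectivity profiling and a
    two-dimensional multidimensional-scaling map of pharmacophore space.
    Includes a synthetic-complex generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: python (>= 3.8) with rdkit, for conformer embedding
Config/testthat/edition: 3
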