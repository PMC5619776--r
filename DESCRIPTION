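Package: acnp
Title: Molecular Theory of Antigen Capture by Antibody-Conjugated Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-consistent molecular theory of ligand-receptor binding on
    crowded nanoparticle surfaces. Generates coarse-grained conformational
    ensembles of surface-tethered antibodies and antibody-antigen complexes
    (rotational-isomeric-state spacers, rigid alpha-carbon bead models),
    minimizes a mean-field free energy under local incompressibility on a
    radial grid around a spherical nanoparticle, and predicts captured
    antigen, surface species populations, and conformational observables as
    functions of surface coverage, bulk concentration, affinity, spacer
    length, and nanoparticle radius for covalent and streptavidin-biotin
    conjugation schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
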