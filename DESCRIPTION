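Package: solvscat
Title: Differential Solution X-Ray Total Scattering from Atomistic Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes coherent X-ray scattering from atomistic ensembles via the
    Debye scattering equation with tabulated atomic form factors, and implements
    a complete framework for the differential solution total-scattering
    experiment: the differential reduced structure function dF(Q) measured
    between a dilute solution and a matched pure-solvent reference is decomposed
    exactly into solute-solute, solute-solvent, excluded-solvent and
    solvent-restructuring terms, transformed to differential reduced pair
    distribution functions dG(r), and the importance of each term is quantified
    with a model ladder scored by the coefficient of determination and the
    crystallographic R factor. Includes fused-sphere van der Waals volumes, the
    excluded-solvent droplet labelling algorithm, a seeded hard-sphere Monte
    Carlo solvent sampler for fully synthetic ideal-dilute test systems, and
    readers/writers for extended-XYZ structures and two-column scattering
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
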