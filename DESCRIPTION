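Package: phagepack
Title: Coarse-Grained Simulation of Viral Genome Packaging and Ejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular-dynamics engine and experiment drivers for studying how
    temperature, backbone charge and a capsid tail affect the packaging and
    ejection of a semiflexible polymer (a coarse-grained phage genome) through
    the pore of a rigid spherical capsid. The polymer is a Kremer-Grest
    bead-spring chain (FENE bonds, repulsive Lennard-Jones cores, bending
    rigidity, optional Debye-Hueckel electrostatics) driven by a constant-force
    motor at the pore and coupled to a stochastic rotation dynamics (SRD/MPCD)
    solvent whose hydrodynamic correlations can be switched off. Includes the
    full packing/ejection protocol, replicate ensembles with mean +/- SEM time
    series, event-time distributions, persistence-length estimation and
    bending-rigidity calibration, an intracapsid nematic order metric, XYZ/CSV
    output and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
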