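Package: sugarglass
Title: Hydrogen Bonding, Structure and Free-Energy Analysis of Disaccharide-Water Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics studies of disaccharide
    (sucrose, trehalose) hydration across a 0-100 wt% water concentration
    series. Provides geometric hydrogen-bond detection with per-oxygen and
    per-group normalisations and symmetry averaging, radial distribution
    functions under periodic boundary conditions with a reproducible contact
    score mapping, dihedral distributions, radius of gyration, OH-bond-vector
    orientational autocorrelation with exponential correlation-time fits, and
    free-energy post-processing: WHAM reconstruction of umbrella-sampling
    windows, well-tempered metadynamics free-energy surfaces from HILLS
    records, and binding free energies from the ratio of Boltzmann integrals
    over bound and unbound regions of a potential of mean force. A synthetic
    systems module generates every input with known ground truth: planted
    hydrogen-bond configurations, rotational-diffusion vector series,
    overdamped Langevin trajectories on analytic potentials under umbrella or
    well-tempered bias, and model sugar-water mixtures on the composition
    series of the study design. Reads and writes GROMACS GRO, an XYZ-with-box
    trajectory dialect, and PLUMED-style HILLS and umbrella time-series text.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
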