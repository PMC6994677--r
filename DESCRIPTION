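Package: nsedyn
Title: Structure and Dynamics of Protein Folding States from Small-Angle
    Neutron Scattering and Neutron Spin-Echo Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterizing folded, molten-globule and
    unfolded protein states in solution by small-angle neutron scattering
    (SANS) and neutron spin-echo (NSE) spectroscopy.  Provides generalized
    Guinier and excluded-volume polymer form-factor models with weighted
    fitting and derived chain parameters (Flory exponent, Kuhn length,
    end-to-end distance, compactness, overlap concentration); experimental
    and mean-spherical-approximation (MSA) structure factors for charged
    macro-ions with hydrodynamic-function corrections; cumulant and
    stretched-exponential analysis of normalized intermediate scattering
    functions; simulation and global fitting of the Zimm and
    Zimm-with-internal-friction (ZIF) dynamic structure factor; rigid-body
    first-cumulant diffusion from coordinates with elastic-network normal
    modes; and seeded synthetic-data generators emulating every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
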