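Package: lutadose
Title: Organ and Tumour Dosimetry Workflows for 177Lu-DOTATATE Therapy Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of internal dosimetry workflows for
    peptide receptor radionuclide therapy with 177Lu-DOTATATE. Provides a
    digital-phantom generator (mono-exponential organ kinetics on top of
    physical decay, photon attenuation, finite-resolution blur, Poisson
    counting noise, a co-scanned calibration syringe), conjugate-view
    (geometric-mean) planar quantification with thickness-weighted
    background correction, SPECT volume-of-interest quantification with
    partial-volume recovery coefficients, hybrid planar/SPECT rescaling with
    projection-overlap removal and substitution, mono-exponential
    time-activity fitting and MIRD residence times, organ and sphere-model
    tumour absorbed doses with individual mass adjustment, and paired
    statistical comparison (Friedman, Wilcoxon signed-rank, Kendall's W) of
    the multi-SPECT-CT, planar-only and hybrid dosimetry scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    minpack.lm
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
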