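Package: halott
Title: Halothermal-Time Threshold Models for Seed Germination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-based threshold ("halothermal time") models for seed
    germination under combined temperature and osmotic (NaCl) stress. Fits the
    base-water-potential distribution, halo/thermal/halothermal time constants,
    the supra-optimal shift coefficient kT and cardinal temperatures by repeated
    probit regression; computes the classical germination and vigour indices
    (GP, GE, GI, GRI, TGI, MGT, MGR, CVG, T50, SVI); simulates germination time
    courses from the generative threshold model; and assembles per-temperature,
    global-parameter and derived-quantity report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
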