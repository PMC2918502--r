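Package: ovocolor
Title: Comparative Analysis of Avian Eggshell Coloration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses of avian eggshell reflectance
    spectra measured against a white standard. Processes raw
    spectrophotometer output onto a canonical 300-700 nm, 5 nm grid,
    computes relative spectra, luminance and brightness, models colours in
    an avian tetrachromatic receptor-noise-limited space in which Euclidean
    distance is a just-noticeable difference (JND), partitions spectral
    variance across five nested taxonomic levels (replicate, egg, clutch,
    species, family) by moment-based nested ANOVA, estimates phylogenetic
    signal as Pagel's lambda by maximum likelihood with likelihood-ratio
    tests against 0 and 1 under equal and proportional branch-length
    schemes, and performs sister-pair, museum-storage, sampling-bias and
    maculation-repeatability analyses. A synthetic-data module generates
    complete studies (phylogeny, taxonomy, pigment-based spectra with
    nested noise, collection years, maculation scores) with known ground
    truth so every pipeline stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
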