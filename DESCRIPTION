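Package: capibridge
Title: Capillary-Bridge Model of Fibrillar Wet Adhesion in Air and Underwater
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric Young-Laplace solver for liquid (and gas) bridges
    pinned to a circular rim, with a discrete energy-minimization backend for
    cross-validation; Young-Dupre combination giving the underwater contact
    angle of an oily adhesive secretion; superposition of single-bridge forces
    into the net force of a rigid hairy adhesive pad in air and underwater,
    with or without a trapped air bubble (Cassie state); parameter studies
    (contact-angle, bubble-volume and contact-splitting sweeps, whole-animal
    predictions, sensitivity analysis); and reduction of experimental-style
    force traces to pull-off forces with time-matched background subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
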