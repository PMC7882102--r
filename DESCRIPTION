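Package: fracdose
Title: Dosimetric Accuracy Analysis for Fractionated Pelvic IMRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the three classes of dosimetric error that
    separate a planned intensity-modulated radiotherapy (IMRT) course from the
    dose actually delivered over a fractionated treatment: machine-control
    error statistics extracted from linac trajectory logs (MLC position and
    monitor unit differences, aperture statistics), residual patient setup
    errors simulated by stochastic rigid blurring of the planned dose cloud
    with DVH readout (D98%, D2%), and daily anatomical change assessed by a
    path-length perturbation dose estimate on stitched limited-field-of-view
    CBCT volumes with fractional and accumulated dose comparison, Dice overlap
    QA and paired significance testing. A synthetic pelvic phantom generator
    supplies CT volumes, structures, plan doses, daily anatomies with weight
    change and gas pockets, registrations, analytic deformation fields and
    trajectory logs with injected error laws, so the whole pipeline runs and
    is tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
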