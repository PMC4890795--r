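Package: glycalf
Title: Intermittent Gastric Emptying and Postprandial Glucose-Insulin
    Dynamics in Milk-Fed Calves
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of postprandial glycemia and insulinemia
    driven by intermittent gastric emptying, for milk-fed calves and similar
    monogastric meal responses. A five-state delay differential model couples
    first-order gastric outflow, switched between fast, slow and zero rates
    by a per-interval Z-schedule classified from acetaminophen marker
    timecourses, to a Bergman-type minimal model of glucose disposal with
    Hill-equation pancreatic insulin secretion. Provides a fixed-step
    Runge-Kutta simulator with transport-delay history, closed-form
    acetaminophen fitting with rMSPE scoring, differential-evolution
    estimation of the glucose-insulin parameters under basal steady-state
    constraints, AUC-based parameter sensitivity coefficients, a synthetic
    timecourse generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
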