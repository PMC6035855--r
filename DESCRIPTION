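Package: dischargesim
Title: Discrete-Event Simulation and Six Sigma Analytics for Hospital
    Inpatient Discharge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the inpatient discharge process of a hospital ward as a
    discrete-event simulation: activities with stochastic durations, finite
    resource pools (porters, pharmacists, medical-records officers,
    accountants), patient-need branching and parallel paperwork/medication
    paths.  Ships a calibrated baseline workflow, a menu of improvement
    scenarios evaluated with common random numbers, a simulated-moments
    calibration routine for unobserved activity durations, a synthetic
    shadowing-data generator, and a statistical process control toolkit
    (individuals/moving-range charts, process capability, sigma quality
    level, sample-size calculation, two-population mixture classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
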