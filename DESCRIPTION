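Package: oxytrace
Title: Intermittent-Flow Respirometry, Critical Oxygen Tension and
    Hypoxia-Tolerance Analysis for Fish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing oxygen time series from intermittent-flow
    and closed respirometry of small fish: per-cycle oxygen-depletion slope
    fitting and conversion to mass-specific metabolic rate, background
    (blank-chamber) correction and quality control, estimation of standard
    and maximum metabolic rate and absolute aerobic scope, Fulton's body
    condition factor, critical oxygen tension (Pcrit) by continuous
    two-segment breakpoint regression with bootstrap confidence intervals,
    loss-of-equilibrium hypoxia tolerance, freshwater dissolved-oxygen unit
    conversion (mg/L, kPa, percent air saturation), and two-factor
    permutational ANOVA for treatment contrasts. Includes a trace simulator
    that generates chamber oxygen records from fish with known physiology
    so that every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
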