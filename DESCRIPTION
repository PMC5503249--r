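Package: edflux
Title: Dynamic Kinetic Model of the Branched Entner-Doudoroff Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic ordinary-differential-equation model of the modified,
    branched Entner-Doudoroff pathway that converts D-glucose to pyruvate in
    thermoacidophilic Archaea, with semi- and non-phosphorylative branches,
    first-order decay of thermolabile intermediates and clamped cofactor
    pools.  Provides steady-state integration with a residual-rate
    convergence criterion, Arrhenius/Van't Hoff temperature scaling between
    70 and 80 degrees Celsius, constrained least-squares estimation of
    unmeasured maximal velocities, deterministic sensitivity analysis,
    seeded Monte-Carlo robustness analysis, in-silico branch knockouts,
    feedforward-inhibition perturbation experiments, a synthetic-data
    generator for end-to-end testing, and an SBML-style model exchange
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
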