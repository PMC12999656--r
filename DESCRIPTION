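Package: tpcevol
Title: Eco-Evolutionary Adaptation of Competition Thermal Performance
    Curves under Stochastic Temperatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how unpredictable temperature fluctuations
    shape the evolution of competition thermal performance curves (TPCs) in
    ectotherm populations. Implements a bounded stochastic temperature
    process, temperature-dependent Ricker population dynamics for resident
    and rare-mutant types competing through beta-density TPCs, invasion
    fitness by long-run time averaging with common random numbers,
    finite-difference selection gradients and fitness Hessians, canonical
    adaptive-dynamics trait trajectories, numerical location and
    classification of evolutionary singularities (CSS/ESS), and parameter
    sweeps over noise magnitude and fluctuation frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
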