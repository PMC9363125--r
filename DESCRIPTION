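Package: wntgrad
Title: Reaction-Diffusion Modelling of Wnt6 Gradient Formation in Cardiogenic Mesoderm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: One-dimensional reaction-diffusion simulation of Wnt6 signalling
    gradient formation in Xenopus cardiogenic mesoderm. Implements a 13-species
    mass-action network coupling the Wnt6 ligand, its receptor Fzd7 (with
    Wnt-signal-dependent positive feedback of receptor production),
    dominant-negative Fzd7 variants, the secreted antagonist sFRP1 (whose
    production is repressed by Wnt signalling) and immobile N-acetyl-rich
    heparan sulfate binding sites. The stiff method-of-lines system is
    integrated with a BDF solver; derived quantities include cumulative
    signalling activity, the threshold-crossing edge of the signal-active
    region, threshold-swept edge-shift robustness analyses, kymographs and
    time-to-steady-boundary measures. Includes deterministic desk-scale
    fixtures with an independent fixed-step explicit reference integrator, and
    pre-configured in-silico experiments (feedback sweeps, ligand-production
    robustness, dominant-negative receptor dissection, antagonist/heparan
    sulfate contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
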