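# wntgrad

Reaction–diffusion modelling of Wnt6 signalling-gradient formation in
*Xenopus* cardiogenic mesoderm.

During heart development, Wnt6 secreted from the epidermis patterns the
adjacent mesoderm: high signalling specifies the thin pericardium, low
signalling the myocardium. The package implements the one-dimensional
extracellular network that shapes this gradient — the receptor Fzd7 with
Wnt-signal-dependent positive feedback of its own production, the secreted
antagonist sFRP1 (repressed by Wnt signalling), immobile N-acetyl-rich
heparan sulfate (HS) that traps sFRP1, and dominant-negative Fzd7 variants —
and the in-silico experiments used to probe it. It is intended for modellers
and developmental biologists who want to re-run, perturb or extend those
simulations.

## The model

Thirteen molecular species plus the cumulative signalling activity
ω(x, t) = k₄ ∫₀ᵗ [WR₂] dt′ evolve on x ∈ [0, 100] µm by mass-action
kinetics; one Wnt engages two receptors:

    W + 2R ⇌ WR₂ → ω   (k₁, k₋₁; internalization k₄)
    W + S ⇌ WS,  W + SH ⇌ WSH        (k₂, k₋₂)
    S + H ⇌ SH,  WS + H ⇌ WSH        (k₃, k₋₃)
    W + 2Dn ⇌ WD₂,  W + R + Dn ⇌ WRD (k₅, k₆; dnFzd7 traps Wnt)
    R + Dn ⇌ RD,  2Dn ⇌ D₂           (rate k₇[W]; dnFzd7 inactivates Fzd7)
    ∅ → W at p₁ f(x),   ∅ → S at p₂ g(x) / ((ω/K_d)ⁿ + 1)
    ∅ → R at p₃ k₄ [WR₂]   (receptor feedback)
    ∅ → Dn at p₄ k₄ [WR₂]

W, S and WS diffuse (D = 20 µm² s⁻¹) with zero-flux boundaries; receptor
and HS start on a sinusoidal bump on 10–40 µm; Wnt is produced on 0–10 µm
and sFRP1 on 25–100 µm. The stiff method-of-lines system (HS binding rates
reach ~2×10⁴ s⁻¹) is integrated by a BDF solver with a banded Jacobian.
Derived quantities: the threshold-crossing **edge** of the Wnt-signal-active
region, its **width**, threshold-swept **edge shifts** under ligand
perturbation (robustness), **kymographs**, and the **time to a steady
boundary**. See `vignette("wnt-gradient-model")` for the full equations,
parameter table and numerical choices.

## Worked example

Receptor feedback steepens the gradient and restricts the signal-active
region:

```r
library(wntgrad)

tr <- simulate_trajectory(wnt_scenario(feedback_multiplier = 5),
                          wnt_params(), discretize_domain(100, 200))
tr
#> <wnt_trajectory> 101 times x 200 cells x 14 components; t in [0, 1e+05 ] s
#> <wnt_scenario> feedback x 5 | initial receptor x 1 | ligand x 1 | sFRP1 on | HS on | dnFzd7 none
#>   final omega: max 10.54 nM at x = 23.25 um

ex <- run_feedback_sweep(wnt_params(), discretize_domain(100, 200),
                         feedback_multipliers = c(0, 1, 5),
                         initial_receptor_multipliers = 1)
ex$tables$widths[, c("feedback", "threshold", "width", "edge")]
#>  feedback threshold    width     edge
#>         0         1 18.36468 34.02029
#>         1         1 17.66132 33.56632
#>         5         1 16.04197 32.32175
```

The width of the region with ω ≥ 1 nM after one simulated day shrinks
monotonically as feedback strengthens (18.4 → 17.7 → 16.0 µm), and its
outer edge moves toward the source — the feedback concentrates signalling
near the ligand source. The boundary also settles sooner with feedback:

```r
time_to_steady_edge(tr, 1)                     # strong feedback
#> [1] 45000
time_to_steady_edge(simulate_trajectory(wnt_scenario(feedback_multiplier = 0),
                                        wnt_params(),
                                        discretize_domain(100, 200)), 1)
#> [1] 63000
```

i.e. with strong feedback the 1 nM boundary is within 1 µm of its final
position from 45 000 s on, versus 63 000 s without feedback — the system
reaches a steady boundary faster.

Other entry points: `run_robustness_experiment()` (edge shift under a 50 %
ligand-production increase), `run_dnfzd7_experiment()` (dissection of the
trap-Wnt and inactivate-Fzd7 functions), `run_sfrp1_hs_experiment()`
(antagonist/HS contrast, kymographs), `make_fixture_scenarios()` +
`explicit_reference_simulate()` (desk-scale fixtures and the independent
explicit integrator), `mass_balance_report()` (conservation checks), and a
small CLI (`inst/scripts/wntgrad`, or `cli_main()`).

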