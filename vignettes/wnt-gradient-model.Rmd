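---
title: "The Wnt6 gradient model: equations, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Wnt6 gradient model: equations, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntgrad)
```

## The biological problem

During *Xenopus* heart development the ligand Wnt6, secreted from the
epidermis, patterns the adjacent cardiogenic mesoderm: cells with high
Wnt/β-catenin signalling become the thin pericardium, cells farther from the
source become myocardium. Three extracellular systems shape the signalling
gradient: the receptor Fzd7, whose expression is itself induced by Wnt
signalling (a positive feedback of receptor production); the secreted
antagonist sFRP1, produced on the myocardial side and repressed by Wnt
signalling; and N-acetyl-rich heparan sulfate (HS), an immobile binding
substrate that captures sFRP1 and restricts its spread. `wntgrad` implements
a one-dimensional reaction–diffusion model of this system and the in-silico
experiments used to probe it: how feedback steepens the gradient, how it
buffers variation in ligand production, how the two separable functions of a
dominant-negative receptor act, and what sFRP1 + HS contribute.

## State variables and reactions

The field is the interval $[0, x_{max}]$ (default 100 µm) from the embryo
surface inward. Fourteen components are tracked per position (nM):
free Wnt6 ($W$), free sFRP1 ($S$), their complex ($WS$), free HS ($H$),
sFRP1–HS ($SH$), the ternary $WSH$, free receptor ($R$), the signalling
complex $WR_2$ (one Wnt engages **two** receptors, per the dimeric receptor
architecture), free dominant-negative receptor ($Dn$; renamed from the
single-letter convention to avoid collision with the diffusion coefficient
$D$), the heterodimer $RD$, homodimer $D_2$, the Wnt-loaded dimers $WD_2$ and
$WRD$, and the cumulative signalling activity
$$\omega(x,t) = k_4 \int_0^t [WR_2]\,\mathrm{d}t',$$
the running total of receptor-complex internalization, which stands in for
accumulated β-catenin-dependent transcription. No intracellular delay is
modelled: signal transduction is treated as fast relative to the one-day
horizon.

Mass-action reactions (rates in parentheses):

* $W + 2R \rightleftharpoons WR_2$ ($k_1$, $k_{-1}$), with internalization
  $WR_2 \to \omega$ at $k_4$; internalization destroys the complex (ligand
  and both receptors) and drives two productions: receptor feedback at
  $p_3 k_4 [WR_2]$ and, when enabled, dnFzd7 at $p_4 k_4 [WR_2]$.
* $W + S \rightleftharpoons WS$ and $W + SH \rightleftharpoons WSH$
  ($k_2$, $k_{-2}$): the antagonist binds Wnt whether or not it sits on HS.
* $S + H \rightleftharpoons SH$ and $WS + H \rightleftharpoons WSH$
  ($k_3$, $k_{-3}$): HS captures the antagonist, free or Wnt-loaded.
* $W + 2Dn \rightleftharpoons WD_2$ ($k_5$) and
  $W + R + Dn \rightleftharpoons WRD$ ($k_6$): the dominant-negative
  receptor traps Wnt.
* $R + Dn \rightleftharpoons RD$ and $2\,Dn \rightleftharpoons D_2$ with
  forward rate proportional to $[W]$ ($k_7[W]\cdot$): Wnt-catalysed
  dimerization, used to isolate the "inactivate-Fzd7" function.
  All receptor-containing complexes share the dissociation rate $k_{-1}$.
* Production: Wnt at $p_1 f(x)$ with $f = 1$ on $x \le 10$ µm; sFRP1 at
  $p_2\, g(x) / ((\omega/K_d)^n + 1)$ with $g = 1$ on $x \ge 25$ µm — the
  Hill term is the repression of sFRP1 production by Wnt signalling,
  evaluated with the *local* $\omega(x,t)$, since the production term
  carries no spatial coupling.

Only $W$, $S$ and $WS$ diffuse (shared coefficient $D$); everything bound to
cells or HS is immobile. Zero-flux (Neumann) boundaries at both ends encode
the bilateral symmetry of the heart field. Initial conditions are zero
everywhere except the receptor and HS, which start on the sinusoidal bump
$r_0\,[\sin(\pi(x-10)/15 - \pi/2) + 1]$ supported on 10 µm < x < 40 µm
(peak $2 r_0$ at 25 µm), and $h\,[\ldots]$ for HS.

One stoichiometric note: in the source description of the dnFzd7 monomer
balance, the dissociation of $WD_2$ is printed with rate constant $k_1$ and
without the factor 2 on the monomers returned by $WD_2$/$D_2$ breakup, which
would quietly destroy dnFzd7. `wntgrad` implements the conversion the
chemical network itself dictates ($+2k_{-1}[WD_2]$, $+2k_{-1}[D_2]$), which
makes the dnFzd7 moiety $Dn + RD + 2D_2 + 2WD_2 + WRD$ grow exactly with
$p_4\int\omega$, a property the mass-balance report checks.

## Parameters

Defaults of `wnt_params()` (the model's reference parameterisation):

| symbol | value | units | meaning |
|---|---|---|---|
| $k_1$ | 2.66e-6 | nM⁻² s⁻¹ | Wnt6 + 2 Fzd7 association |
| $k_{-1}$ | 9.6e-5 | s⁻¹ | receptor-complex dissociation |
| $k_2$, $k_{-2}$ | 4.33e-5, 4.86e-4 | nM⁻¹ s⁻¹, s⁻¹ | Wnt–sFRP1 binding |
| $k_3$, $k_{-3}$ | 1.86e-4, 3.66e-3 | nM⁻¹ s⁻¹, s⁻¹ | sFRP1–HS binding |
| $k_4$ | 2.52e-4 | s⁻¹ | complex internalization |
| $p_1$, $p_2$ | 1e-4, 1e-3 | nM s⁻¹ | Wnt / sFRP1 production density |
| $p_3$ | 10 | – | receptor feedback coefficient |
| $K_d$, $n$ | 1e-2 nM, 2 | | Hill repression of sFRP1 production |
| $D$ | 20 | µm² s⁻¹ | diffusion of $W$, $S$, $WS$ |
| $r_0$, $h$ | 75, 1e8 | nM | initial receptor / HS amplitude |
| $x_{max}$, $t_{max}$ | 100 µm, 1e5 s | | field width, ≈1 day |

Scenario switches (`wnt_scenario()`) are pure parameter overrides — never
structural changes to the right-hand sides: feedback multiplier on $p_3$
(0 = none, 1 = normal, 5 = strong), initial-receptor multiplier on $r_0$
(4 = the "high initial expression" condition), ligand multiplier on $p_1$
(1.5 = the 50 % production increase of the robustness analysis), on/off
switches zeroing $p_2$ or $h$, and the four dnFzd7 conditions, which set
$(p_4, k_5, k_6, k_7)$ to (0, $k_1$, $k_1$, 0), (100 $p_3$, $k_1$, $k_1$, 0),
(100 $p_3$, 0, 0, $k_1$) or (100 $p_3$, $k_1$, 0, 0) for no production, both
functions, inactivate-only and trap-only respectively. $p_4$ is tied to the
*base* $p_3$; the feedback multiplier does not rescale dnFzd7 production.

A nondimensional layer (`nondimensionalize()`) exposes the natural scales
$t^* = t_{max}$, $c^* = p_1 t^*$ (10 nM) and the diffusion length
$x^* = \sqrt{4 D t^*}$ (≈ 2828 µm). The source material prints the length
scale as $4D(t_{max}-t_{min})$, which is dimensionally a length squared; we
read it as a typeset loss of the square root, under which the scaled
diffusion coefficient is exactly 1/4. The dimensional equations are the
normative implementation either way; the layer exists for magnitude checks.

## Numerical method

The PDEs are discretized by method of lines on a uniform cell-centered grid
(default 200 cells, 0.5 µm; a minimum of 20 cells is enforced so the 10 / 25
/ 40 µm region boundaries stay resolvable). Step-function sources are
evaluated at cell centres: a cell is "in" a region iff its centre satisfies
the printed inequality, which makes the semantics grid-independent at the
boundaries. On the default and miniature grids the discrete Wnt-source width
is exactly the nominal 10 µm; the mass-balance report always uses the
discrete width so the production integral is exact at any resolution.
Diffusion is the standard 3-point stencil with reflecting ghost cells, which
is conservative to round-off.

The system is severely stiff: $k_3 h \approx 1.9\times10^4$ s⁻¹ against a
$10^5$ s horizon, so explicit schemes would need $\sim 10^9$ steps.
Integration uses the BDF solver `vode` (via \pkg{deSolve}) with an
internally generated *banded* Jacobian: the solver state is ordered
cell-major (all 14 components of a cell adjacent), so reactions couple
within the diagonal block and diffusion couples identical species in
neighbouring cells at offset ±14, giving half-bandwidth 14 regardless of
grid size. Default tolerances are rtol = 1e-6, atol = 1e-9 nM, with 101
uniform time samples. Mass-action kinetics preserve non-negativity in exact
arithmetic; saved states clip excursions above $-10^3\cdot$atol to zero,
and anything worse aborts the run as a solver failure. Convergence is
verified empirically: doubling the grid to 400 cells changes the final
$\omega$ profile by ~0.04 % (relative L∞), and tightening rtol to 1e-8
changes it by ~1e-8 — comfortably inside the 1 % / 0.1 % gates the test
suite enforces.

## Derived quantities

The signal-active region at threshold $\theta$ is $\{x: \omega(x) \ge
\theta\}$. `edge_position()` returns the rightmost threshold crossing
(linearly interpolated between cell centres; sentinels 0 / $x_{max}$ when
the profile is everywhere below / above), which for this left-source
geometry is the outer boundary of the active region. `active_region_width()`
measures the whole super-threshold set of the piecewise-linear interpolant,
which matters because $\omega$ vanishes where the receptor never existed
(x < 10 µm), making profiles non-monotone. Robustness is quantified by
`edge_shift()`: the absolute final-time edge difference between two runs,
swept over 200 log-spaced thresholds from $10^{-3}\max\omega$ to
$\max\omega$ of the base run — a dense stand-in for "all possible
thresholds" (the max-shift statistic is stable well below 1 µm against the
sweep resolution; the top level is pinned exactly at $\max\omega$ because
rounding it above the maximum would flip the base edge to the sentinel and
corrupt the statistic). `time_to_steady_edge()` reports the earliest saved
time from which the edge stays within ε (default 1 µm — below biological
relevance, above discretization noise) of its final position: the
"verticality" of a kymograph contour.

No single numeric threshold is printed for the dashed edge line in the
figures this package reproduces, so edge-based claims are evaluated as
threshold sweeps wherever possible; where one level is unavoidable the
package uses `default_edge_threshold()` = 1 nM, one tenth of the
concentration scale $c^*$, a mid-gradient level.

## Fixtures and the independent oracle

`make_fixture_scenarios()` builds six deterministic desk-scale systems: a
no-ligand field (signal machinery exactly silent), a no-antagonist field, a
closed well-mixed Wnt+sFRP1 binding system (relaxes to
$[WS]/([W][S]) = k_2/k_{-2} \approx 0.0891$ nM⁻¹), a softened miniature of
the default scenario (25 cells, $t_{max} = 10^3$ s, HS at $10^3$ nM), a
full-stiffness short HS run and the default-miniature conservation fixture
(50 cells, $10^4$ s). `explicit_reference_simulate()` is a fixed-step
forward-Euler transcription of the same network, written independently of
the solver path, with a stability guard ($\mathrm{d}t \times$ fastest rate
< 0.1, including the explicit diffusion limit). Explicit integration at the
full HS amplitude is infeasible, so oracle comparisons run on the softened
fixtures (agreement is ~3e-5 relative L∞, against a 2 % gate); the
full-stiffness runs are validated through conservation laws (HS moiety
constant per cell to ~1e-15, Wnt and Fzd7 balances to ~1e-9) and tolerance
tightening instead.

These fixtures emulate the *structure* of the study system — sources,
bumps, stiff HS capture — at reduced cost; they do not emulate measurement
noise or any biological variability (the model consumes no data), so
passing tests demonstrate numerical correctness of the stated equations,
not fidelity of the model to embryos.

## Design choices made where the design was open

* **Simulation start**: $t^* = t_{max} - t_{min}$ is defined without a
  stated $t_{min}$; zero is the only consistent start and is used.
* **Feedback sweep defaults**: factorial feedback {0, 1, 5} × initial
  receptor {1, 4}, with sFRP1 and HS enabled (the full model); the
  antagonist contrast toggles them. Mixed sFRP1-only / HS-only scenarios are
  available behind `include_mixed` as mechanism-dissection extras.
* **Cell-major state ordering** inside the solver (for the banded Jacobian);
  user-facing trajectories are `[time, cell, species]` arrays, so the
  ordering is invisible outside the integrator.
* **ω as a state component** ($\mathrm{d}\omega/\mathrm{d}t = k_4[WR_2]$)
  rather than post-hoc quadrature, which is what makes the Wnt balance
  $\int(\text{all } W\text{-species}) + \int\omega = p_1 \cdot 10\,\mu m
  \cdot t$ hold to solver precision at every saved time.

## Known limitations

* The geometry is strictly one-dimensional and the intracellular cascade is
  not modelled; conclusions concern extracellular shaping only.
* At the reference parameters the simulated sFRP1 + HS effect on the
  signal edge is directionally consistent with the narrowing claim but
  small (~0.01–0.3 µm depending on threshold), because HS confines the
  antagonist to a band the ligand barely reaches; the steadiness time is
  indistinguishable between the two conditions at the default time
  sampling. The package reports both quantities as computed.
* The ligand-production robustness experiment reproduces the feedback
  claim (max edge shift 3.78 µm with feedback vs 4.44 µm without) but not
  the high-initial-receptor claim: with 4× initial receptor and no
  feedback the max shift is *larger* (4.73 µm), because abundant receptor
  narrows the active region yet flattens the logarithmic slope of ω at the
  edge. The corresponding acceptance test is deliberately left failing
  rather than weakened; the numbers are recomputed by
  `scripts/acceptance.R` on every run.

## Problem sizes

Full-scale experiments use the 200-cell grid over the full $10^5$ s horizon
(each run integrates a 2800-dimensional stiff system; about a second per
run). The conservation and equilibrium fixtures use 20–50 cells and
$10^3$–$10^4$ s, chosen so the entire validation battery stays at
desk scale while still exercising the full-stiffness regime where the
implicit solver is the component under test.
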