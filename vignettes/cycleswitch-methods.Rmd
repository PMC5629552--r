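---
title: "Methods: the G0/G1-to-S switch model, the 81-way regulatory screen, and its numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the G0/G1-to-S switch model, the 81-way regulatory screen, and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleswitch)
```

## The biological question

Hematopoietic stem cells (HSCs) sit at a restriction point: quiescent (G0)
cells commit to the cycle when active CyclinD:Cdk4/6 ("Cyc D\*") and
CyclinE:Cdk2 ("Cyc E\*") phosphorylate Rb, releasing E2F, whose
autoactivation locks the decision in.  Two transcription factors, Maff and
Egr3, are strongly induced in leukemic HSCs, and their individual
overexpression accelerates and arrests the cycle, respectively.  How they
plug into the switch is unknown: each has a small set of candidate targets
(Maff on Cdk2:CyclinE and on p18; Egr3 on Cdk2:CyclinE and on Cdk4/6:CyclinD),
and each candidate edge can be activatory, absent, or inhibitory.  This
package reconstructs the switch as an ODE model, enumerates all
3^4 = 81 edge-sign combinations ("regulatory codes", digits 1 = inhibitory,
2 = none, 3 = activatory), and screens them against qualitative criteria
that encode the experimental observations.

## The model

Eight dynamic species (moles/cell; time in minutes): Maff protein `MF`,
Egr3 protein `EG`, the active complexes `CD` (Cyc D\*) and `CE` (Cyc E\*),
free `E2F`, hypophosphorylated `RB`, and the CDK inhibitors `P18`, `P19`.
All regulation is first-order Hill: activation `A(x;K) = x/(K+x)`,
repression `I(x;K) = K/(K+x)`.  A candidate edge enters as the modifier
`M(x; action, K)`: `1 + beta*A(x;K)` if activatory, `1` if none, `I(x;K)`
if inhibitory.  The full equations are documented in `R/model.R` and in
`?build_model`.  Structural commitments:

* `MF` and `EG` are constitutive birth–death processes whose synthesis
  rates `ks_maff`, `ks_egr3` are the "expression level" axes swept in all
  analyses; their equilibria are exactly `ks/kd`.
* `E2F` is produced under Rb repression with autoactivation
  (`e0 + e_auto*A(E2F;K_ee)`), the core positive loop of the restriction
  point.
* `RB` is consumed by Michaelian phosphorylation proportional to
  `kp_cd*CD + kp_ce*CE`; together with E2F autoactivation this
  double-negative loop produces the bistability that the sweeps expose.
* `P18`/`P19` are E2F targets, are always up-regulated by Egr3 (base-model
  edges `g_eg18`, `g_eg19`, independent of the hypothesis tuple), and p18
  in particular loads the Cyc D\* degradation term (`alpha18`).
* p16, p21, p27, p53 and Akt are quasi-static pools, not ODEs: only
  p18/p19 have described dynamics and regulation in this system, so the
  remaining CKIs enter as constant degradation loads, with
  `P21 = P21_base*(1 + beta53*A(P53;K53))` (apoptosis coupling) and
  `P27 = P27_base*I(Akt;K_akt)` (survival coupling).  Whether the original
  analysis coupled p53/Akt dynamically is unstated; static is the minimal
  reading and is what we implement.

## The default parameter set and how it was calibrated

The literature-derived rate table behind the original model is not
available, so the package ships one frozen, versioned default set
(`default_parameters()`), produced by a guided calibration whose target was
*not* any numeric output but the qualitative criteria themselves, evaluated
for the accepted code "2111".  The structural reasoning, which the
calibration made quantitative:

* **ON state within reach of the OFF state.**  `ks_rb` is the Rb synthesis
  flux that cyclin-driven phosphorylation must beat; the baseline cyclin
  flux exceeds it by ~2.5x, placing the ON state a finite distance from the
  saddle-node so that Egr3 repression can fold it away within the swept
  range while ordinary perturbations cannot.
* **E2F readout sensitivity.**  `K_rb_e2f` is small relative to resting
  Rb, and E2F sits mid-slope of its autoactivation (`K_ee` = 2), so the
  modest Rb decrease produced by Maff-driven Cyc D\* relief is amplified
  into the >= 1.5-fold E2F rise that criterion C1 demands.
* **Cyc E\* saturated in E2F** (`K_ece` = 0.05): its synthesis is nearly
  E2F-independent on the ON branch, so only a *direct* inhibitory edge can
  suppress it — this is what makes "Egr3 -| Cdk2(:CyclinE)" necessary
  rather than an indirect consequence of switch shut-off.
* **Cyc D\* basal floor** (`GF` = 0.12): growth signalling keeps Cyc D\*
  synthesis above ~15% of baseline even with E2F off, so indirect routes
  cannot push it below the 10% suppression threshold — making
  "Egr3 -| Cdk4/6(:CyclinD)" necessary.
* **p18 leverage** (`alpha18` = 15, `K_mf_p18` = 4): p18 carries most of
  the Cyc D\* degradation load, so Maff's repression of p18 yields the
  >= 1.5-fold Cyc D\* rise of C1, while Egr3's p18 induction (`g_eg18` = 8)
  still dominates at dual overexpression, keeping the p18 surrogate *up*
  (criterion C3) despite Maff pulling it down.

Units: moles/cell, minutes, moles/cell/min.  Degradation rates near
0.05/min (half-life ~14 min) put transients on the hours scale and
steady states within the default 5000-min horizon.  With this set, the
exhaustive screen passes exactly codes "2111" and "3111" — the three
inhibitory edges plus an optional Maff -> Cdk2 activation — which is the
minimal-mechanism outcome the screen is designed to detect; the acceptance
suite recomputes this rather than assuming it.

## Numerics

* **Integration.**  The system is stiff (Rb collapse near the fold).  The
  bundled integrator (`src/model.cpp`) is an adaptive variable-step
  BDF(1,2): implicit steps solved by Newton iteration with the analytic
  Jacobian, local error estimated against the predictor, step size adapted
  with the usual 0.9 safety factor.  Defaults `rtol = 1e-6`, `atol = 1e-9`,
  horizon 5000 min; a trajectory is "settled" when the state moves less
  than `1e-6` (relative) over the last 10% of the horizon.  Inside Hill
  terms the state is clamped at zero so solver under-shoot cannot cross a
  pole; linear decay uses the raw value so negativity self-corrects.
* **Equilibria.**  `find_equilibrium()` is a damped Newton iteration
  (Armijo backtracking on |f|^2, Levenberg fallback on singular Jacobians,
  states clipped to the non-negative orthant), tolerance
  `1e-8 * max(synthesis rates)`, at most 50 iterations.  Stability follows
  the Lyapunov linearisation rule on the Jacobian eigenvalues with a
  `1e-9` real-part band; the boundary is labelled `"marginal"`.
* **Multi-start protocol.**  `find_all_equilibria()` seeds `n_starts`
  (default 8) initial states log-spaced across low/high E2F-Cyc E\*
  regimes (with Rb complements and lognormal jitter under a fixed seed),
  integrates each to settling, refines by Newton, then additionally runs
  Newton from the unsettled starts and from points between distinct
  attractors — settling alone finds only attractors, and the saddle
  between the ON and OFF branches is wanted for the departure tests.
  Duplicates collapse at relative distance `1e-4`.
* **Sweeps.**  Multi-start per grid point (default 60 log-spaced points
  over [1e-3, 0.5] moles/cell/min) instead of numerical continuation: the
  original analysis describes time-course plus root refinement, and the
  seeded multi-start is simpler and reproducible.  Bistable intervals are
  maximal grid runs carrying >= 2 stable equilibria; per-point failures
  become flagged gaps, not aborts.

## The screen

Criteria (thresholds in `screen_criteria()`):

* **C1** (proliferation, Maff sweep at `ks_egr3 = low`): stable-branch
  Cyc D\* and E2F at the grid maximum must exceed `fold_up_min` (1.5)
  times their grid-minimum values, and Cyc E\* must stay at or above
  `ce_floor_frac` (0.5) of baseline throughout.
* **C2** (G0 arrest, Egr3 sweep at `ks_maff = low`): every stable
  equilibrium at the grid maximum must have Cyc D\*, Cyc E\* and E2F at or
  below `suppress_frac` (0.1) of baseline, and the sweep must contain a
  bistable interval whose stable branches separate more than 2-fold in
  E2F or Cyc E\*.
* **C3** (expression profile under dual overexpression): starting from the
  baseline state, the system is settled under `ks_maff = ks_egr3 = high`
  and the synthesis-rate surrogates (the synthesis term of each ODE at
  equilibrium, a proxy for transcription activity) are compared with a
  sign profile; a ratio beyond `flat_band` (1.2) counts as a direction.

"Low" and "high" are frozen to the sweep-grid endpoints (1e-3 and 0.5
moles/cell/min); "medium" Egr3 is defined relative to the detected
bistable interval (the tests use its geometric midpoint).  The dual-high
profile directions for Cyc D\*/Cyc E\*/E2F are not printed in the source
figures; we default them to *down* (with p18/p19 *up* and G0 fraction
*up*), reasoning from the reported predominance (>90%) of G0 cells under
dual overexpression.  The profile is configurable, and the screen consumes
only signs, so the lognormal fold-change noise of the synthetic reference
profiles exercises robustness, not correctness.

Criteria are encoded as qualitative 0/1 agreements per hypothesis — the
same scheme as the original exhaustive table — and `necessary_edges()`
takes the signed intersection of non-`none` edges over all passing codes:
the minimum mechanistic inference supported by the data.

## Motif scanning conventions

Exact matching only ("all nucleotides must be matched"); `N` never
matches.  The window is the half-open `[TSS - 2000, TSS)` interval; the
reported upstream offset is measured from the TSS to the motif base
*nearest* it (>= 1) — the source reports offsets like "156 bp upstream"
without fixing start-vs-end, so nearest-base is the package convention and
`offset_from = "start"` switches to the 5'-most base.  Both strands are
scanned by default; the maf recognition element's long variant
(`TGCTGACGTCAGCA`) is its own reverse complement, so palindromic
double-reports collapse to a single plus-strand hit.  Minus-strand records
are reverse-complemented on load so "upstream" is always leftward.

## What the synthetic data does and does not establish

`generate_promoter()` plants motif variants (optional bases present) at
exact offsets in an i.i.d. background of requested GC content,
rejection-resampling until no unplanted occurrence of any planted variant
survives in the window.  The background has no dinucleotide structure, CpG
islands, or repeats: sufficient for exact-match scanning (where only
presence/absence at known positions matters), but a green planted-motif
test says nothing about scanning real genomes with ambiguity codes or
annotation-version drift — reproducing the published 156 bp (Prdm1) and
523 bp (Anapc11) offsets against live records is explicitly out of scope.
Likewise `generate_reference_profile()` provides sign patterns with
lognormal fold noise standing in for qRT-PCR and flow-cytometry readouts;
it emulates their *roles* in the screen, not their measurement models.

## Known limitations

* The ODE system is a qualitative-equivalent reconstruction constrained by
  the published statements (first-order Hill terms, readouts, p18/p19
  regulation, bistability), not the original supplementary equations, and
  the default parameters are a calibrated stand-in for the original
  literature-derived table.  Conclusions are therefore structural
  (which edge signs can reproduce the phenomena), not kinetic.
* At the frozen defaults the OFF state coexists with the ON state from the
  low end of the Egr3 grid (the bistable interval abuts the grid minimum);
  the baseline used by the criteria is always the upper (proliferative)
  branch.
* Multi-start equilibrium search has no completeness guarantee; it is
  cross-checked in the tests against an independent 1-D nullcline-scan
  oracle that exploits the model's structure (every species is an explicit
  function of E2F at steady state, except Rb which is a scalar root).
* No S/G2/M phases, division bookkeeping, stochastic simulation, Hopf
  detection, or two-parameter bifurcation analysis.
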