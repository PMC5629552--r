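# cycleswitch

Kinetic modelling and regulatory-hypothesis screening of the G0/G1 → S
cell-cycle switch.

## What this is for

Hematopoietic stem cells commit to the cell cycle at an E2F-governed
restriction point: active CyclinD:Cdk4/6 (Cyc D\*) and CyclinE:Cdk2
(Cyc E\*) phosphorylate Rb, freeing E2F, whose autoactivation makes the
commitment bistable.  The transcription factors **Maff** and **Egr3** are
strongly induced in leukemic HSCs and respectively accelerate and arrest
the cycle, but their molecular entry points into the switch are uncertain.
`cycleswitch` is for systems biologists who want to

1. simulate an 8-species ODE model of the switch (Maff, Egr3, Cyc D\*,
   Cyc E\*, E2F, Rb, p18, p19; first-order Hill regulation; p16/p21/p27,
   p53 and Akt as quasi-static pools) with pluggable Maff/Egr3 edges;
2. enumerate all 3⁴ = 81 sign combinations of the four candidate edges
   (Maff→Cdk2, Maff→p18, Egr3→Cdk2, Egr3→Cdk4/6; digit code
   1 = inhibitory, 2 = none, 3 = activatory) and screen them against
   qualitative experimental criteria — recovering the *necessary edge set*,
   the minimum mechanism consistent with the data;
3. trace steady-state branches against expression level, classify
   stability from Jacobian eigenvalues, and detect bistable intervals
   (saddle-node folds);
4. scan promoter windows for exact transcription-factor elements — the maf
   recognition element `TGCTGAC(G)TCAGCA` (MARE, palindromic) and the Egr3
   cis element `CGCCCCCGC` — with strand handling and TSS-relative offsets;
5. generate deterministic synthetic fixtures (planted-motif promoters,
   qualitative reference profiles) so the whole pipeline runs without
   downloads.

The model at its core, for species `X` with synthesis `S_X` and decay
`kd_X`:

    dX/dt = S_X(state; edges) − kd_X·X,      A(x;K) = x/(K+x),  I(x;K) = K/(K+x)

e.g. `S_E2F = ks_e2f·[e0 + e_auto·A(E2F;K_ee)]·I(RB;K_rb_e2f)` and
`dRB/dt = ks_rb − (kp_cd·CD + kp_ce·CE)·A(RB;K_prb) − kd_rb·RB`.  A
candidate edge multiplies its target's synthesis by `1 + β·A(x;K)`
(activatory), `1` (none) or `I(x;K)` (inhibitory).  Stiff trajectories are
integrated with a bundled adaptive BDF(1,2) scheme; equilibria are refined
by damped Newton iteration and classified by the Lyapunov rule.  See the
methods vignette (`vignettes/cycleswitch-methods.Rmd`) for assumptions,
parameter provenance and numerical choices.

## Worked example

```r
library(cycleswitch)

m <- build_model(default_parameters(), "2111")   # the accepted hypothesis
m
#> <cc_model> G0/G1->S switch, regulatory code 2111
#>   effective pools: P21 = 0.5833, P27 = 0.1667 moles/cell

find_all_equilibria(m)   # baseline: proliferative ON state, quiescent OFF
                         # state, and the saddle between them
#> [[1]] <cc_equilibrium> stable (residual 2.5e-09)
#>       MF       EG       CD       CE      E2F       RB      P18      P19
#> 0.020000 0.020000 0.060097 0.171160 0.816860 0.120770 1.466500 1.419800
#> [[2]] <cc_equilibrium> unstable (residual 1.18e-10)
#>  ... E2F 0.053862 ...
#> [[3]] <cc_equilibrium> stable (residual 3.33e-15)
#>  ... E2F 0.0084945 ...

sweep_parameter(m, "ks_egr3", default_grid(20), n_starts = 6)
#> <cc_sweep> ks_egr3 over 20 points [0.001, 0.5]
#>   bistable interval: [0.001, 0.005132]
```

The ON state carries E2F ≈ 0.82 moles/cell; raising Egr3 expression folds
it away through a bistable interval, after which only the quiescent state
(E2F ≈ 0.008, ~1% of baseline) survives — the G0-arrest phenotype.  The
screen and the scanner:

```r
scr <- run_screen(default_parameters(), screen_criteria(grid_n = 20, n_starts = 6))
scr$table$code[scr$table$pass]
#> [1] "2111" "3111"
necessary_edges(scr)
#>                  edge     action
#> 1           Maff->p18 inhibitory
#> 2   Egr3->Cdk2(:CycE) inhibitory
#> 3 Egr3->Cdk4/6(:CycD) inhibitory

fix <- make_screen_fixture("fixture_dir", seed = 1)
scan_promoter(read_promoters(fix$fasta, fix$tss)$Prdm1_synthetic, cc_motifs()$MARE)
#>                id motif        variant strand upstream_offset abs_start
#> 1 Prdm1_synthetic  MARE TGCTGACGTCAGCA      +             156      2231
```

Every passing code keeps the three inhibitory edges (Maff⊣p18,
Egr3⊣Cdk2:CycE, Egr3⊣Cdk4/6:CycD) — the necessary set — while the
Maff→Cdk2 digit is free (none or activatory).  The planted-motif hit shows
the offset convention: distance from the TSS to the motif base nearest it.

A command-line launcher is installed at `inst/cli/cycleswitch`
(`screen`, `scan`, `synth`, `fixture` subcommands).

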