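# nanobridge

Quantitative tools for **nanoscale intercellular membrane bridges** — the
tunnelling-nanotube-like conduits (~290 nm wide, ~30 μm long) that metastatic
cancer cells extend to endothelial cells and use to transfer cytoplasmic
cargo and microRNA. The package is aimed at cell biophysicists and
quantitative cell biologists who need to (i) reason mechanically about which
bridge geometries are possible, and (ii) quantify bridge morphometry,
dye-transfer cytometry and qPCR fold changes with the study-standard
statistics, with seeded simulators for end-to-end validation of every
pipeline.

## The model at the core

A bridge is an Euler column supported by a mixed bundle of `n_a` actin
filaments and `n_t` microtubules:

- additive flexural rigidity `B = k_B T (n_a L_p,a + n_t L_p,t)`;
- buckling force `F_b = I B / L²` (clamped-free prefactor `I = π²/4` by
  default), hence a maximum sustainable length `L_max = √(I B / F)` at
  working load `F`;
- hexagonal packing diameter `D_min = 2 √((n_a r_a² + n_t r_t²)/φ)`,
  `φ = 0.9069`.

Because a microtubule is vastly stiffer than an actin filament
(`ρ = L_p,t / L_p,a`) but 4× thicker (`q = (r_t/r_a)² = 16`), the flexural
performance `P(f) = L_max / D_min²` over the tubulin number fraction `f` has
an interior optimum with closed form `f* = 1/(q−1) − 2/(ρ−1)` — about **6.6%
tubulin** in the stiff-microtubule regime. The package computes feasibility
curves (max length vs minimum diameter per composition), classifies observed
geometries as feasible/infeasible per composition, and locates the optimum
both in closed form and by numerical search.

Around the mechanics sit four measurement pipelines: projection morphometry
(summaries, nanobridge/lamellipodium classification, connection statistics,
kinetics peak windows, ANOVA + Bonferroni group comparison), gated
flow-cytometry transfer quantification with background subtraction, ΔΔCt
microRNA fold-change quantification, and seeded synthetic-data generators
for all of the above.

## Worked example

```r
library(nanobridge)

m <- bundle_model()   # literature-standard constants; all configurable
m
#> Composite filament-bundle buckling model
#>   actin    r =    3.5 nm, L_p = 1.77e+04 nm
#>   tubulin  r =   14.0 nm, L_p = 5.2e+06 nm
#>   kT = 4.28 pN nm, load F = 10 pN, phi = 0.9069, I = 2.4674

# How long can an actin-only bridge of the observed 290 nm width be?
b <- max_filaments_for_diameter(m, 290, tubulin_fraction = 0)
b$n_actin                                   # 1556 filaments fit
buckling_length(m, b$n_actin, 0)            # 5393 nm
classify_feasibility(m, length_nm = 30690, diameter_nm = 290,
                     tubulin_fraction = 0)
#> [1] "infeasible"
```

An actin-only bundle filling the observed width buckles beyond ~5.4 μm, so
the observed 30.7 μm mean length is infeasible without microtubules — and the
composition that best trades stiffness against thickness is

```r
optimal_tubulin_fraction(lp_ratio = 3000, radius_ratio_sq = 16)$fraction
#> [1] 0.06599978   # 6.6% tubulin
```

The transfer pipeline, run on a simulated co-culture whose true transfer
fraction is 30% with a 3% cargo background (thresholds from an unstained
control, background measured on a cargo-free control):

```r
uns <- gen_facs_events("unstained",  0, 0,    0.5, n_events = 50000, seed = 101)
ctl <- gen_facs_events("control",    0, 0.03, 0.5, n_events = 50000, seed = 102)
co  <- gen_facs_events("co_culture", 0.30, 0.03, 0.5, n_events = 50000, seed = 103)
g <- derive_gate(uns)
percent_positive(gate_endothelial(co, g), gate_endothelial(ctl, g), g)
#> cfse+ among 24933 gated events: raw 33.51%, background 3.65%
#> corrected 29.86% (95% CI 29.23-30.49)
```

The corrected 29.9% recovers the 30% generator truth: raw positivity (33.5%)
minus the background measured on the cargo-free control (3.7%). Finally, ΔΔCt
quantification of a synthetic Ct table embedding a 5× increase and a 26×
decrease (Ct noise s.d. 0.1, triplicates):

```r
ct <- gen_ct_table(c(recipient = 5, antagomir = 1/26, control_mirna = 1),
                   noise_sd = 0.1, replicates = 3, seed = 104)
delta_delta_ct_fold_change(ct, "control_mirna")
#> 2^(-ddCt) fold changes vs calibrator 'control_mirna':
#>      condition delta_ct delta_delta_ct fold_change fold_lower fold_upper
#>      recipient    1.673         -2.358     5.12513     4.4766    5.86766
#>      antagomir    8.762          4.731     0.03765     0.0326    0.04348
#>  control_mirna    4.031          0.000     1.00000     0.8906    1.12288
```

The recipient condition recovers ~5× up; the antagomir condition ~26× down
(1/0.03765 ≈ 26.6).

See `vignettes/nanobridge-methods.Rmd` for the full account of the models,
defaults and design decisions.

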