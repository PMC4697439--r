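---
title: "Models and methods behind nanobridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanobridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobridge)
```

nanobridge is a quantitative toolkit for nanoscale intercellular membrane
bridges — tunnelling-nanotube-like conduits, a few hundred nanometres wide and
tens of micrometres long, through which metastatic cancer cells transfer
cytoplasmic cargo and microRNA to endothelial cells. It has four analysis
layers (mechanics, morphometry, transfer quantification, expression
quantification) and a set of seeded generators that simulate the measurement
tables those layers consume, so every pipeline can be exercised end-to-end
against known ground truth. This vignette explains the models, the defaults
and the design decisions.

## The composite-bundle buckling model

A membrane projection is modelled as a slender elastic column supported by a
bundle of `n_a` actin filaments and `n_t` microtubules. Three standard
ingredients are combined:

1. **Rigidity.** Each filament contributes a flexural rigidity
   $B_i = k_BT\,L_{p,i}$, where $L_{p,i}$ is its persistence length. The
   bundle is treated as uncoupled (filaments bend independently), so
   rigidities add:
   $$B = k_BT\,(n_a L_{p,a} + n_t L_{p,t}).$$
   Whether such bundles behave as uncoupled ($B \propto N$) or fully
   cross-linked ($B \propto N^2$) is unsettled in general; the constructor
   exposes a `coupling_exponent` (default 1, uncoupled) so the cross-linked
   variant is one argument away.

2. **Euler buckling.** A column of length $L$ under axial load buckles at
   $F_b = I\,B/L^2$. The boundary-condition prefactor $I$ defaults to
   $\pi^2/4$ (clamped at the cell body, free at the tip — the usual filopodial
   idealization) and is configurable across the admissible range
   $[\pi^2/4,\,4\pi^2]$. Inverting at a working load $F$ gives the longest
   projection that can exist without buckling,
   $L_{\max} = \sqrt{I\,B/F}$.

3. **Packing.** Filaments of radius $r_i$ packed hexagonally (areal fraction
   $\varphi = 0.9069$) require a circumscribing diameter
   $D_{\min} = 2\sqrt{(n_a r_a^2 + n_t r_t^2)/\varphi}$. The same formula is
   used down to a single filament for continuity, at the cost of a slight
   $>2r$ artefact there.

Default constants: $k_BT = 4.28$ pN·nm (310 K), $r_a = 3.5$ nm,
$r_t = 14$ nm (the 4× microtubule/actin radius ratio), $L_{p,a} = 17.7$ μm,
$L_{p,t} = 5.2$ mm, working load $F = 10$ pN — literature-standard filopodial
values. All are constructor arguments of `bundle_model()`, so an alternative
parameterization is a one-line change, and every result object records the
constants it was computed with.

With the defaults, an actin-only bundle filling the observed mean bridge
width of 290 nm (1,556 filaments) sustains at most

```{r}
m <- bundle_model()
b <- max_filaments_for_diameter(m, 290, tubulin_fraction = 0)
buckling_length(m, b$n_actin, b$n_tubulin)
```

about 5.4 μm — far short of the observed 30.7 μm mean length, so the observed
geometry is classified infeasible for actin alone:

```{r}
classify_feasibility(m, length_nm = 30690, diameter_nm = 290,
                     tubulin_fraction = 0)
```

This is the model's central qualitative conclusion: bridges of the observed
aspect must recruit microtubules.

### The optimal tubulin fraction

Microtubules are ~300–3,000× stiffer than actin per filament but cost
$q = (r_t/r_a)^2 = 16$ times the cross-sectional area, so there is a trade-off
between flexural strength and thickness. We operationalize "maximize strength
while minimizing thickness" as maximizing
$$P(f) = \frac{L_{\max}(f)}{D_{\min}(f)^2}$$
over the tubulin *number* fraction $f$ at fixed total filament count. On the
continuous relaxation $P(f) \propto \sqrt{1+f(\rho-1)}/(1+f(q-1))$ with
$\rho = L_{p,t}/L_{p,a}$, and the maximizer has the closed form
$$f^\* = \frac{1}{q-1} - \frac{2}{\rho-1},$$
valid when $\rho > 2q-1$ (otherwise the optimum sits at the actin-only
boundary, which `optimal_tubulin_fraction()` flags). In the stiff-microtubule
regime the optimum approaches $1/(q-1) = 1/15 \approx 6.7\%$; at
$\rho = 3000$ it is exactly

```{r}
optimal_tubulin_fraction(lp_ratio = 3000, radius_ratio_sq = 16)$fraction
```

i.e. 6.6%. Among the candidate metrics we examined (maximizing $L_{\max}$ at
fixed $D_{\min}$, rigidity fractions, area fractions), $P(f)$ over the number
fraction is the one consistent with both the 4× radius ratio and a ~6.6%
optimum; it is implemented with both the closed form and an independent 1-D
numerical maximization, which agree to $10^{-6}$.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* of the study's
measurement tables, with published summary values as generator truths, under
mandatory seeds (each generator restores the caller's RNG state, so there is
no hidden global randomness).

* **Projection dimensions** (`gen_morphometry()`): published summaries are
  mean ± s.e.m. with $n$ reported, so the population s.d. is
  $\mathrm{sem}\times\sqrt{n}$. For the bridge short axis (290 ± 20 nm,
  $n = 300$) that implies a coefficient of variation above 1, which rules out
  a normal distribution on positive lengths; a lognormal matched by moments
  ($\mu_{\log} \approx 5.227$, $\sigma_{\log} \approx 0.941$) is used
  instead, with a truncated-normal alternative available.
* **Growth kinetics** (`gen_kinetics()`): a logistic rise reaching ~97.5% of
  plateau at `t_peak_h`, followed by a slow exponential relaxation (default
  0.05 h⁻¹). A pure rise-then-plateau would make the "peak window" extend to
  the last observation; the relaxation makes the peak a genuine interior
  window, matching the reported peak *between* 15 and 20 h. Defaults (rate
  0.6 h⁻¹, relaxation 0.05 h⁻¹) put the noiseless smoothed ≥95% window at
  16–19 h.
* **Cytometry events** (`gen_facs_events()`): lognormal intensity mixtures
  over three channels (DiI-Ac-LDL, PECAM-1, CFSE) with 30× median separation
  between negative and positive populations (well above the 10× sanity bound,
  below which the generator sets a warning attribute). Endothelial events are
  dual-positive for the two markers; a `true_transfer_fraction` of them are
  cargo-positive and an additional `background_rate` (default 3% in every
  condition — the study reports only that background was subtracted, not its
  size) are spuriously cargo-positive. Cancer events are cargo-loaded. Ground
  truth labels ride along for oracle tests. No compensation/spillover, doublet
  or scatter modelling: channels are generated independent.
* **Composition labels** (`gen_composition_labels()`): Bernoulli draws at the
  published ~70% dual actin+tubulin rate.
* **Ct tables** (`gen_ct_table()`): the target-gene Ct is shifted by
  $-\log_2(\text{fold})$ per condition with Gaussian replicate noise; the
  reference gene is flat. A noiseless table therefore round-trips exactly
  through the ΔΔCt pipeline.

Passing recovery tests on these populations shows the pipelines are unbiased
and correctly calibrated *for data with this structure*. Real data add what
the generators deliberately omit: instrument-specific intensity artefacts,
spectral spillover, non-lognormal tails, cell-cycle and batch structure, and
amplification-efficiency deviations from 2. Recovery on synthetic data is a
necessary check, not a validation on real measurements.

## Morphometry and statistics

* `summarize_dimensions()` reports mean, s.d. ($n-1$ denominator; the study
  does not state its convention) and s.e.m. per group.
* `classify_projection_kind()` separates nanoscale bridges from lamellipodia
  by width < 1 μm AND aspect ratio ≥ 10 — thresholds placed between the two
  published population means (bridges 290 nm × 30.7 μm, aspect ~106;
  lamellipodia 4.99 μm × 12.9 μm, aspect ~2.6), both configurable. The rule is
  invariant to joint unit rescaling. On the published (heavy-tailed)
  populations themselves the two classes overlap slightly; perfect separation
  is only expected — and tested — for well-separated populations.
* `kinetics_peak()` smooths with a centred moving average (window 3) and
  reports the window of timepoints within 5% of the peak. The 5% is measured
  relative to the smoothed *range*, not the raw maximum, which makes the
  window invariant to adding a constant to all means; an all-equal series
  returns the full range with a `flat` flag.
* `compare_groups()` is the study's stated statistic — one-way ANOVA followed
  by Bonferroni-adjusted pooled-SD pairwise t tests
  ($p_{\text{adj}} = \min(1, m\,p_{\text{raw}})$ over the $m$ pairs) — built
  on `stats::aov()` and `stats::pairwise.t.test()`. Classic (non-Welch) tests
  by default, matching the stated method. Zero variance in every group is a
  degenerate-input error.

## Transfer quantification

Gating follows conventional cytometry practice. Intensities are transformed
as $\operatorname{asinh}(x/150)$; thresholds sit at the 99.5th percentile of
an *unstained* control per channel (`derive_gate()`), both cofactor and
percentile configurable. Endothelial events are those above threshold in both
DiI and PECAM channels. The cargo-positive percentage is measured on the
gated set; the background percentage is measured *identically* on the gated
cargo-free stained control; and the corrected value is the clipped
percentage-point difference $\max(0,\text{raw}-\text{background})$. The
corrected percentage therefore can never be negative nor exceed the raw one.
Standard errors and confidence intervals use the normal approximation from
the two binomial proportions (chosen over the bootstrap for determinism and
speed; at the default 25,000 gated events the normal approximation is
excellent, and its ~93–95% empirical coverage is verified in the test suite).
`conduit_attributable_transfer()` differences two corrected results —
co-culture minus contact-free Boyden baseline — to isolate the
conduit-mediated component from basal exosome/gap-junction transfer.

## Expression quantification

`delta_delta_ct_fold_change()` implements the standard $2^{-\Delta\Delta
C_t}$ method with amplification efficiency fixed at 2 (not estimated — the
package takes Ct values as given and does no amplification-curve fitting).
Replicates aggregate by arithmetic mean of Ct; confidence intervals are
propagated on the $\Delta\Delta C_t$ scale from replicate standard deviations
and then exponentiated, so they are asymmetric on the fold scale. Single
replicates yield flagged point estimates. Folds are
multiplicative-inverse symmetric in condition and calibrator. At the
simulated bench conditions (Ct noise s.d. 0.1 cycles, triplicates) the
recovered fold has a relative s.d. of ~8%, so roughly 94% of simulated
experiments land within 15% of truth — the calibration the test suite
verifies. `marker_mfi_summary()` summarizes downstream marker intensities
(CD137, CD276, p120RasGAP, pAkt) by median (robust to lognormal tails) with
means alongside, delegates inference to `compare_groups()` and reports the
direction of the recipient vs non-recipient contrast.

## Numerical choices and degenerate inputs

* Packing inversion (`max_filaments_for_diameter()`) floors counts to
  integers, resolves composition-rounding ties toward fewer microtubules
  (conservative: fewer thick filaments), and errors on diameters below a
  single filament's packed footprint.
* The closed-form optimum is cross-checked against `stats::optimize()` at
  tolerance $10^{-10}$ and against a $10^{-5}$ brute-force grid.
* Buckling force/length round-trip to $10^{-9}$ relative over random bundles.
* Zero-filament bundles, non-positive lengths/loads/folds, missing channels,
  missing calibrators and empty gated sets raise immediate, specific errors.

## Problem sizes

Simulation sizes used throughout the tests and the reproduction script were
chosen to make Monte-Carlo error small relative to every tolerance while
keeping a full run in seconds on a laptop: 10,000 projections or labels for
population recovery, 50,000 events per cytometry condition (≈25,000 gated),
100 replicate scenarios for coverage calibration, and 200 seeded qPCR
simulations for the fold-recovery rate.

## Known limitations

* Statics only: no polymerization dynamics, membrane tension beyond the
  single load-force parameter, or post-Euler mechanics.
* The uncoupled-rigidity default and the $P(f)$ metric are reconstructions of
  a standard filopodial framework; both are configurable, and conclusions that
  depend on them (the 6.6% optimum, the actin-only infeasibility) should be
  read within that framework.
* The cytometry model omits spillover and autofluorescence structure; the
  background is a single condition-independent rate.
* ΔΔCt assumes perfect doubling per cycle and a stable reference gene.
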