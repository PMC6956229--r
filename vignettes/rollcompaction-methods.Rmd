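---
title: "Models and methods behind rollcompactr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rollcompactr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollcompactr)
```

This vignette explains the science the package implements, the choices
made where the design was genuinely open, and what the synthetic
material library does and does not emulate.

## The problem

Roll compaction (dry granulation) densifies a powder between rollers
into a ribbon whose **solid fraction** (SF = 1 − ε) and **tensile
strength** (TS) largely determine downstream granule and tablet
quality. A widely used target is 0.6 ≤ SF ≤ 0.8 together with
TS ≥ 1 MPa: dense enough to mill, not so dense that tabletability is
lost. The package takes a *material library* — many single materials,
each compacted over a pressure grid — and asks which raw-material
attributes drive ribbon quality and which materials can reach the
target at all.

## Powder descriptors

Twenty-two descriptors per material follow the SeDeM characterisation
conventions. The computed ones are simple ratios of raw instrument
readings: Da = m/Va, Dc = m/Vc, Ie = (Dc−Da)/(Dc·Da),
IC = 100·(Dc−Da)/Dc, IH = Dc/Da, AOR = atan(2h/r),
%H = 100·(m₃−m₂)/(m₂−m₁), Dt = m/(V₁−V₂), SFp = Da/Dt, εp = 1 − SFp,
span = (D90−D10)/D50. Directly measured quantities (flow time,
moisture, tablet hardness Icd, texture metrics Co/Sp/Sp-co) are
validated and passed through, never recomputed
(`descriptor_provenance()` records which is which).

Open points resolved here:

* **Fines fraction %Pf** is obtained by linear interpolation of the
  cumulative undersize curve on the histogram bin edges at 50 µm. This
  is instrument-agnostic and deterministic.
* **Homogeneity index Iθ** uses the SeDeM form
  Iθ = F_m / (100 + Σₙ (d_{m+n} − d_m)F_{m+n} + (d_m − d_{m−n})F_{m−n})
  with d the bin mean diameter in µm and F in percent; a single
  occupied bin gives the limit Iθ = 1, and spreading mass to farther
  bins strictly lowers the index. Ties for the majority bin resolve to
  the smaller-diameter bin so that one majority fraction is always
  reported.
* **Ie units**: the defining ratio carries mL/g dimensions although the
  index is used as dimensionless; the raw value is stored unmodified.
* Bulk density exceeding true density is physically inconsistent; such
  rows are flagged with a warning but not clamped, preserving the audit
  trail.
* Porosities and solid fractions are stored as fractions in [0, 1];
  percent forms appear only at I/O time.

## Ribbon metrology

Porosity comes from oil intrusion:
V_oil = (m_sat − m_ribbon)/ρ_oil, V_ribbon = m_ribbon/Dt,
ε = V_oil/(V_oil + V_ribbon) — invariant to the ribbon sample size.
Tensile strength comes from three-point bending, TS = 3FL/(2WT²) (MPa
with N and mm, support span 15 mm by default). Replicates aggregate by
arithmetic mean with the standard deviation kept as metadata. A ribbon
can split transversally (T) and longitudinally (L2/L3/LJ/LN) at the
same time; tallies count the two families independently, which is why
a frequency table's T and L rows may each approach the tangible sample
count.

## Compaction models and screening

The Ryshkewitch–Duckworth law TS = TS₀·exp(−k_b·ε) is fitted as an OLS
line of ln TS on ε, because the model is linear there and the fit
quality is judged on that scale; `r2` is therefore reported in log
space. TS₀ is the extrapolated zero-porosity strength and k_b the
bonding capacity. The power law TS = d·P^g is fitted in raw space by
Levenberg–Marquardt (minpack.lm), initialised from a log–log OLS line;
g > 1 gives a concave-up (accelerating) pressure profile, g < 1 a
saturating one, g = 1 a straight line through the origin.

A fit is **applicable** when it has at least 3 points, R² ≥ 0.7, and
physically sane coefficients. The TS₀ cap defaults to 1000 MPa: nearly
porosity-invariant data can extrapolate to absurd intercepts (hundreds
of thousands of MPa) that no pharmaceutical compact approaches.
Non-monotone TS sequences are flagged as metadata rather than rejected
outright — the R² screen already removes the pathological ones. Points
with missing or non-positive TS are excluded, never imputed.

## RCBCS classification

Category I: some pressure point has 0.6 ≤ SF ≤ 0.8 **and** TS ≥ 1 MPa.
Category II: no such point, but some point has SF > 0.8 with
TS ≥ 1 MPa. Category III: TS < 1 MPa everywhere (including materials
that form no ribbon or whose ribbons cannot be tested). Subcategory A
means the criterion is met somewhere in 30–70 bar, B only at
90–110 bar. All bounds are inclusive; I takes precedence over II when
both criteria hold at different pressures, and A over B. Missing TS at
a pressure counts as failing the strength criterion there.

## PLS modelling choices

Both blocks are autoscaled (mean 0, variance 1 per column) — the usual
chemometric convention. The PLS2 core is NIPALS with X-deflation;
weight-vector signs are fixed by making the first non-zero element
positive. Tolerance 1e-10, 500 iterations. When the inner power
iteration stalls — which happens for minor components whose residual
cross-covariance has nearly equal singular values, i.e. directions that
are statistically interchangeable — the component is accepted as-is and
flagged in `nipals_converged` rather than raising an error: the
extracted subspace, and hence every prediction, is stable even when the
split between such components is not, and aborting cross-validation on
unremarkable data would be worse than recording the stall.

Cross-validation uses 7 venetian-blind folds over a seed-shuffled row
order, so fold assignment is deterministic given the seed. Q²cum(A) is
1 − PRESS_A/SS with PRESS from A-component fold-wise predictions and SS
the total sum of squares of the centred response block. (This is the
cumulative-PRESS definition; the per-component product rule some
software uses differs slightly.) The component count is the smallest A
whose Q² gain drops below 0.01, capped at 10; models feeding the
two-LV design-space map enforce a minimum of 2 components.

VIP_j = sqrt(p·Σ_a SSY_a w²_ja / Σ_a SSY_a); the mean of squared VIPs
is identically 1, so VIP > 1 marks above-average importance and is the
cut for the refined model. Score-plot limits: the Hotelling T² ellipse
from the F distribution for the plotted pair of components, and an
empirical Euclidean limit (95th percentile of score distances). Both
are offered because they answer different questions — the ellipse is a
parametric outlier bound per axis pair, the circle an empirical
envelope of the observed library; the design space uses the Euclidean
circle by default with Hotelling as an option.

## Design space

The refined model keeps the VIP > 1 predictors and refits. In the
(t₁, t₂) score plane the two-component prediction is affine, so
TS ≥ 1 MPa is a half-plane and 0.6 ≤ SF ≤ 0.8 a band; the design space
is their intersection with the confidence circle. The region is
reported twice: as a grid mask (default 201×201 spanning 1.2× the limit
radius — smooth rendering at negligible cost) and as an analytic
polygon obtained by clipping the circle with the constraint
half-planes; the two agree by construction and the tests verify it.
Because the plane uses only two of the model's components, projected
materials also carry full-component predictions for comparison; whether
the two-LV or full prediction should gate membership is genuinely
ambiguous, so both are exposed and the membership flag uses the two-LV
values that define the plotted region.

## The synthetic library

No per-material raw library is shipped, so a generator provides one
with the statistical structure the analysis assumes. Per material, two
latent factors (plasticity, packing) drive correlated descriptors
inside the measured envelopes (true density 1.145–2.915 g/mL, powder
porosity 0.4479–0.8456, cohesion index 0–503 N, springiness
0.1255–0.46, with one glucose-like Icd = 0 material always present).
Ribbon behaviour follows a saturating porosity–pressure law
ε(P) = ε∞ + (ε₀ − ε∞)·exp(−P/Pc) with ε₀ the powder porosity, and the
strength law TS(P) = TS₀·exp(−k_b·ε(P)) with TS₀ ∈ [0.8457, 144.8] MPa
and k_b ∈ [2.954, 32.28].

Category membership is imposed by construction: for each intended
(sub)category the law parameters are solved from the category
inequalities with safety margins (e.g. a IIB material crosses TS = 1
between 70 and 90 bar by choosing the strength pair on either side and
solving k_b from the porosity drop), then a bounded redraw handles the
rare draws whose implied coefficients leave the published envelopes.
Oil-intrusion masses and bending forces are back-computed so the
metrology recovers ε and TS exactly; replicate noise is multiplicative
lognormal on TS (σ = 0.05) and additive on ε (σ = 0.01) — small enough
that intended categories survive almost always at replicate-mean level,
large enough to exercise the screening code. Splitting modes are drawn
with transversal probability decreasing and longitudinal increasing in
pressure, lower transversal rates for Category I. Default sizes: 81
materials (IA 26, IB 3, IIA 26, IIB 15, III 11, two of the III
non-compactable) at 30–110 bar in 20 bar steps, three replicates.

What the generator does **not** emulate: real measurement error in the
descriptors, inter-descriptor relationships beyond the two latent
factors, deviations from the exponential porosity law, pressure-
dependent splitting correlated with strength, or named-material
idiosyncrasies. Passing tests therefore demonstrate correctness of the
computational chain and recoverability under the stated noise model,
not predictive validity on any particular real library.

The PLS fixture (`make_lvm_fixture()`) is simpler still: responses are
a known affine map of standardised predictors, with the pressure
coefficient (2.0) above the active descriptors (1.5–1.2) and eight
true-zero columns, so that pressure ranks first in VIP and the noise
columns fall below 1 with wide margins. The affine rescaling places TS
near 2.5 ± 3 MPa and SF near 0.70 ± 0.15 so that the quality targets
cut non-trivially through the score plane.

## Problem sizes and determinism

The default end-to-end run (81 × 5 × 3 observations, 27-variable PLS
with 7-fold CV, 201² design-space grid) completes in a few seconds on
one CPU; the test suite uses 20-material libraries for most module
tests, a 200-material library for parameter-recovery statistics, and
10⁴ random profiles for classifier fuzzing. Every random element —
library generation, CV fold shuffling, fixtures — flows from explicit
seeds, and two runs with the same seed are bit-identical (the pipeline
bundle is reproducible byte for byte).

## Known limitations

* Mixtures are out of scope: the oil-intrusion conversion uses the raw
  material's true density, valid for single materials only.
* The R–D and power fits use 5 pressure points per material; with so
  few points the applicability screen, not the standard errors, is the
  meaningful quality gate, and no confidence intervals are reported.
* Q² uses the cumulative-PRESS definition; numbers are comparable
  across models fitted here but not identical to software using the
  per-component product rule.
* The design-space region inherits the refined model's prediction
  error; membership of individual materials near the boundary should
  be read together with the full-component predictions.
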