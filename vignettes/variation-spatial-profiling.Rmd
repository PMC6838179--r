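---
title: "Variation spatial profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variation spatial profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsprofiler)
```

## The problem and the model

A disease gene typically harbours hundreds of missense variants, but
functional measurements exist for only a few dozen of them. Variation
spatial profiling treats those measured variants as sparse samples of a
smooth genotype-phenotype surface and interpolates the rest with the
machinery of geostatistics, exactly as a geologist interpolates ore grade
from sparse boreholes.

Each variant is a point in a two-dimensional plane. Its first coordinate
is the residue position normalized to the protein length, `x = position /
protein_length`, so x lies in (0, 1] for any protein. Its second
coordinate y is one functional measurement (for the NPC1 worked examples
in this package: a cholesterol-accumulation score, or the trafficking
index). The remaining measurement is the response z to be interpolated.
Swapping which measurement plays y and which plays z re-analyses the same
panel in the orthogonal orientation; `vsp_config(y_col =, z_col =)`
exposes exactly that switch.

**Molecular variogram.** For every unordered pair of variants we compute
the separation

$$h_{ij} = \sqrt{(x_i - x_j)^2 + (y_i - y_j)^2}$$

and the semivariance

$$\gamma_{ij} = \tfrac{1}{2}(z_i - z_j)^2 .$$

Averaging the semivariances in uniform distance bins gives the empirical
variogram; a parametric curve fitted to the bin means summarizes how
fast functional similarity decays with distance. Three parameters matter:

* **nugget** `c0` — micro-scale/measurement variance, the semivariance as
  h approaches 0 from above (dimensionless, on the z² scale; default fit
  lower bound 0);
* **sill** (plateau) `c0 + c` — the total variance of the process, read
  biologically as the stringency of the fold;
* **range** `a` — the distance at which the curve flattens; variants
  closer than the range carry information about each other.

Four standard families are implemented (spherical, linear with sill,
exponential, gaussian). The spherical family is the default; on fields
simulated from a spherical model it also wins the leave-one-out
comparison run by `compare_variogram_families()`. The exponential and
gaussian curves use the effective-range convention (factor 3 in the
exponent) so their fitted `a` is comparable to the spherical range.

**Ordinary Kriging.** The spatial covariance implied by the fitted
variogram, `C(h) = C(0) − γ(h)` with `C(0)` the sill, feeds the ordinary
Kriging equations. For a target u with k neighbors, the weights ω and
Lagrange multiplier μ solve

$$\begin{pmatrix} C & \mathbf{1} \\ \mathbf{1}^\top & 0 \end{pmatrix}
\begin{pmatrix} \omega \\ \mu \end{pmatrix} =
\begin{pmatrix} c_u \\ 1 \end{pmatrix},$$

giving the best linear unbiased prediction `z*_u = Σ ω_i z_i` (the
constraint Σω = 1 guarantees unbiasedness) and the Kriging variance
`σ²_u = C(0) − (Σ ω_i C_{i,u} + μ)`, the model-based confidence of each
prediction. Evaluating both on a dense grid yields the phenotype
landscape; thresholding σ² at an empirical quantile draws the
confidence contours; subtracting two landscapes of the same variants
under two treatments yields the delta-landscape of a drug response.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_bins` | 12 | bins | uniform lag bins; enough resolution for ~1 000 pairs without empty bins |
| `active_lag` | max pair distance / 2 | distance | standard geostatistics practice; long lags are pair-poor and unstable |
| `min_n` / `max_n` | 5 / 20 | neighbors | published neighborhood practice is a minimum of 5 and a maximum of about 19–25; one fixed default keeps runs reproducible |
| `search_radius` | variogram range | distance | beyond the range observations are uncorrelated with the target; the `min_n` floor overrides the radius when the neighborhood is too empty |
| `grid_res` | 100 | cells/axis | resolves a ~1 300-residue protein to ~13 residues per column; raise it for finer structure maps |
| `confidence_q` | 0.25 | fraction | "top 25% confidence" quartile contour |
| `cv_repeats` | 5 | repeats | k-fold partitions are re-drawn five times and r/p averaged |

## Numerical choices

* **γ(0) ≡ 0.** The model evaluates to exactly zero at h = 0 while the
  nugget applies at any h > 0. This makes Kriging an exact interpolator:
  at an observed variant (with zero nugget) the landscape reproduces the
  measurement with zero variance.
* **Duplicate coordinates.** Two variants at identical (x, y) make the
  covariance matrix singular. Loading reports duplicates (both labels);
  matrix assembly jitters the second member by +1e−9 in x. Reports and
  tables always show original coordinates.
* **Variogram fitting** is deterministic: a fixed 10×10×10 multi-start
  grid spanning the empirical γ scale and lag span, then bounded
  Levenberg–Marquardt refinement from the five best starts; ties resolve
  to the first start in grid order. Degenerate input (all bin means
  equal) returns a pure-nugget model with a warning instead of failing.
* **Kriging solves** use a dense LU factorization of the (k+1)×(k+1)
  augmented system — k ≤ 25, so cost is negligible and iterative solvers
  are pointless. Kriging variances in (−1e−12, 0) from round-off clamp
  to zero; anything more negative raises an internal-consistency error.
* **Weighted correlation.** Cross-validated performance is the Pearson
  correlation weighted by prediction precision 1/σ²; weights are
  normalized, so the statistic is invariant to rescaling. The p-value is
  the F-test of the weighted-least-squares slope on (1, n − 2) degrees
  of freedom. A zero σ² (possible only with a zero nugget at a duplicated
  coordinate) is replaced by the smallest positive σ² in the set, with a
  message; constant inputs yield an explicit `undefined` flag rather than
  NaN.
* **Leave-one-out protocol.** The variogram is fitted once on all data
  and held fixed while each point is predicted from the remainder — the
  literal published protocol. `refit_per_fold = TRUE` gives the stricter
  variant for honesty checks; on the synthetic panels the two agree to
  within the stochastic noise of the fit.
* **k-fold folds** differ in size by at most one and are assigned by a
  seeded shuffle; `k = n` reduces exactly to leave-one-out.

## Design choices where the design was genuinely open

* **Trafficking-class boundaries.** The published class definitions are
  approximate ("~0.2", "~0.5"). This package fixes [0, 0.2) = II,
  [0.2, 0.5] = III, (0.5, 1] = IV, and class I is only assignable from an
  explicit null/truncation flag — a trafficking index of 0 is still an
  expressed protein.
* **Reference normalization.** "Normalized to variant V" is implemented
  as division by V's raw value (V maps to 1.0); a min–max alternative is
  available behind `normalize = "minmax"` because the published formula
  is not stated. The normalization used is recorded in the dataset's
  axis metadata.
* **Confidence contours** are empirical quantiles of the grid σ², not
  fixed σ² levels: quantiles are the only reproducible reading of a "top
  25% confidence quartile", and they adapt across conditions whose
  absolute variance scales differ.
* **Delta-landscape uncertainty** adds the two conditions' Kriging
  variances (independent-error convention); only delta values, not delta
  uncertainties, have a published counterpart.
* **Structure mapping** assigns each residue the value of the
  minimum-σ² cell in its nearest landscape column, with ties resolved to
  the lower y. Values are written to the PDB B-factor field scaled ×100
  and clipped to the field's printable width, recorded in a REMARK line;
  every other byte of the structure file is preserved. Residues present
  in the structure but absent from the annotation are left untouched and
  reported, never imputed. A warning fires when the grid has fewer than
  `protein_length / 10` columns.
* **Neighborhood floor versus radius.** Whether the published runs
  applied the search radius before or after the minimum-neighbor floor
  is unstated; here the floor wins — if fewer than `min_n` observations
  fall inside the radius, the `min_n` nearest overall are used.

## What the synthetic generator does and does not emulate

`simulate_field()` draws a Gaussian random field with a specified
variogram by dense Cholesky factorization of the implied covariance
(`C_ij = C(0) − γ(h_ij)`, diagonal `C(0)`, jitter 1e−10·I) — appropriate
at desk scale (n up to a few thousand), deterministic per seed.

`make_npc1_like_fixture()` produces a paired control/treated panel with
the statistical shape of a real disease-variant dataset: 48 variants on
a 1278-residue protein; a trafficking index drawn from a spherical field
over the (position, cholesterol) plane with range 0.19 and sill 0.05
(the spatial scale estimated for the real control panel); a cholesterol
score from a smooth 1-d field along the sequence (range 0.08, sill
0.02, centred on a reference-normalized value of 1); and a
trafficking–cholesterol correlation steered to −0.36 by blending the
standardized field with the cholesterol axis. The control mean
trafficking index is 0.35 so that clipping to [0, 1] affects well under
2% of draws. The treated condition reuses the same standard-normal draw
with range and sill multiplied by `condition_effect` (default 0.6, the
published ~40% plateau shrink under HDAC inhibition) plus an additive
trafficking shift of 0.15; `condition_effect = 1` reproduces the control
exactly. A single shrink factor cannot simultaneously match the
published plateau shrink (×0.6) and the much stronger range shrink
(×~0.16); the factor is applied to both and is configurable.

The generator matches spatial covariance structure only. It does not
emulate: heteroskedastic measurement error across variants, the discrete
multi-domain architecture of the real protein (variants cluster in
luminal domains), truncation/null alleles, or any mechanistic coupling
between trafficking and cholesterol handling. Passing tests on these
fixtures therefore demonstrates that the estimator recovers known
spatial structure, not that real variant panels satisfy the stationarity
assumptions.

## Problem sizes used in the shipped checks

The test-suite simulations are sized for a desk run: parameter-recovery
uses 50 replicate fields of n = 200; calibration of standardized
leave-one-out residuals uses one field of n = 300; cross-validation
checks use n = 100–200; landscape oracles use grids of 50×50 and below.
The acceptance script re-runs the same computations from scratch with
the seed supplied on its command line.

## Known limitations

* The plane treats sequence distance and functional distance as
  commensurable after normalization; there is no anisotropy correction
  (a directional variogram is out of scope by design).
* Ordinary Kriging assumes second-order stationarity of z over the
  plane; strong trends (e.g. a systematically drifting baseline along
  the sequence) violate it and would call for universal Kriging, which
  is deliberately not implemented.
* Kriging weights can be negative, so landscape values can modestly
  overshoot the observed z range; trafficking-index landscapes are not
  clipped to [0, 1].
* With 48 observations a single fitted range is a noisy estimate; the
  stochastic recovery bands in the tests quantify exactly how noisy.

## A worked micro-example

```{r example, eval = FALSE}
fx <- make_npc1_like_fixture(seed = 1)
emp <- empirical_variogram(pairwise_semivariances(fx$ctl))
fit <- fit_variogram(emp)
glance(fit)

cv <- loo_cv(fx$ctl, model = fit)
glance(cv)

ls <- build_landscape(fx$ctl, fit, grid_res = 60) |>
  confidence_mask(0.25)
autoplot(ls, dataset = fx$ctl)

ann <- annotate_residues(ls, protein_length(fx$ctl))
head(ann)
```
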