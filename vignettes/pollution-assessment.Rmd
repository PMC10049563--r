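---
title: "Assessing soil heavy-metal pollution by functional area: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing soil heavy-metal pollution by functional area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
```

`metalrisk` implements a complete assessment pipeline for heavy-metal
contamination (Zn, Cu, Cr, Pb, As, Hg) in surface-soil samples grouped
into land-use functional areas — a commercial zone (A), an industrial
zone (B) and an agricultural zone (C) of a semi-arid region in NW
China. This vignette explains the models, the tunable parameters, the
synthetic-data generator that stands in for the (undeposited) raw field
samples, and the numerical and design choices that were genuinely open.

## Pollution and risk indices

Three standard indices are computed per sample and element, each
against the regional (Xinjiang) geochemical background value $B_n$:

* **Geo-accumulation index** (Muller):
  $I_{geo} = \log_2\!\big(C_n / (1.5\,B_n)\big)$. The factor 1.5
  absorbs natural lithogenic variability; a doubling of concentration
  raises $I_{geo}$ by exactly 1. Classes: clean ($\le 0$), then light /
  moderate / high pollution in unit steps, very high above 3.
* **Single-factor pollution index**: $P_i = C_i / B_n$, classified
  clean ($\le 1$) up to heavy pollution ($> 5$).
* **Hakanson potential ecological risk**: per element
  $E_r^i = T_n^i\, C_i / C_n^i$ with toxic-response coefficient
  $T_n^i$, summed over the six elements into the sample-level index
  $PRI = \sum_i E_r^i$. With the shared background, $E_r^i$ is exactly
  $T_n^i P_i$, and $PRI$ is linear in concentrations.

The toxic-response coefficients are not part of the survey's published
tables; the package ships the standard Hakanson (1980) set (Zn = 1,
Cr = 2, Cu = Pb = 5, As = 10, Hg = 40), overridable through
`element_references(overrides = ...)`. Because the coefficients are a
convention, reported $E_r^i$/$PRI$ values are convention-dependent;
every table and surface that uses them states the coefficient set via
the reference table it was computed from.

**Boundary conventions.** The published class tables are ambiguous at
their edges. The $I_{geo}$/$P_i$ scales are written with "$\le$", so a
value exactly on a boundary joins the lower (less severe) class; the
risk scales are printed as dash ranges ("40–80"), which we read as
half-open $[40, 80)$, so a boundary value starts the upper class. Both
rules are explicit (`boundary_rule`) and overridable in
`classification_scheme()`.

**Zero concentrations** are legal for $P_i$ and $E_r^i$ (a ratio of 0)
but a domain error for $I_{geo}$ (log of zero); the sample validator
rejects non-positive concentrations outright since real digests report
detection-limited positives.

## Area statistics

`summarize_area()` reports mean, sample SD ($n-1$), CV = SD/mean ×
100%, and *adjusted* Fisher–Pearson skewness and excess kurtosis
(`e1071` type 2) — the estimators SPSS prints, which is what the
reference survey used. Both are configurable via `type`.

Derived quantities:

* **Exceedance ratios** — area mean over background and over the
  GB 15618-2018 screening level. On the reference marginal statistics,
  As is the only element whose area means exceed the screening level.
* **Strong-variation screening** — elements with CV strictly greater
  than 36% are flagged as strongly variable (uneven anthropogenic
  input). The strict inequality reproduces the reference survey's
  flagged set exactly: Cu in area B; Cr, As and Hg in area C.
* **Composite area means** — the survey's printed composite values
  (65.67 / 57.86 / 55.24 mg/kg) equal the *sum of the six element
  means divided by five*, not six. Whether this reflects an intended
  exclusion or a typo is unknowable from the publication, so the
  default is the arithmetic mean (`denominator = 6`) and the
  five-denominator convention is an explicit, warning-emitting option.
  Note the printed composites themselves cannot be matched beyond
  ±0.011: they were computed from unrounded means, while only 2-dp
  means are published (six inputs each ±0.005, propagated through
  sum/5, plus ±0.005 on the printed target).

A related irreproducibility: the published Hg summary rows print
0.03 ± 0.01 mg/kg (one significant figure) next to CVs of 23.92, 19.38
and 37.95%. No reconstruction from the printed mean/SD can recover
those CVs (0.01/0.03 = 33.3%). The acceptance suite asserts the
CV-reconstruction bound for all 18 rows and knowingly reports the three
Hg rows as failures rather than widening the bound.

## Spatial surfaces

`idw_interpolate()` implements inverse-distance weighting,
$\hat v = \sum w_i v_i / \sum w_i$ with $w_i = d_i^{-p}$, on planar
Euclidean distances. The survey names IDW but no parameters, and its
maps carry no coordinate system, so the surfaces are qualitative:

* power $p = 2$ and an all-points neighborhood by default, both
  configurable (`power`, `k_neighbors`);
* coincident points are averaged before weighting; a cell center within
  $\varepsilon = 10^{-9} \times$ cell size of a sample returns that
  sample's value exactly (IDW's exactness property);
* rasters are stored north-up and exported as ESRI ASCII grids — a
  plain-text format any GIS reads; no GeoTIFF dependency is taken;
* every interpolated value is a convex combination of sample values,
  which the tests assert against a naive double-loop oracle.

`risk_surface()` interpolates per-sample $PRI$ and classifies each cell
on the summed-risk scheme, mirroring the survey's risk maps.

## Source apportionment

Per area: Pearson correlation matrix, Kaiser–Meyer–Olkin adequacy
(anti-image partial correlations from the inverse correlation matrix;
KMO is identically 0.5 for two variables, a closed form the tests pin),
Bartlett's sphericity test
$\chi^2 = -(n - 1 - (2p+5)/6)\ln\det R$ on $p(p-1)/2$ df, and PCA.

PCA operates on the **correlation** matrix — element scales span three
orders of magnitude (Hg vs Pb), and the reference eigenvalues sum to 6.
Retention uses the Kaiser rule (eigenvalue > 1), which reproduces the
reference survey's 3/2/2 component pattern from its printed correlation
matrices exactly; a fixed-`retain` override exists for degenerate
inputs. Retained loadings $v_k\sqrt{\lambda_k}$ are varimax-rotated
with Kaiser normalization (convergence 1e-8; normalization is applied
manually so zero-communality rows cannot produce non-finite values).
Sign convention: each component's largest-magnitude loading is made
positive; negative loadings are reported as-is. Communalities and the
retained-subspace reconstruction $LL^\top$ are rotation-invariant to
1e-8, which the tests assert.

Whether the original analysis pooled or per-area standardized its data
and its exact rotation settings are unpublished, so the reference PCA
table is matched *structurally* (component counts, eigenvalue
conservation) rather than numerically.

Hierarchical clustering of elements defaults to the correlation
distance $1 - r$ with average linkage (monotone merge heights;
perfectly co-varying elements merge at height 0) and a flat cut at
$k = 3$, all configurable. The survey does not state its distance or
linkage, so the published dendrogram topology is not asserted; the
tests check cluster structure only on synthetic draws, where e.g. the
commercial area's Pb/As pair separates from Cu/Hg by construction.

## The synthetic-data generator

No raw samples are deposited with the survey, so `generate_area()`
draws them: a Gaussian copula over the six elements with
truncated-normal marginals, calibrated so that large draws recover the
published per-area statistics:

* **Marginals.** For each element the truncated-normal *parent*
  $(\mu, \sigma)$ on the published range $[\min, \max]$ is solved
  (Nelder–Mead on the tail-stable moment formulas) so the truncated
  distribution itself attains the published mean and SD. Truncated
  normal was chosen over lognormal because the published skewness is
  mixed-sign and mostly small and the ranges give hard truncation
  bounds; matching skewness/kurtosis is explicitly out of scope.
* **Family-boundary marginals.** Five published (mean, SD, range)
  triples (Zn and Pb in A, Hg in A and B, Cu in B — the heavy-tailed
  rows with skewness up to 4.7) lie outside what *any* truncated
  normal can represent: with the mean that close to one range bound,
  the family's SD tops out below the target (the limiting shape is a
  truncated exponential). The solver then sits on the boundary: the
  mean is matched, the SD falls short by 11–23%, and the element is
  flagged `sd_feasible = FALSE` in the `calibration` attribute.
  Mean and correlation recovery are unaffected.
* **Dependence.** Feeding the target Pearson matrix directly into the
  copula attenuates realized correlations (monotone but nonlinear
  marginal transforms), by up to 0.05 for the boundary marginals — so
  the latent correlation is inverted per pair (NORTA): a 48-node
  Gauss–Hermite quadrature evaluates the induced Pearson correlation as
  a function of the latent one, and a root-finder matches the target.
  Realized correlations at $n = 10{,}000$ then land within ~0.015 of
  the published matrices (the residual is PSD repair plus sampling
  error). The latent matrix is floored at eigenvalue $10^{-6}$
  (`psd_repair()`, iterated clip-and-rescale) if needed; the three
  published matrices are already positive definite.
* **Coordinates** are uniform in synthetic planar boxes (projected
  meters, one box per area); no real sampling geography is published
  beyond a small-scale map, so spatial stages are exercised on
  synthetic geometry only.
* **Counts.** The survey states 104 samples in total but per-area
  counts of 26, 35 and 62 (sum 123). `default_study_fixture()` emits
  the per-area counts by default and attaches a note flagging the
  discrepancy; `mode = "scaled"` rescales by largest remainder to a
  104-sample draw (22/30/52). Neither convention is asserted correct.
* **Determinism.** All randomness flows from one integer seed; the
  default 20190104 encodes the study year and stated total and is
  overridable everywhere. Calibration is deterministic and cached
  per configuration.

**What passing tests do and do not show.** The generator reproduces
first and second moments, ranges and pairwise correlations — not the
real data's skewness, kurtosis, spatial autocorrelation or outlier
structure. Downstream results on synthetic draws therefore validate
the *computations* (indices, statistics, surfaces, PCA mechanics), not
the survey's substantive findings on real soil; published figures that
depend on the raw samples (per-sample index averages, the real KMO and
loading values) are checked only as structural properties or tolerance
bands, never as point reproductions.

## Problem sizes and runtime choices

Calibration-recovery checks use $n = 10{,}000$ draws per area (CLT
tolerances: means ±2%, SDs ±5% where the family can attain them,
correlations ±0.03); pipeline smoke tests use the survey-sized fixture
(~100–123 samples); IDW oracle comparisons use 10 × 10 grids with 20
points, and the analysis drivers interpolate 60-cell-wide grids. These
sizes keep the full suite under a minute while leaving the statistical
tolerances comfortably non-trivial.

## Known limitations

* Toxicity coefficients, IDW parameters, PCA preprocessing and cluster
  settings are conventions where the survey is silent; all are
  explicit, documented defaults rather than recovered facts.
* The published composite means (sum/5) and the Hg CV rows are
  internally inconsistent at printed precision, as described above; the
  package reproduces what arithmetic supports and flags the rest.
* The survey's risk-narrative section mixes in an element (Cd) that was
  never measured and an index value inconsistent with its own
  formulas; the package does not attempt to reproduce that section.
* No kriging/variogram modelling, no health-risk (HQ/HI) model, no
  receptor modelling (PMF/UNMIX): out of scope by design.
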