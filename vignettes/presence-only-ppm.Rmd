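---
title: "Presence-only point-process distribution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only point-process distribution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmrange)
```

This vignette is the package's own account of its statistical machinery:
the models and conventions it implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The point-process model

Presence-only records carry no absences, so `ppmrange` models them as an
inhomogeneous Poisson point process (IPP): the expected density of records
at location $x$ is an intensity $\lambda(x)$ with

$$\log \lambda(x) = \alpha + \beta^\top f(x),$$

where $f(x)$ are features of the environmental predictors. Only linear and
quadratic features are implemented: each predictor $v$ contributes
$(v - \min v)/(\max v - \min v)$ and $(v^2 - \min v^2)/(\max v^2 - \min
v^2)$, with the min/max taken over the calibration data so features lie in
$[0,1]$ there. Projection data outside the calibration range is clamped to
$[0,1]$ and the clamped fraction logged. The intercept $\alpha$ is not a
free parameter: it is absorbed by normalizing over the background sample.

Fitting minimizes the convex objective

$$-\frac1n \sum_{i \in \text{presences}} \beta^\top f(x_i)
 + \log \sum_{j \in \text{background}} e^{\beta^\top f(z_j)}
 + \sum_k \lambda_k |\beta_k|$$

by FISTA (accelerated proximal gradient with backtracking line search and
restart on non-monotone steps), declaring convergence when the objective
changes by less than `tol` ($10^{-5}$ by default, the conventional setting
for this model family) within at most `max_iter = 5000` iterations;
non-convergence is recorded in the model object rather than raised. The
penalty weights follow the maxent default schedule
$\lambda_k = \mathrm{rm} \cdot \Lambda_{\text{class}}(n) \cdot s_k /
\sqrt{n}$, where $s_k$ is the feature's standard deviation over the
presences, $n$ the presence count, and $\Lambda$ is interpolated from the
published per-class tables (linear: $n = 0,10,30,100 \to 1,1,0.2,0.05$;
quadratic: $n = 0,10,17,30,100 \to 1.3,0.8,0.5,0.25,0.05$; the quadratic
table governs all features whenever quadratic features are present, as in
the reference open-source implementation). The regularization multiplier
`rm` is the single knob the tuning stage varies.

**Equivalence to weighted logistic regression.** The same estimator can be
obtained as the large-weight limit of a penalized logistic regression with
presences weighted 1 and background weighted $W$. The suite checks this
numerically against an independent penalized-GLM solver (`glmnet`): the
coefficient gap decreases monotonically in $W$ and is below $10^{-3}$ at
$W = 10^4$ on 150-cell instances. At $W = 100$ the finite-weight bias is
of order $10^{-3}$-$10^{-2}$, which is why the package treats the
equivalence as a limit statement rather than an identity at moderate
weights.

**Outputs.** `raw` is $e^{\beta^\top f(x)}/Z$ with $Z$ the stored
background normalizer (it sums to 1 over the calibration background);
`cloglog` is $1 - \exp(-e^{H}\,\mathrm{raw})$ with $H$ the entropy of the
fitted raw distribution. cloglog is a monotone transform of the linear
predictor, lies in $(0,1)$, and equals $1 - e^{-1} \approx 0.632$
everywhere in the uniform (all-zero-coefficient) limit — a useful exact
identity that the tests assert to $10^{-12}$.

## 2. Model selection and validation

`ppm_tune()` fits every combination of `rm_grid` (default 1 to 5 by 0.5)
and feature classes (linear; linear+quadratic), 18 candidates in all. Each
is scored by AICc with the raw prediction re-standardized over the full
grid, $K$ = number of nonzero coefficients, and
$\mathrm{AICc} = 2K - 2\log L + 2K(K+1)/(n-K-1)$; candidates with
$n - K - 1 \le 0$ are flagged invalid and excluded rather than raising.
Ties in AICc break toward smaller $K$, then smaller `rm`.

Cross-validation is spatially blocked. The partition crosses a fine
checkerboard (blocks of `agg1` cells) with coarse latitudinal banding
(blocks of `agg1 * agg2` cells), yielding four spatial folds. This is the
package's own hierarchical scheme: the classical two-scale nested
checkerboard degenerates to two folds whenever the two aggregation scales
coincide, whereas this crossing always produces four usable folds
(including on a 2x2 grid at unit aggregation) while preserving the spatial
blocking that makes test AUC an honest out-of-area estimate. A seeded
random k-fold alternative (`random_partition()`) is provided for
non-spatial protocols such as the five-fold Boyce evaluation.

Metrics: AUC in Mann-Whitney form (exact pair counting is the test
oracle); omission rates under strict inequality so minimum-training-
presence omission is zero on its own training data; the 10% training
presence threshold uses the linear-interpolation quantile (type 7 — the
convention is configurable in principle and documented because published
analyses rarely state it); bootstrap partial ROC (default 5% omission
error, 1000 replicates resampling 50% of test points) as the ratio of the
partial area of the (proportion-of-area, sensitivity) curve to the 1:1
null line's partial area, with the null area computed analytically; and
the Continuous Boyce Index over 101 moving windows whose width defaults to
10% of the background score range — the documented default of the method's
lineage; the paper trail for this constant is thin, so it is an explicit
argument. CBI is exactly invariant under affine score transforms and only
approximately so under nonlinear monotone transforms (the windows live on
the score scale even though the final correlation is rank-based); the
tests encode both facts.

## 3. Geography

Binary maps threshold the cloglog surface at $\ge t$. Cell areas use the
exact spherical quadrilateral $R^2\,\Delta\lambda\,(\sin\varphi_{\text{top}}
- \sin\varphi_{\text{bottom}})$ with $R = 6371$ km and cell-edge latitudes
(a $\cos\varphi_{\text{center}}$ approximation would bias coarse cells);
the full-globe identity $4\pi R^2$ and an independent geodesic-polygon
oracle validate it. The extent of occurrence is the spherical area of the
occurrence convex hull, computed on the sphere by default (an equal-area
projection would be an alternative; which convention published analyses
use is rarely stated). "Excluding the ocean" is implemented as restriction
to a supplied landmask grid — no coastline is bundled, keeping the package
download-free. Great-circle distances for thinning use the haversine with
the same $R = 6371$ km.

Spatial thinning enforces a minimum pairwise distance (default 4 km, a
biologically motivated inter-territory scale; it is a parameter, not a
constant) by a randomized greedy heuristic: repeatedly remove one of the
records with the most neighbours inside the radius, uniformly among ties,
and keep the best of `n_trials = 100` trials. Exact RNG-stream replication
of other thinning implementations is deliberately not promised — the
contract is cardinality (the suite verifies >= 95% optimality against an
exhaustive maximum-independent-set oracle on small instances), plus a
feasibility audit of every output.

## 4. ENFA

Predictors are standardized by the background sample's mean and SD, so the
analysis is invariant to affine changes of raw predictor units. Occupied
cells are weighted by their occurrence counts (duplicating every record
leaves the result unchanged), and ENFA deliberately uses *all* cleaned
records rather than the thinned set: it measures environments at points,
where resampling the same conditions is information, not bias. The
marginality vector $m$ is the weighted mean of standardized occupied
values; $M = \|m\|$ without the classical 1.96 scaling, so a one-SD shift
on one axis gives $M = 1$. Specialization factors maximize
$u^\top R_g u / u^\top R_s u$ ($R_g$, $R_s$ the background and weighted
occupied covariances) subject to $R_s$-orthogonality to earlier factors,
solved in closed form through the symmetric matrix
$R_s^{-1/2} R_g R_s^{-1/2}$; a singular $R_s$ raises an error carrying the
condition number. $S = \sqrt{\text{mean}(\lambda)}$ over all $P$ achieved
ratios (marginality axis included), which makes the background-identical
null exactly $S = 1$; a sum-based alternative exists in the literature but
the mean-based form is the one with the clean null. Axis variance shares
are reported as $100\,\lambda_k/\sum\lambda$ — one of several conventions
in circulation, hence documented here. The constrained-eigen solution is
verified against direct numerical Rayleigh-quotient maximization to
$10^{-6}$ for 2-3 predictors.

## 5. Projection, overlap, stability

Projection onto another period's stack rebuilds features with the stored
calibration bounds (clamping logged) and the stored normalizer and
entropy, so projecting onto the calibration stack reproduces training
suitability exactly. Ensembles are cell-wise means (or sums); Schoener's
$D = 1 - \frac12\sum|p - q|$ is computed on surfaces normalized to sum to
1 over the shared unmasked cells — whether to overlap cloglog or raw
surfaces is the caller's choice, and normalization makes $D$ invariant to
positive rescaling either way. The stability classifier uses the current
binary state $c$ and the fraction $f$ of past periods suitable: stable
($c=1, f=1$), colonizable ($c=1, f<1$), unstable ($c=0, f>0$), absence
($c=0, f=0$), with numeric codes $1$, $f-1 \in (-1, 0]$ (the boundary case
$f=0$ maps to $-1$), $2$ and $-2$ respectively. Because published recodes
of this map vary, the class raster, the numeric codes and the raw $(c, f)$
layers are all returned so any alternative legend is derivable. Past
periods reuse the current 10TP threshold.

## 6. The synthetic-data generator

The generator exists so that every stage has a recoverable ground truth.
Per layer, white Gaussian noise is mixed across layers by the symmetric
square root of the target cross-correlation matrix (tolerating
semi-definite targets where a Cholesky would fail; non-PSD targets are
rejected naming the offending eigenvalue), smoothed by a separable
Gaussian kernel of scale `autocorr_length` cells (edge-renormalized), and
re-standardized to zero mean and unit variance. Mixing before smoothing
preserves the between-layer correlation because all layers share one
kernel. True intensity is log-linear with per-layer linear and quadratic
coefficients; presences are multinomial over cells with uniform
within-cell jitter, so points live in continuous space and thinning tests
are not degenerate on cell centers.

The reference landscape (`default_config()`) is a 100x100 grid of 2.5
arc-minute cells, three independent layers with `autocorr_length = 5`,
concave responses (`beta_linear = (1, -0.7, 0.5)`, `beta_quadratic =
(-0.8, -0.4, -0.2)`), and 500 presences — chosen once as a realistic
mid-density design: strong enough signal that model selection is
meaningful, weak enough that evaluation metrics are not saturated. What
the generator does **not** emulate: real bioclimatic variable semantics
and units, sampling bias fields, nodata coastlines, non-Gaussian predictor
marginals, and observation error in coordinates. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to every pathology of real occurrence data.

## 7. Orchestration and reproducibility

`run_pipeline()` executes the stages in order from a plain list or YAML
configuration, expanding one master seed deterministically into per-stage
seeds; the report embeds the configuration and every stage seed, and
re-running with the same seed is byte-identical. Each call recomputes all
stages — there is no stage cache; for the problem sizes this package
targets a full run is seconds to minutes, and recomputation keeps the
determinism guarantee trivial to audit. The pipeline's stages are ordinary
exported functions, and the package's interface is R itself (plus the
`scripts/acceptance.R` entry point), following the conventions of the
distribution-modelling packages this one sits alongside rather than
shipping a shell tool. Rasters are exchanged as single-band plain-text
ESRI ASCII grids (`.asc`, nodata -9999) and occurrences as `lon,lat` CSV;
polygons as closed lon/lat rings.

Problem sizes used by the validation suite — 150-cell instances for the
weighted-logistic equivalence, ten 100x100 landscapes with 1000 presences
and 10,000 background points for intensity recovery, $10^5$ background
points for the ENFA null, 200 small instances for thinning optimality —
were chosen as the smallest designs at which each statistical claim is
sharp.

## 8. Known limitations

- Hinge, product and threshold features are out of scope by design, as are
  MESS-style extrapolation diagnostics; clamping is the only projection
  safeguard.
- Percent-contribution-style variable importances are path-dependent in
  any implementation; this package reports coefficient-based and
  permutation-style summaries through the evaluation and ENFA modules
  instead of promising numeric identity with other software.
- No reprojection or resampling between mismatched grids: lattices must
  agree exactly, otherwise operations error.
- The thinning heuristic is near-optimal, not exact, on large instances;
  the exhaustive oracle is only feasible for small point sets.
- Areas assume a spherical Earth ($R = 6371$ km); ellipsoidal refinements
  are below the resolution of the method's other uncertainties.
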