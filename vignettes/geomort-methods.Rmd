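---
title: "Methods: from topsoil geochemistry to areal cancer relative risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from topsoil geochemistry to areal cancer relative risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`geomort` implements an ecological-regression workflow for linking soil
element concentrations, measured at irregular sampling points, to mortality
counts aggregated over areal units (towns). This vignette documents the
statistical model at each stage, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## 1. Interpolation: ordinary kriging to area centroids

Mortality is areal; geochemistry is point-referenced. The package assigns
each area a representative concentration by ordinary kriging of every
element to the area centroid.

* **Empirical semivariogram.** Matheron's estimator
  $\hat\gamma(h) = \frac{1}{2N(h)}\sum_{(i,j)\in N(h)} (z_i - z_j)^2$ over
  pairs binned by Euclidean distance. Bin centres are the mean pair
  distance per bin (empty bins are dropped); the default cutoff is half the
  maximum pair distance, the usual rule of thumb since long lags are
  pair-poor.
* **Model fit.** A parametric model (exponential by default; spherical and
  Gaussian available) is fitted by weighted least squares with Cressie
  weights $N(h)/\gamma_{\text{model}}(h)^2$, which favour well-populated
  short lags. The optimiser is box-constrained quasi-Newton from five
  starting ranges spanning the lag window, polished by a derivative-free
  pass; on noiseless model-generated input the parameters are recovered to
  well below $10^{-4}$. A fit whose curve barely rises over the observed
  lags is collapsed to a canonical pure-nugget model and flagged with a
  warning rather than failing: a flat variogram is a legitimate (if
  uninformative) description of spatially unstructured data.
* **Prediction.** For each target the ordinary-kriging system
  $\begin{pmatrix}\Gamma & 1\\ 1^\top & 0\end{pmatrix}
  \begin{pmatrix}w\\ \mu\end{pmatrix} =
  \begin{pmatrix}\gamma_0\\ 1\end{pmatrix}$
  is solved on the 32 nearest samples (equidistant ties broken by sample
  index, so results are reproducible). Weights sum to one by construction;
  with a zero nugget the predictor interpolates exactly. Duplicate sample
  coordinates would make the system singular and are averaged with a
  warning.

Two choices here are deliberate and not forced by the method:

* **Kriging on the log scale.** Concentrations in mg/kg are heavily
  right-skewed (survey maxima sit one to two orders of magnitude above
  medians), and everything downstream requires strictly positive values.
  Each element is therefore kriged as log-concentration and
  back-transformed by exponentiation. Any non-positive back-transformed
  value (impossible for finite predictions, but guarded) is clipped to the
  element's smallest positive observation; positivity is enforced in
  exactly one place, and the clr stage *refuses* non-positive input rather
  than silently imputing.
* **Exponential family by default**, matching the correlation family of the
  synthetic generator and the common default for geochemical surfaces.

Interpolation typically narrows the range of determinations relative to the
raw samples; the package reports per-element observed versus interpolated
ranges (`range_report`) rather than asserting the narrowing, which is not a
mathematical guarantee of ordinary kriging.

## 2. Compositional transformation

Element concentrations are parts of a (nearly) fixed total mass, so raw
correlations are partially spurious. The centred log-ratio transform

$$ y_d = \log\frac{x_d}{\big(\prod_{e=1}^{D} x_e\big)^{1/D}} $$

is computed in log space (log of each value minus the row mean of logs) for
numerical stability. Every clr row sums to zero, so the clr covariance
matrix is singular with rank at most $D-1$ — a property the package treats
as a feature to be handled (below), not an error. Subcompositional
incoherence (dropping an element changes the remaining clr values) is
inherent to clr and documented by a test. No below-detection-limit
replacement scheme is provided: the generator produces strictly positive
values, and zero-handling policy is survey-specific.

## 3. Robust factor analysis

The clr variables are collinear by construction; regression on them
directly is ill-posed. The package extracts a small number of latent
factors:

* **Robust correlation.** A minimum-covariance-determinant (MCD) scatter
  estimate at support fraction 0.75 (the usual compromise between a 50%
  breakdown point and efficiency; fraction 1 falls back to the classical
  Pearson matrix exactly). The MCD is undefined on collinear data, so the
  estimate is computed on the full-rank principal subspace of the data and
  mapped back; the returned matrix carries `rank_deficient` /
  `min_eigenvalue` attributes flagging the clr null direction.
* **Iterated principal factor analysis.** Squared multiple correlations
  initialise the communalities (via pseudo-inverse, since the clr
  correlation is singular); the reduced matrix is eigendecomposed, top-$k$
  loadings extracted, communalities updated, and the loop repeated until
  the largest communality change is below $10^{-4}$ (the order of tolerance
  used by standard iterated-PFA implementations; convergence is linear and
  can need thousands of sweeps at much tighter tolerances, with no
  practical change in the loadings). Negative eigenvalues of the reduced
  matrix — including the clr-induced near-zero one — are excluded from the
  factor space.
* **Varimax rotation** by pairwise plane rotations with Kaiser row
  normalisation, each angle solved in closed form. The criterion is
  monotonically nondecreasing across sweeps by construction and the trace
  is returned so callers (and the tests) can assert it; row communalities
  are invariant because the rotation is orthogonal. The number of factors
  defaults to $k = 4$, the dimension at which surveys of this element set
  typically pass 75% cumulative explained variance; the share is reported,
  never enforced.
* **Scores** by the regression (Thomson) method,
  $F = y_{\text{std}} R^{+} \Lambda$, with a rank-$(D-1)$ pseudo-inverse of
  the correlation matrix; standardisation uses population (1/n) variances so
  scores are invariant under row duplication. Score columns are centred
  exactly.
* **Sign convention.** Loading signs are arbitrary after extraction and
  rotation, but the sign of a factor flips the direction of its fitted
  relative risk. Each factor is therefore flipped — loading and score
  columns jointly — so its largest-|loading| element is positive. The
  operation is idempotent and recorded.

## 4. Ecological regression with BYM spatial effects

Observed deaths are modelled as
$O_i \sim \text{Poisson}(E_i\lambda_i)$ with
$\log\lambda_i = \alpha + \sum_j \beta_j F_{ij} + \sum_k \delta_k
\text{Soc}_{ik} + u_i + v_i$, where $E_i$ (expected deaths under reference
rates) enters as an offset so $\lambda_i$ is a relative risk. The spatially
structured effect $u$ has the intrinsic CAR (ICAR) prior with kernel
$-\tfrac{\tau_u}{2}\sum_{i\sim j}(u_i - u_j)^2$ on the contiguity graph,
identified by a sum-to-zero constraint per connected component; $v$ is iid
normal with precision $\tau_v$.

**Priors.** $N(0, 10^3)$ on the intercept and all coefficients and
$\text{Gamma}(1, 5\cdot 10^{-4})$ on both precisions — common weakly
informative defaults in disease mapping. All are configurable.

**Inference** is by MCMC rather than a Laplace-approximation engine: the
contract is posterior summaries, and a self-contained sampler can be
verified against exact oracles (a naive-loop log-posterior, closed-form
Gibbs conditionals) in the test suite. The sampler (C++ core) uses:

* conjugate Gibbs updates for $\tau_u$
  ($\text{shape} + (n_{\text{free}} - c)/2$, $\text{rate} + \tfrac12
  \sum_{i\sim j}(u_i - u_j)^2$, with $c$ the number of connected
  components) and $\tau_v$;
* adaptive random-walk Metropolis for the intercept, coefficients and both
  random-effect vectors (adaptation toward 44% acceptance during burn-in
  only, so the retained chain is a fixed Markov kernel);
* per-sweep sum-to-zero centring of $u$ per connected component — for a
  fully connected graph the mean is absorbed into the intercept, leaving
  the linear predictor unchanged;
* an interweaving move that shifts mass between $\alpha$ and $v$ along the
  direction that leaves the linear predictor invariant, sampled from its
  closed-form Gaussian conditional. Without it the intercept mixes an
  order of magnitude more slowly.

Design columns are centred (continuous sociodemographic indicators also
scaled to unit SD), identically in the simulator and the fitter, so
coefficients are unchanged but decorrelated from the intercept. Isolated
areas (no neighbours) are excluded from $u$ (fixed at 0) and kept in $v$.
Proposals pushing the linear predictor beyond $\pm 35$ are rejected
outright as an overflow guard.

**Summaries.** $RR = \exp(\text{posterior mean coefficient})$ with the
(2.5%, 97.5%) quantiles of the exponentiated draws; *significant* means the
interval excludes 1. Convergence is monitored by split-$\hat R$ and
autocorrelation-based effective sample size on the fixed effects; any
$\hat R > 1.1$ flags the summary as non-converged — the flag is returned
with the results, never used to suppress them.

## 5. The synthetic generator: what it emulates, and what it does not

The generator reproduces the *statistical structure* the analysis assumes:

* **Geochemistry.** Ten elements (Al, As, Cd, Cr, Cu, Fe, Mn, Ni, Pb, Zn)
  with log-means set to median topsoil values typical of national
  geochemical atlases. Log-fields are Gaussian processes with exponential
  correlation (range 2 distance units in a 10-unit window, i.e. strong
  mesoscale structure), simulated exactly by Cholesky factorisation —
  adequate to ~2000 points, which covers desk-scale validation. A known
  10 × 4 loading matrix induces cross-element correlation through four
  common factor fields, mimicking the associations reported for such
  surveys (an Al/Mn/Zn vs Cu/Ni contrast; an Fe/Cr vs Cd contrast; a Pb–Ni
  axis; an As-dominated axis); element-specific fields (sill 0.15) plus
  white noise (0.05) leave the common factors ~75% of total log variance.
* **Areal units.** An `nx` × `ny` lattice with queen contiguity — a
  connected, planar graph with degree heterogeneity (3/5/8), the standard
  stand-in for municipal contiguity.
* **Mortality.** Expected counts log-uniform over [20, 200] (the scale of
  multi-year town-level totals), ICAR $u$ drawn exactly via the
  eigendecomposition of the graph Laplacian (null eigenvectors excluded,
  which enforces the per-component sum-to-zero constraint), iid $v$, and
  Poisson counts from the log-linear model with known $\alpha, \beta,
  \delta, \tau_u, \tau_v$ (defaults $\beta_1 = 0.10$, both precisions 10).
  Truth is recorded alongside the data for recovery tests.
* **Sociodemography.** Population-size category (rural/semi-urban/urban as
  two indicators), illiteracy, farmers and unemployment percentages,
  persons per household, mean income — census-style covariates with
  plausible scales, entering the design centred/standardised.

It does **not** emulate: age standardisation (expected counts are drawn,
not computed from age structure), irregular municipal geometry and areas of
wildly varying size, non-uniform sampling density, below-detection-limit
censoring, multi-endpoint correlation, or measurement error in the
covariates. Passing the parameter-recovery suite therefore demonstrates
correctness of the *computations* under the model's own assumptions, not
robustness of the *scientific design* to real-data violations of them.

## 6. Validation design and a known limitation

The test suite validates each stage against an independent route: clr
against direct formula evaluation (including a frozen oracle for a
published town-median composition), kriging against a dense solve of the
augmented system, the variogram fit by noiseless self-consistency, varimax
against a brute-force angle grid and against `stats::varimax`, PFA by
loading recovery with Procrustes alignment, the log-posterior against naive
loops, the Gibbs conditionals against closed-form gamma densities, and the
full sampler by parameter recovery (a 0.10 log-RR on a 900-area lattice is
recovered within ±0.04 with ~95% interval coverage over 20 replicates) and
null calibration. The end-to-end run injects one factor effect into one
endpoint and checks that exactly that endpoint × factor is flagged as
shared-significant in both sexes.

One phenomenon deserves emphasis because it is a property of the *design*,
not a bug: **spatial confounding**. Kriged exposure surfaces are smooth,
and the ICAR field concentrates its variance on the smoothest eigenvectors
of the lattice Laplacian — the same subspace. On small lattices (~200
areas) the effective spatial degrees of freedom are few, so a simulated
null factor can correlate at |r| ≈ 0.4 with the realised spatial field and
produce a genuine (identically reproduced by a non-spatial GLM)
association in both sexes at once. The end-to-end validation therefore
runs at 576 areas, where this ambient correlation is small; users applying
the pipeline to real data with few areas should expect the same effect,
which no amount of MCMC accuracy removes. Factor-score recovery is likewise
assessed after orthogonal Procrustes alignment, since varimax on the clr
basis identifies the score space only up to rotation and sign.

Problem sizes used throughout the validation — 400–900 areas, 150–800
sampling points, 2 chains of 4000–5000 sweeps — were chosen as the smallest
sizes at which the stochastic checks are statistically sharp; all
generator defaults are stated above and held fixed across the suite.
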