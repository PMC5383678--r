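# geomort

Ecological regression of areal cancer mortality on kriged topsoil
geochemistry.

`geomort` is for spatial epidemiologists and environmental-health analysts
who want to relate **area-level mortality counts** to **point-sampled soil
element concentrations** — the classic geochemistry-to-disease-mapping
workflow — without stitching together four different packages and hand-rolled
glue. It implements the full chain as one tested pipeline:

1. **Ordinary kriging** of each element's (log) concentration from irregular
   sampling points to the centroids of areal units (towns), with empirical
   Matheron semivariograms and weighted-least-squares variogram fits.
2. **Centred log-ratio (clr) transformation** of the interpolated
   compositions, `y_d = log(x_d / g(x))` with `g(x)` the row geometric mean,
   removing the spurious correlation of closed (parts-of-a-whole) data.
3. **Robust principal factor analysis** (MCD-based correlation, iterated
   principal factors, varimax rotation, regression scores) reducing the
   collinear, singular clr variables to a few latent exposure factors
   `F_ij`.
4. **Bayesian Poisson ecological regression** with expected deaths as
   offset and Besag–York–Mollié (BYM) spatial random effects:

   ```
   O_i ~ Poisson(E_i * lambda_i)
   log(lambda_i) = alpha + sum_j beta_j F_ij + sum_k delta_k Soc_ik + u_i + v_i
   ```

   where `u` is an intrinsic CAR (ICAR) spatially structured effect on the
   contiguity graph (sum-to-zero constrained), `v` an unstructured normal
   effect, and `Soc_ik` sociodemographic covariates. Inference is by MCMC
   (conjugate Gibbs for the precisions, adaptive Metropolis for the rest;
   C++ core), and covariate effects are reported as relative risks
   `RR = exp(beta)` with 95% credibility intervals; an effect is flagged
   significant when its interval excludes 1.
5. **Reporting**: per-endpoint, per-sex association tables split into
   RR > 1 and RR < 1, with a `shared_flag` marking endpoint × factor cells
   significant in both sexes on the same side of 1.

Because real geochemical-atlas samples and national mortality registers are
rarely redistributable, the package ships a first-class **synthetic-data
module**: spatially autocorrelated log-normal multi-element fields at
irregular points (with a known factor-loading structure), a queen-contiguity
lattice of towns, census-style sociodemographic indicators, and Poisson
counts drawn from the BYM model with known parameters — so every stage is
testable by parameter recovery.

## Worked example

Simulate a geochemical survey, reduce it to exposure factors:

```r
library(geomort)

sp <- generate_sample_points(600, field = field_params(seed = 42))
lat <- generate_area_lattice(24, 24)
lat$areas$x <- lat$areas$x / 2.4   # scale centroids into the sampling window
lat$areas$y <- lat$areas$y / 2.4

kr <- krige_composition(sp, as.matrix(lat$areas[, c("x", "y")]))
y  <- clr_transform(kr$predictions)
fa <- robust_pfa(y, k = 4, mcd_fraction = 0.75, seed = 42)
round(fa$model$loadings, 2)
#>       F1    F2    F3    F4
#> Al  0.93  0.12  0.07 -0.03
#> As  0.10 -0.29 -0.04  0.95
#> Cd -0.22  0.04  0.96 -0.15
#> Cr -0.44  0.19 -0.69 -0.11
#> Cu -0.86  0.05  0.01 -0.32
#> Fe -0.63  0.12 -0.48 -0.16
#> Mn  0.83  0.02  0.07  0.00
#> Ni -0.41  0.85  0.09 -0.19
#> Pb -0.24 -0.78  0.21  0.19
#> Zn  0.82 -0.29 -0.12  0.02
round(100 * fa$model$cumulative_share, 1)
#> [1] 82.6
```

Four factors carry 82.6% of the total clr variance; each column reads like a
geochemical association (e.g. F1 contrasts Al/Mn/Zn against Cu/Fe/Ni — the
sign convention makes each factor's dominant element positive).

The full pipeline — kriging, clr, factor analysis, then one BYM fit per
cancer site and sex — runs from a single config. Here a relative risk of
`exp(0.30) = 1.35` per unit of factor-1 score is injected into the simulated
"stomach" endpoint, and none into "lung":

```r
res <- run_pipeline(list(
  seed = 42, output_dir = "demo",
  endpoints = list(list(site = "stomach", beta = c(0.30, 0, 0, 0)),
                   list(site = "lung",    beta = c(0, 0, 0, 0))),
  synthetic = list(n_points = 600, nx = 24, ny = 24),
  regression = list(chains = 2, iter = 4000, burnin = 2000, thin = 4)))

subset(res$report, shared_flag | significant)
#>       site factor   sex    RR ci_low ci_high significant shared_flag
#> 1  stomach     F1   men 1.356  1.304   1.400        TRUE        TRUE
#> 5  stomach     F1 women 1.385  1.338   1.438        TRUE        TRUE
#> 10    lung     F2   men 0.937  0.892   0.977        TRUE       FALSE
#> 16    lung     F4 women 1.048  1.007   1.093        TRUE       FALSE
```

The injected association is recovered at its true magnitude and is the only
cell flagged as *shared* by both sexes; the two single-sex `lung` hits are
the kind of isolated findings the shared-flag convention is designed to
screen out. `demo/` now contains every stage's output (sample points,
kriged compositions, clr table, loadings, scores, per-fit RR tables, the
report split into RR > 1 / RR < 1, a choropleth-ready score map, fitted
variogram parameters, and a structured run log), each CSV stamped with the
config hash; a rerun with the same config is byte-identical.

A thin command-line wrapper with per-stage subcommands (`simulate`,
`krige`, `clr`, `factors`, `fit`, `report`, `run-all`) is installed at
`inst/scripts/geomort-cli.R`.

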