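# Synthetic study generator: multi-element geochemical fields at irregular
# sample points, a queen-contiguity lattice of towns, sociodemographic
# covariates, and Poisson mortality counts from a known BYM model, so every
# downstream stage is testable by parameter recovery.

GEOMORT_ELEMENTS <- c("Al", "As", "Cd", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn")

# Median topsoil concentrations (mg/kg) typical of national geochemical
# atlas surveys; used as default log-field means.
GEOMORT_MEDIANS <- c(Al = 19100, As = 9.0, Cd = 0.10, Cr = 23.2, Cu = 15.7,
                     Fe = 2.42, Mn = 384, Ni = 22.5, Pb = 21.4, Zn = 51.6)

# Default ground-truth loading structure (element x factor) on the
# log-concentration scale. The four columns mimic the associations commonly
# reported for topsoil surveys: F1 contrasts Ni/Cu (+) with Zn/Al/Mn (-),
# F2 contrasts Fe/Cr (+) with Cd (-), F3 follows the Pb/Ni ratio, F4 is an
# As-dominated axis.
default_loading_truth <- function() {
  m <- rbind(
    Al = c(-0.65,  0.10,  0.00,  0.10),
    As = c( 0.00,  0.10,  0.10, -0.75),
    Cd = c( 0.30, -0.60,  0.10,  0.00),
    Cr = c( 0.30,  0.60,  0.00,  0.10),
    Cu = c( 0.60,  0.10,  0.15,  0.10),
    Fe = c( 0.35,  0.60,  0.00,  0.00),
    Mn = c(-0.55,  0.15,  0.10,  0.10),
    Ni = c( 0.55,  0.10, -0.45,  0.00),
    Pb = c( 0.15,  0.00,  0.70,  0.10),
    Zn = c(-0.65,  0.10,  0.15,  0.10))
  colnames(m) <- paste0("F", 1:4)
  m
}

#' Parameters of the synthetic geochemical field
#'
#' Log-concentrations are generated as
#' `log X_d(s) = mean_log_d + sum_j loading_truth[d, j] f_j(s) + e_d(s)`,
#' where the `f_j` are independent unit-variance Gaussian random fields
#' with exponential correlation `exp(-d / gp_range)` (the cross-element
#' structure) and `e_d` are element-specific fields with marginal variance
#' `gp_sill` plus white-noise variance `nugget`.
#'
#' @param n_elements number of elements (default 10: Al, As, Cd, Cr, Cu,
#'   Fe, Mn, Ni, Pb, Zn).
#' @param elements element names.
#' @param mean_log per-element log-concentration means; default the log of
#'   median topsoil values of the ten elements.
#' @param gp_range correlation length, in coordinate units (> 0).
#' @param gp_sill marginal variance of each element-specific log-field.
#' @param nugget micro-scale (white noise) log-variance.
#' @param loading_truth n_elements x n_factors matrix inducing
#'   cross-element correlation.
#' @param seed integer seed used by [generate_sample_points()].
#' @return object of class `field_params`.
#' @export
field_params <- function(n_elements = 10,
                         elements = GEOMORT_ELEMENTS[seq_len(n_elements)],
                         mean_log = log(GEOMORT_MEDIANS[elements]),
                         gp_range = 2, gp_sill = 0.15, nugget = 0.05,
                         loading_truth = default_loading_truth()[seq_len(n_elements), , drop = FALSE],
                         seed = 1L) {
  loading_truth <- as.matrix(loading_truth)
  stopifnot(gp_range > 0, gp_sill >= 0, nugget >= 0,
            length(mean_log) == n_elements,
            nrow(loading_truth) == n_elements,
            ncol(loading_truth) <= n_elements)
  structure(list(n_elements = n_elements, elements = elements,
                 mean_log = stats::setNames(as.numeric(mean_log), elements),
                 gp_range = gp_range, gp_sill = gp_sill, nugget = nugget,
                 loading_truth = loading_truth, seed = as.integer(seed)),
            class = "field_params")
}

#' Ground-truth parameters of the mortality model
#'
#' Houses the intercept, factor effects, sociodemographic effects and
#' random-effect precisions of the log-linear relative-risk model
#' `log(lambda_i) = alpha + sum_j beta_j F_ij + sum_k delta_k Soc_ik +
#' u_i + v_i` used by [simulate_mortality()].
#'
#' @param alpha intercept (log baseline relative risk).
#' @param beta factor effects per unit score (default one active factor at
#'   0.10, i.e. RR 1.105 per unit score).
#' @param delta sociodemographic effects (default all zero; seven columns
#'   — two population-size indicators plus five continuous indicators).
#' @param tau_u precision of the spatially structured (ICAR) effect.
#' @param tau_v precision of the unstructured effect.
#' @param seed integer seed.
#' @return object of class `truth_params`.
#' @export
truth_params <- function(alpha = 0, beta = c(0.10, 0, 0, 0),
                         delta = rep(0, 7), tau_u = 10, tau_v = 10,
                         seed = 1L) {
  stopifnot(tau_u > 0, tau_v > 0)
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 tau_u = tau_u, tau_v = tau_v, seed = as.integer(seed)),
            class = "truth_params")
}

# Lower Cholesky of an exponential-correlation matrix on a point set, with
# a small jitter for numerical positive-definiteness. Adequate at desk
# scale (<= ~2000 points).
chol_expcov <- function(coords, range) {
  C <- exp(-as.matrix(stats::dist(coords)) / range)
  diag(C) <- diag(C) + 1e-10
  t(chol(C))
}

#' Generate point-sampled multi-element concentrations
#'
#' Draws `n_points` uniform locations in `bbox` and simulates the
#' log-concentration model of [field_params()] by Cholesky factorisation
#' of the exponential covariance, then exponentiates to mg/kg. With
#' `gp_sill = 0`, `nugget = 0` and zero loadings every location equals
#' `exp(mean_log)` exactly.
#'
#' @param n_points number of sampling points (>= 10).
#' @param bbox bounding box `c(xmin, ymin, xmax, ymax)`, non-degenerate.
#' @param field a `field_params` object.
#' @param seed overrides `field$seed` if given.
#' @return object of class `sample_points`: `coords` (n x 2),
#'   `concentrations` (n x D positive matrix), `factor_fields` (n x
#'   n_factors true common fields, kept for recovery tests), `field`.
#' @export
generate_sample_points <- function(n_points, bbox = c(0, 0, 10, 10),
                                   field = field_params(), seed = field$seed) {
  stopifnot(n_points >= 10, length(bbox) == 4,
            bbox[3] > bbox[1], bbox[4] > bbox[2])
  if (field$gp_range <= 0) stop("gp_range must be positive")
  set.seed(seed)
  coords <- cbind(x = stats::runif(n_points, bbox[1], bbox[3]),
                  y = stats::runif(n_points, bbox[2], bbox[4]))
  stopifnot(!anyDuplicated(coords))
  D <- field$n_elements
  k <- ncol(field$loading_truth)
  needs_gp <- field$gp_sill > 0 || any(field$loading_truth != 0)
  Lc <- if (needs_gp) chol_expcov(coords, field$gp_range) else NULL
  Ff <- matrix(0, n_points, k)
  if (any(field$loading_truth != 0)) {
    for (j in seq_len(k)) Ff[, j] <- Lc %*% stats::rnorm(n_points)
  }
  logx <- matrix(rep(field$mean_log, each = n_points), n_points, D) +
    Ff %*% t(field$loading_truth)
  if (field$gp_sill > 0) {
    for (d in seq_len(D))
      logx[, d] <- logx[, d] + sqrt(field$gp_sill) * (Lc %*% stats::rnorm(n_points))
  }
  if (field$nugget > 0) {
    logx <- logx + matrix(stats::rnorm(n_points * D, sd = sqrt(field$nugget)),
                          n_points, D)
  }
  conc <- exp(logx)
  colnames(conc) <- field$elements
  colnames(Ff) <- paste0("F", seq_len(k))
  structure(list(coords = coords, concentrations = conc,
                 factor_fields = Ff, field = field),
            class = "sample_points")
}

#' Generate a rectangular lattice of areal units with queen contiguity
#'
#' `nx * ny` unit cells with centroids at cell centres, numbered row-major
#' (west to east, then south to north). Cells touching by an edge or a
#' corner are neighbours; the resulting graph is connected.
#'
#' @param nx,ny lattice dimensions, both >= 2.
#' @return object of class `area_table`: `areas` (data.frame `area_id`,
#'   `x`, `y`), `neighbors` (list of integer vectors), `edges` (two-column
#'   matrix, each undirected edge once, first column < second), `nx`, `ny`.
#' @export
generate_area_lattice <- function(nx, ny) {
  stopifnot(nx >= 2, ny >= 2)
  n <- nx * ny
  id <- seq_len(n)
  col <- (id - 1) %% nx + 1
  row <- (id - 1) %/% nx + 1
  nbrs <- vector("list", n)
  for (i in id) {
    dc <- rep(-1:1, times = 3); dr <- rep(-1:1, each = 3)
    cc <- col[i] + dc; rr <- row[i] + dr
    ok <- cc >= 1 & cc <= nx & rr >= 1 & rr <= ny & !(dc == 0 & dr == 0)
    nbrs[[i]] <- sort((rr[ok] - 1) * nx + cc[ok])
  }
  edges <- do.call(rbind, lapply(id, function(i) {
    j <- nbrs[[i]][nbrs[[i]] > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  dimnames(edges) <- list(NULL, c("area_a", "area_b"))
  structure(list(areas = data.frame(area_id = id, x = col - 0.5, y = row - 0.5),
                 neighbors = nbrs, edges = edges, nx = nx, ny = ny),
            class = "area_table")
}

#' Draw from the intrinsic CAR (ICAR) distribution on a graph
#'
#' Exact draw via the eigendecomposition of the graph Laplacian `L = D - W`:
#' only eigenvectors with non-null eigenvalue are sampled, each with
#' variance `1 / (tau_u * lambda)`, which enforces a sum-to-zero constraint
#' within every connected component. Exact and simple for a few thousand
#' areas.
#'
#' @param structure an `icar_structure` from [build_icar()] (an
#'   `area_table` is accepted and converted).
#' @param tau_u precision (> 0); `Inf` returns the zero vector.
#' @return numeric vector of length n, summing to zero per component.
#' @export
simulate_icar <- function(structure, tau_u) {
  if (inherits(structure, "area_table")) structure <- build_icar(structure)
  stopifnot(tau_u > 0)
  n <- structure$n
  if (is.infinite(tau_u)) return(numeric(n))
  L <- icar_laplacian(structure)
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values)
  z <- stats::rnorm(sum(pos))
  u <- as.vector(e$vectors[, pos, drop = FALSE] %*%
                   (z / sqrt(tau_u * e$values[pos])))
  # re-centre per component to remove accumulated rounding
  for (cmp in unique(structure$components))
    u[structure$components == cmp] <-
      u[structure$components == cmp] - mean(u[structure$components == cmp])
  u
}

#' Generate sociodemographic covariates for areal units
#'
#' Emulates census-style town indicators: population-size category (rural /
#' semi-urban / urban, entering the design as two indicators with rural as
#' reference), percentages of illiteracy, farmers and unemployment, mean
#' persons per household and mean income.
#'
#' @param n number of areas.
#' @param seed integer seed.
#' @return data.frame with columns `semi_urban`, `urban`,
#'   `illiteracy_pct`, `farmers_pct`, `unemployment_pct`,
#'   `persons_per_household`, `mean_income`.
#' @export
generate_soc_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  size <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  data.frame(
    semi_urban = as.integer(size == 2),
    urban = as.integer(size == 3),
    illiteracy_pct = pmax(stats::rnorm(n, 4, 2), 0),
    farmers_pct = pmax(stats::rnorm(n, 15, 8), 0),
    unemployment_pct = pmax(stats::rnorm(n, 12, 5), 0),
    persons_per_household = pmax(stats::rnorm(n, 3, 0.4), 1),
    mean_income = exp(stats::rnorm(n, log(18000), 0.25)))
}

# Design columns for sociodemographic covariates: every column centred
# (decorrelates the coefficients from the intercept without changing
# them), continuous columns additionally standardised so effects are per
# SD. Used identically by the simulator and the fitter, so effects are
# recoverable on the same scale.
soc_design <- function(soc) {
  soc <- as.data.frame(soc)
  X <- as.matrix(soc)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    s <- if (all(v %in% c(0, 1))) 1 else stats::sd(v)
    X[, j] <- (v - mean(v)) / if (s > 0) s else 1
  }
  X
}

#' Simulate mortality counts from the BYM ecological model
#'
#' Fills an areal lattice with expected counts `E_i` (log-uniform over
#' `expected_range`), spatial effects `u` (ICAR with precision `tau_u`,
#' sum-to-zero), unstructured effects `v` (iid normal with precision
#' `tau_v`), relative risks
#' `lambda_i = exp(alpha + sum_j beta_j F_ij + sum_k delta_k Soc_ik + u_i
#' + v_i)` and observed deaths `O_i ~ Poisson(E_i lambda_i)`. The true
#' latent values are recorded in the `truth` attribute for recovery tests.
#'
#' @param lattice an `area_table` from [generate_area_lattice()]; its
#'   adjacency must be connected (the ICAR draw is undefined per component
#'   without extra constraints).
#' @param scores n x length(beta) matrix of factor scores (from the factor
#'   stage, or supplied directly in unit tests). `NULL` is allowed when
#'   `beta` is empty or all zero.
#' @param truth a `truth_params` object.
#' @param expected_range positive interval for `E_i` (default 20 to 200
#'   expected deaths, the scale of multi-year town-level counts).
#' @param soc data.frame of sociodemographic covariates; generated by
#'   [generate_soc_covariates()] when omitted.
#' @param seed overrides `truth$seed` if given.
#' @return the `area_table` with `areas` gaining columns `observed`,
#'   `expected` and the soc covariates; attribute `truth` holds the
#'   parameters plus the simulated `u`, `v`, `lambda`.
#' @export
simulate_mortality <- function(lattice, scores, truth = truth_params(),
                               expected_range = c(20, 200), soc = NULL,
                               seed = truth$seed) {
  stopifnot(inherits(lattice, "area_table"),
            all(expected_range > 0), length(expected_range) == 2)
  n <- nrow(lattice$areas)
  structure_ <- build_icar(lattice)
  if (structure_$n_components > 1)
    stop("adjacency graph is disconnected: ICAR simulation requires a connected graph")
  if (is.null(scores)) scores <- matrix(0, n, length(truth$beta))
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == n, ncol(scores) == length(truth$beta))
  set.seed(seed)
  if (is.null(soc)) soc <- generate_soc_covariates(n, seed = seed)
  stopifnot(nrow(soc) == n, ncol(soc) == length(truth$delta))
  E <- exp(stats::runif(n, log(expected_range[1]), log(expected_range[2])))
  u <- simulate_icar(structure_, truth$tau_u)
  v <- if (is.infinite(truth$tau_v)) numeric(n) else
    stats::rnorm(n, sd = 1 / sqrt(truth$tau_v))
  lp <- truth$alpha + as.vector(scores %*% truth$beta) +
    as.vector(soc_design(soc) %*% truth$delta) + u + v
  lambda <- exp(lp)
  O <- stats::rpois(n, E * lambda)
  lattice$areas$observed <- O
  lattice$areas$expected <- E
  lattice$areas <- cbind(lattice$areas, soc)
  lattice$soc_names <- names(soc)
  attr(lattice, "truth") <- c(unclass(truth), list(u = u, v = v, lambda = lambda))
  lattice
}
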