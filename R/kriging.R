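# Ordinary kriging of element concentrations to area centroids:
# Matheron semivariogram -> WLS variogram fit -> OK system per target.

#' Evaluate a variogram model
#'
#' Semivariance `gamma(h)` for the supported isotropic families. By
#' definition `gamma(0) = 0`; the nugget is the limit from the right.
#'
#' @param model a `variogram_model` (or list with `family`, `nugget`,
#'   `partial_sill`, `range`).
#' @param h numeric vector of distances, >= 0.
#' @return semivariances, same length as `h`.
#' @export
variogram_gamma <- function(model, h) {
  stopifnot(all(h >= 0))
  ng <- model$nugget; ps <- model$partial_sill; rg <- model$range
  g <- switch(model$family,
    exponential = ng + ps * (1 - exp(-h / rg)),
    spherical = {
      hr <- pmin(h / rg, 1)
      ng + ps * (1.5 * hr - 0.5 * hr^3)
    },
    gaussian = ng + ps * (1 - exp(-(h / rg)^2)),
    stop("unknown variogram family: ", model$family)
  )
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by Euclidean distance and computes
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` per bin. Bin centres are the
#' mean pair distance within each bin; empty bins are dropped.
#'
#' @param coords n x 2 matrix of planar coordinates.
#' @param values numeric vector of length n.
#' @param n_bins number of equal-width distance bins.
#' @param max_dist maximum pair distance retained; default half the largest
#'   pair distance (a standard rule of thumb — long lags are pair-poor).
#' @return object of class `empirical_semivariogram`: list with
#'   `bin_centers`, `gamma`, `n_pairs`, `max_dist`.
#' @export
empirical_semivariogram <- function(coords, values, n_bins = 15, max_dist = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2, nrow(coords) == length(values))
  d <- as.vector(stats::dist(coords))
  if (is.null(max_dist)) max_dist <- max(d) / 2
  stopifnot(max_dist > 0)
  sq <- as.vector(stats::dist(values))^2
  keep <- d <= max_dist & d > 0
  if (!any(keep)) stop("no point pairs within max_dist")
  d <- d[keep]; sq <- sq[keep]
  brk <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(d, brk, include.lowest = TRUE, labels = FALSE)
  np <- tabulate(bin, nbins = n_bins)
  nonempty <- which(np > 0)
  gam <- vapply(nonempty, function(b) sum(sq[bin == b]) / (2 * np[b]), 0)
  ctr <- vapply(nonempty, function(b) mean(d[bin == b]), 0)
  structure(list(bin_centers = ctr, gamma = gam, n_pairs = np[nonempty],
                 max_dist = max_dist),
            class = "empirical_semivariogram")
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises the Cressie-weighted objective
#' `sum n_pairs * (gamma_emp / gamma_model - 1)^2` (weights
#' `n_pairs / gamma_model^2`) over non-negative `(nugget, partial_sill,
#' range)` with box-constrained quasi-Newton iterations from several
#' starting ranges.
#'
#' @param emp an `empirical_semivariogram` with >= 3 retained bins.
#' @param family one of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @return object of class `variogram_model`: `family`, `nugget`,
#'   `partial_sill`, `range`, `sill`, `objective`, `pure_nugget` flag (a
#'   near-zero partial sill is flagged, not fatal).
#' @export
fit_variogram_model <- function(emp, family = c("exponential", "spherical", "gaussian")) {
  family <- match.arg(family)
  stopifnot(inherits(emp, "empirical_semivariogram"), length(emp$gamma) >= 3)
  g <- emp$gamma; h <- emp$bin_centers; np <- emp$n_pairs
  scale_g <- max(g, 1e-12)

  obj <- function(par) {
    m <- list(family = family, nugget = par[1], partial_sill = par[2], range = par[3])
    gm <- pmax(variogram_gamma(m, h), 1e-10 * scale_g)
    sum(np * (g / gm - 1)^2)
  }
  sill0 <- max(mean(g[h >= stats::median(h)]), 1e-10)
  nug0 <- max(min(g[1], 0.5 * sill0), 0)
  best <- NULL
  for (r0 in emp$max_dist * c(0.05, 0.15, 0.3, 0.6, 1)) {
    fit <- try(stats::optim(
      c(nug0, max(sill0 - nug0, 1e-8), r0), obj, method = "L-BFGS-B",
      lower = c(0, 0, 1e-8 * emp$max_dist),
      upper = c(2 * sill0, 4 * sill0, 100 * emp$max_dist),
      control = list(factr = 10, maxit = 500)), silent = TRUE)
    if (!inherits(fit, "try-error") && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("variogram fit failed for all starting values")
  # polish with Nelder-Mead from the best box-constrained solution
  pol <- stats::optim(best$par, function(p) if (any(p[1:2] < 0) || p[3] <= 0) Inf else obj(p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (pol$value < best$value) best <- pol
  par <- best$par
  # a fit whose curve barely rises over the observed lags is degenerate:
  # collapse it to the canonical pure-nugget representation
  mfit <- list(family = family, nugget = par[1], partial_sill = par[2],
               range = par[3])
  rise <- variogram_gamma(mfit, emp$max_dist) -
    variogram_gamma(mfit, 1e-6 * emp$max_dist)
  pure_nugget <- par[2] < 1e-8 * scale_g || rise < 1e-6 * max(par[1] + par[2], scale_g)
  if (pure_nugget) {
    par <- c(sum(np * g) / sum(np), 0, emp$max_dist)
    warning("degenerate variogram fit: partial sill ~ 0 (pure nugget)")
  }
  structure(list(family = family, nugget = par[1], partial_sill = par[2],
                 range = par[3], sill = par[1] + par[2],
                 objective = best$value, pure_nugget = pure_nugget),
            class = "variogram_model")
}

# Average values at exactly duplicated coordinates (OK system is singular
# otherwise).
dedupe_samples <- function(coords, values) {
  key <- paste(coords[, 1], coords[, 2], sep = "\r")
  if (!anyDuplicated(key)) return(list(coords = coords, values = values))
  warning("duplicate sample coordinates: averaging values per location")
  agg <- tapply(values, key, mean)
  first <- !duplicated(key)
  ord <- match(key[first], names(agg))
  list(coords = coords[first, , drop = FALSE], values = as.vector(agg[ord]))
}

#' Ordinary kriging prediction
#'
#' For each target solves the ordinary-kriging system
#' `[Gamma 1; 1' 0] [w; mu] = [gamma0; 1]` on the `neighborhood` nearest
#' samples (stable tie-break by sample index), giving the best linear
#' unbiased predictor `w'z` with kriging variance `w'gamma0 + mu`. Weights
#' sum to one by construction; with a zero nugget the predictor is exact at
#' sample locations. Duplicate sample coordinates are averaged with a
#' warning.
#'
#' @param coords n x 2 sample coordinates.
#' @param values sample values (length n).
#' @param model a `variogram_model`.
#' @param targets m x 2 target coordinates.
#' @param neighborhood number of nearest samples per target, or `"all"`.
#' @param return_weights keep the weight vector per target (diagnostics).
#' @return object of class `kriging_result`: `predictions`,
#'   `kriging_variance` (>= 0), optionally `weights` (list) and `lagrange`.
#' @export
ordinary_kriging_predict <- function(coords, values, model, targets,
                                     neighborhood = 32, return_weights = FALSE) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  stopifnot(nrow(targets) >= 1, ncol(coords) == 2, ncol(targets) == 2)
  dd <- dedupe_samples(coords, values)
  coords <- dd$coords; values <- dd$values
  n <- nrow(coords)
  k <- if (identical(neighborhood, "all")) n else min(neighborhood, n)
  m <- nrow(targets)
  pred <- numeric(m); kv <- numeric(m); lag <- numeric(m)
  wts <- if (return_weights) vector("list", m) else NULL

  full <- k == n
  if (full) {
    G <- variogram_gamma(model, as.matrix(stats::dist(coords)))
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  }
  for (t in seq_len(m)) {
    d0 <- sqrt((coords[, 1] - targets[t, 1])^2 + (coords[, 2] - targets[t, 2])^2)
    if (full) {
      idx <- seq_len(n); At <- A
    } else {
      idx <- order(d0, seq_len(n))[seq_len(k)]
      Gt <- variogram_gamma(model, as.matrix(stats::dist(coords[idx, , drop = FALSE])))
      At <- rbind(cbind(Gt, 1), c(rep(1, k), 0))
    }
    g0 <- variogram_gamma(model, d0[idx])
    sol <- solve(At, c(g0, 1))
    w <- sol[seq_along(idx)]
    pred[t] <- sum(w * values[idx])
    kv[t] <- max(sum(w * g0) + sol[length(sol)], 0)
    lag[t] <- sol[length(sol)]
    if (return_weights) wts[[t]] <- stats::setNames(w, idx)
  }
  structure(list(predictions = pred, kriging_variance = kv, lagrange = lag,
                 weights = wts),
            class = "kriging_result")
}

#' Krige a multi-element composition to target locations
#'
#' Applies, per element, the semivariogram estimate, WLS model fit and
#' ordinary kriging prediction, and returns a strictly positive
#' composition table at the targets. Kriging is performed on
#' log-concentrations and back-transformed by exponentiation: mg/kg data
#' are heavily right-skewed and downstream clr work requires positivity.
#' Any non-positive back-transformed prediction (impossible for finite
#' log-scale predictions, but guarded) is clipped to the smallest positive
#' observed value of that element.
#'
#' @param samples a `sample_points` object (list with `coords` and positive
#'   `concentrations` matrix), as produced by [generate_sample_points()].
#' @param targets m x 2 matrix of target (centroid) coordinates.
#' @param n_bins,max_dist passed to [empirical_semivariogram()].
#' @param family variogram family (default exponential).
#' @param neighborhood passed to [ordinary_kriging_predict()].
#' @return list of class `kriged_composition`: `predictions` (m x D
#'   positive matrix), `variograms` (per-element `variogram_model`),
#'   `range_report` (data.frame of observed vs interpolated min/max per
#'   element — interpolation typically narrows the range of
#'   determinations, reported rather than asserted).
#' @export
krige_composition <- function(samples, targets, n_bins = 15, max_dist = NULL,
                              family = "exponential", neighborhood = 32) {
  conc <- as_composition_matrix(samples$concentrations)
  coords <- as.matrix(samples$coords)
  targets <- as.matrix(targets)
  D <- ncol(conc)
  out <- matrix(NA_real_, nrow(targets), D, dimnames = list(NULL, colnames(conc)))
  vgs <- vector("list", D); names(vgs) <- colnames(conc)
  for (d in seq_len(D)) {
    lz <- log(conc[, d])
    emp <- empirical_semivariogram(coords, lz, n_bins = n_bins, max_dist = max_dist)
    vg <- fit_variogram_model(emp, family = family)
    kr <- ordinary_kriging_predict(coords, lz, vg, targets, neighborhood = neighborhood)
    p <- exp(kr$predictions)
    minpos <- min(conc[, d])
    p[!is.finite(p) | p <= 0] <- minpos
    out[, d] <- p
    vgs[[d]] <- vg
  }
  rr <- data.frame(element = colnames(conc),
                   obs_min = apply(conc, 2, min), obs_max = apply(conc, 2, max),
                   pred_min = apply(out, 2, min), pred_max = apply(out, 2, max),
                   row.names = NULL)
  rr$range_narrowed <- rr$pred_min >= rr$obs_min & rr$pred_max <= rr$obs_max
  structure(list(predictions = out, variograms = vgs, range_report = rr),
            class = "kriged_composition")
}
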