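# Robust principal factor analysis of clr-transformed geochemistry:
# MCD correlation -> iterated PFA -> varimax rotation -> regression scores.

# Moore-Penrose pseudo-inverse of a symmetric matrix via eigendecomposition.
pseudo_inverse_sym <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

#' Robust correlation matrix via minimum covariance determinant
#'
#' Correlation derived from an MCD scatter estimate at support fraction
#' `mcd_fraction` (the fraction of observations the determinant is
#' minimised over). `mcd_fraction = 1` returns the classical Pearson
#' correlation. clr-transformed data are rank deficient (rows sum to
#' zero), and the MCD is undefined on collinear data, so the estimate is
#' computed on the full-rank principal subspace of the data and mapped
#' back to the original variables; the result then carries attributes
#' `rank_deficient` and `min_eigenvalue` flagging the near-zero
#' eigenvalue.
#'
#' @param y n x D numeric matrix, n > rank of the data.
#' @param mcd_fraction support fraction in `[0.5, 1]` (default 0.75).
#' @param seed optional integer; the MCD uses random subsampling for large
#'   n, so fixing this makes the estimate reproducible.
#' @return D x D correlation matrix (unit diagonal, symmetric), with
#'   attributes `rank_deficient` (logical) and `min_eigenvalue`.
#' @export
robust_correlation <- function(y, mcd_fraction = 0.75, seed = NULL) {
  y <- as.matrix(y)
  n <- nrow(y); D <- ncol(y)
  stopifnot(mcd_fraction >= 0.5, mcd_fraction <= 1, n > 2)
  if (mcd_fraction == 1) {
    R <- stats::cor(y)
  } else {
    ev <- eigen(stats::cov(y), symmetric = TRUE)
    rank <- sum(ev$values > 1e-10 * max(ev$values))
    if (n <= rank) stop("need more rows than the rank of the data for MCD")
    if (!is.null(seed)) set.seed(seed)
    if (rank < D) {
      V <- ev$vectors[, seq_len(rank), drop = FALSE]
      z <- sweep(y, 2, colMeans(y)) %*% V
      q <- max(floor(mcd_fraction * n), floor((n + rank + 1) / 2))
      S <- V %*% MASS::cov.rob(z, method = "mcd", quantile.used = q)$cov %*% t(V)
    } else {
      q <- max(floor(mcd_fraction * n), floor((n + D + 1) / 2))
      S <- MASS::cov.rob(y, method = "mcd", quantile.used = q)$cov
    }
    R <- stats::cov2cor(S)
    dimnames(R) <- list(colnames(y), colnames(y))
  }
  diag(R) <- 1
  eR <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  attr(R, "rank_deficient") <- min(eR) < 1e-8 * max(eR)
  attr(R, "min_eigenvalue") <- min(eR)
  R
}

#' Iterated principal factor analysis
#'
#' Places squared-multiple-correlation estimates of the communalities on
#' the diagonal of the correlation matrix, eigendecomposes the reduced
#' matrix, takes the top-`k` `eigenvector * sqrt(eigenvalue)` loadings,
#' updates the communalities from the loadings, and iterates until the
#' largest communality change is below `tol`. Negative eigenvalues of the
#' reduced matrix (including the near-zero one induced by the clr
#' constraint) are excluded from the factor space.
#'
#' @param R D x D correlation matrix.
#' @param k number of factors, `k < D` (default 4).
#' @param max_iter,tol iteration controls; the default tolerance on the
#'   largest communality change (1e-4) is of the order used by standard
#'   iterated-PFA implementations.
#' @return object of class `pfa_fit`: `loadings` (unrotated D x k),
#'   `communalities` (in `[0, 1]`), `eigenvalues` of the final reduced
#'   matrix, `explained_share` (per-factor fractions of total variance D),
#'   `cumulative_share`, `converged`, `iterations`. The accounting
#'   identity `sum(communalities)/D == cumulative_share` holds exactly.
#' @export
principal_factor_analysis <- function(R, k = 4, max_iter = 2000, tol = 1e-4) {
  R <- as.matrix(R)
  D <- ncol(R)
  stopifnot(k >= 1, k < D, isSymmetric(unname(R), tol = 1e-8))
  # SMC start; pseudo-inverse handles the singular clr case (SMC -> 1)
  Rinv <- tryCatch(solve(R), error = function(e) pseudo_inverse_sym(R))
  h <- pmin(pmax(1 - 1 / pmax(diag(Rinv), 1), 0), 1)
  converged <- FALSE
  L <- matrix(0, D, k)
  ev <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    ev <- e$values
    lam <- pmax(ev[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] * rep(sqrt(lam), each = D)
    hn <- pmin(rowSums(L^2), 1)
    if (max(abs(hn - h)) < tol) {
      h <- hn; converged <- TRUE; break
    }
    h <- hn
  }
  if (!converged) warning("principal factor analysis did not converge in ",
                          max_iter, " iterations; returning last iterate")
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(k))
  share <- colSums(L^2) / D
  structure(list(loadings = L, communalities = h, eigenvalues = ev,
                 explained_share = share, cumulative_share = sum(share),
                 converged = converged, iterations = it),
            class = "pfa_fit")
}

# Normalised varimax criterion: summed variance of squared loadings per
# factor (rows Kaiser-normalised upstream when requested).
varimax_criterion <- function(W) {
  D <- nrow(W)
  sum(colSums(W^4) - colSums(W^2)^2 / D)
}

#' Varimax rotation by pairwise plane rotations
#'
#' Orthogonal rotation maximising the (Kaiser-normalised) varimax
#' criterion: cycles over factor pairs, solving each planar rotation angle
#' in closed form, until a full sweep improves the criterion by less than
#' `tol`. The criterion is nondecreasing across sweeps by construction and
#' the trace is returned so callers can assert it. Row communalities are
#' invariant because the rotation is orthogonal.
#'
#' @param loadings D x k loading matrix, k >= 2 (e.g. from
#'   [principal_factor_analysis()]).
#' @param normalize Kaiser row-normalisation before rotation (default TRUE).
#' @param tol convergence tolerance on the criterion (default 1e-10).
#' @param max_sweeps cap on full sweeps.
#' @return object of class `factor_model`: rotated `loadings`, `rotation`
#'   (k x k orthogonal), `communalities`, `explained_share` per rotated
#'   factor, `cumulative_share`, `criterion_trace`, `sweeps`.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, tol = 1e-10,
                           max_sweeps = 500) {
  A <- as.matrix(loadings)
  D <- nrow(A); k <- ncol(A)
  stopifnot(k >= 2)
  h <- sqrt(rowSums(A^2))
  hs <- ifelse(h < 1e-12, 1, h)
  W <- if (normalize) A / hs else A
  Rot <- diag(k)
  trace <- varimax_criterion(W)
  for (sweep in seq_len(max_sweeps)) {
    for (p in seq_len(k - 1)) for (q in seq((p + 1), k)) {
      x <- W[, p]; y <- W[, q]
      u <- x^2 - y^2; v <- 2 * x * y
      A_ <- sum(u); B_ <- sum(v)
      C_ <- sum(u^2 - v^2); D_ <- 2 * sum(u * v)
      num <- D_ - 2 * A_ * B_ / D
      den <- C_ - (A_^2 - B_^2) / D
      phi <- atan2(num, den) / 4
      if (abs(phi) > 1e-14) {
        cs <- cos(phi); sn <- sin(phi)
        W[, p] <- cs * x + sn * y
        W[, q] <- -sn * x + cs * y
        rp <- Rot[, p]
        Rot[, p] <- cs * rp + sn * Rot[, q]
        Rot[, q] <- -sn * rp + cs * Rot[, q]
      }
    }
    crit <- varimax_criterion(W)
    if (crit < trace[length(trace)] - 1e-12)
      stop("varimax criterion decreased across a sweep (numerical fault)")
    improved <- crit - trace[length(trace)]
    trace <- c(trace, crit)
    if (improved < tol) break
  }
  L <- if (normalize) W * hs else W
  dimnames(L) <- dimnames(A)
  if (is.null(colnames(L))) colnames(L) <- paste0("F", seq_len(k))
  share <- colSums(L^2) / D
  structure(list(loadings = L, rotation = Rot, communalities = rowSums(L^2),
                 explained_share = share, cumulative_share = sum(share),
                 criterion_trace = trace, sweeps = length(trace) - 1),
            class = "factor_model")
}

#' Factor scores by the regression (Thomson) method
#'
#' Scores `F = y_std R^+ Lambda`, with `y_std` the column-standardised
#' data, `R` the correlation matrix used in fitting and `Lambda` the
#' rotated loadings. The clr constraint makes `R` singular, so a
#' Moore-Penrose pseudo-inverse (rank `D - 1`) is used. Score columns are
#' centred exactly.
#'
#' @param y n x D data matrix (clr coordinates).
#' @param model a `factor_model` (or any list with `loadings`).
#' @param R correlation matrix used for the fit; classical correlation of
#'   `y` if omitted.
#' @return n x k matrix of scores, columns named after the factors,
#'   column means zero.
#' @export
factor_scores <- function(y, model, R = NULL) {
  y <- as.matrix(y)
  L <- model$loadings
  stopifnot(ncol(y) == nrow(L))
  if (is.null(R)) R <- stats::cor(y)
  # population-sd standardisation: invariant under row duplication
  mu <- colMeans(y)
  sd_pop <- sqrt(colMeans(y^2) - mu^2)
  ys <- sweep(sweep(y, 2, mu), 2, ifelse(sd_pop < 1e-300, 1, sd_pop), "/")
  Fs <- ys %*% pseudo_inverse_sym(unname(as.matrix(R))) %*% L
  Fs <- sweep(Fs, 2, colMeans(Fs))
  colnames(Fs) <- colnames(L)
  rownames(Fs) <- rownames(y)
  Fs
}

#' Fix factor sign conventions
#'
#' Loading signs are arbitrary after extraction and rotation; for
#' interpretable relative risks each factor is flipped (loading column and
#' score column jointly) so that its largest-|loading| element is
#' positive. Idempotent.
#'
#' @param model a `factor_model`.
#' @param scores optional matching score matrix, flipped jointly.
#' @return list with `model`, `scores` (NULL if not given) and `flipped`
#'   (logical per factor).
#' @export
sign_align <- function(model, scores = NULL) {
  L <- model$loadings
  flip <- vapply(seq_len(ncol(L)), function(j) {
    L[which.max(abs(L[, j])), j] < 0
  }, logical(1))
  if (any(flip)) {
    s <- ifelse(flip, -1, 1)
    model$loadings <- sweep(L, 2, s, `*`)
    model$rotation <- sweep(model$rotation, 2, s, `*`)
    if (!is.null(scores)) scores <- sweep(scores, 2, s, `*`)
  }
  list(model = model, scores = scores, flipped = flip)
}

#' Robust PFA of a clr table, rotated and scored
#'
#' Convenience wrapper chaining [robust_correlation()],
#' [principal_factor_analysis()], [varimax_rotate()], [factor_scores()]
#' and [sign_align()] — the full dimension-reduction stage.
#'
#' @param y n x D clr matrix.
#' @param k number of factors (default 4).
#' @param mcd_fraction MCD support fraction (default 0.75).
#' @param seed passed to [robust_correlation()].
#' @return list with `model` (`factor_model`), `scores` (n x k, sign
#'   aligned), `correlation`, `pfa` (the unrotated `pfa_fit`).
#' @export
robust_pfa <- function(y, k = 4, mcd_fraction = 0.75, seed = NULL) {
  R <- robust_correlation(y, mcd_fraction = mcd_fraction, seed = seed)
  pfa <- principal_factor_analysis(R, k = k)
  model <- varimax_rotate(pfa$loadings)
  sc <- factor_scores(y, model, R = R)
  al <- sign_align(model, sc)
  list(model = al$model, scores = al$scores, correlation = R, pfa = pfa)
}
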