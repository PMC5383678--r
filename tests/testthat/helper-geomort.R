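# Shared fixtures and independent oracles for the test suite.

# Tucker congruence coefficient between two loading columns.
congruence <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Orthogonal Procrustes alignment of L onto target T: L %*% Q with
# Q = U V' from the SVD of L'T.
procrustes_align <- function(L, target) {
  s <- svd(t(L) %*% target)
  L %*% (s$u %*% t(s$v))
}

# Known 10 x 4 loading matrix with unit-diagonal implied correlation
# R = Lambda Lambda' + diag(uniqueness); used for factor-recovery oracles.
known_loading_model <- function() {
  L <- geomort:::default_loading_truth()
  # rescale rows so communalities stay below 0.95
  h2 <- rowSums(L^2)
  L <- L / sqrt(pmax(h2, 0.4)) * sqrt(pmin(h2 / max(h2) * 0.8 + 0.1, 0.95))
  R <- L %*% t(L)
  diag(R) <- 1
  list(loadings = L, R = R, uniqueness = 1 - rowSums(L^2))
}

# Naive-loop evaluation of the BYM log-posterior (independent of the
# vectorised implementation).
naive_log_posterior <- function(state, spec, structure, areas, scores) {
  a <- areas$areas
  X <- cbind(as.matrix(scores),
             geomort:::soc_design(a[, areas$soc_names, drop = FALSE]))
  bf <- c(state$beta, state$delta)
  total <- 0
  for (i in seq_len(nrow(a))) {
    lp <- state$alpha + state$u[i] + state$v[i]
    for (j in seq_along(bf)) lp <- lp + X[i, j] * bf[j]
    lam <- exp(lp)
    total <- total + a$observed[i] * log(a$expected[i] * lam) -
      a$expected[i] * lam
  }
  q <- 0
  for (r in seq_len(nrow(structure$edges))) {
    i <- structure$edges[r, 1]; j <- structure$edges[r, 2]
    q <- q + (state$u[i] - state$u[j])^2
  }
  total <- total +
    (structure$n - structure$n_components) / 2 * log(state$tau_u) -
    state$tau_u / 2 * q
  for (i in seq_len(structure$n))
    total <- total - state$tau_v / 2 * state$v[i]^2
  total <- total + structure$n / 2 * log(state$tau_v)
  total <- total - state$alpha^2 / (2 * spec$prior_var)
  for (j in seq_along(bf)) total <- total - bf[j]^2 / (2 * spec$prior_var)
  as.numeric(total +
    (spec$tau_shape - 1) * (log(state$tau_u) + log(state$tau_v)) -
    spec$tau_rate * (state$tau_u + state$tau_v))
}

# Random BYM state for a lattice with p1 factor and p2 soc covariates.
random_state <- function(n, p1, p2) {
  u <- rnorm(n); u <- u - mean(u)
  list(alpha = rnorm(1, 0, 0.3), beta = rnorm(p1, 0, 0.2),
       delta = rnorm(p2, 0, 0.2), u = u, v = rnorm(n, 0, 0.3),
       tau_u = rexp(1) + 0.5, tau_v = rexp(1) + 0.5)
}

# Small simulated dataset for regression tests: connected queen lattice,
# supplied scores, known truth.
small_bym_dataset <- function(nx = 12, ny = 12, beta = c(0.2, 0, 0, 0),
                              seed = 42, tau_u = 10, tau_v = 10,
                              expected_range = c(20, 200)) {
  lat <- generate_area_lattice(nx, ny)
  n <- nx * ny
  set.seed(seed)
  scores <- matrix(rnorm(n * length(beta)), n, length(beta))
  tr <- truth_params(alpha = 0, beta = beta, delta = rep(0, 7),
                     tau_u = tau_u, tau_v = tau_v, seed = seed + 1)
  at <- simulate_mortality(lat, scores, tr, expected_range = expected_range)
  list(areas = at, structure = build_icar(at), scores = scores, truth = tr)
}

fit_quick <- function(dat, iter = 2000, burnin = 1000, chains = 2, seed = 9,
                      thin = 2, ...) {
  spec <- regression_spec(c(paste0("F", seq_len(ncol(dat$scores))),
                            dat$areas$soc_names),
                          chains = chains, iter = iter, burnin = burnin,
                          thin = thin, seed = seed, ...)
  suppressWarnings(fit_bym(spec, dat$structure, dat$areas, dat$scores))
}
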