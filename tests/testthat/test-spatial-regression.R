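test_that("build_icar enumerates degrees, components and a zero-row-sum Laplacian", {
  st <- build_icar(generate_area_lattice(3, 3))
  expect_equal(st$degrees, c(3L, 5L, 3L, 5L, 8L, 5L, 3L, 5L, 3L))
  expect_equal(st$n_components, 1L)
  expect_true(all(abs(rowSums(icar_laplacian(st))) == 0))

  # two disjoint 2 x 2 blocks -> 2 components
  nbrs <- c(lapply(1:4, function(i) setdiff(1:4, i)),
            lapply(5:8, function(i) setdiff(5:8, i)))
  st2 <- build_icar(nbrs)
  expect_equal(st2$n_components, 2L)
  expect_equal(sort(unique(st2$components)), 1:2)

  bad <- list(2L, integer(0))  # 1 claims 2 as neighbour, not reciprocated
  expect_error(build_icar(bad), "asymmetric.*\\(1,2\\)")
  expect_error(build_icar(list(c(1L, 2L), 1L)), "self-adjacency")
})

test_that("log_posterior matches the hand-computed two-area example", {
  lat <- generate_area_lattice(2, 2)
  lat$areas <- lat$areas[1:2, ]
  lat$neighbors <- list(2L, 1L)
  lat$edges <- matrix(c(1L, 2L), 1)
  lat$areas$observed <- c(1L, 2L)
  lat$areas$expected <- c(1, 1)
  lat$soc_names <- NULL
  st <- build_icar(lat)
  spec <- regression_spec(character(0))
  state <- list(alpha = 0, beta = numeric(0), delta = numeric(0),
                u = c(0, 0), v = c(0, 0), tau_u = 1, tau_v = 1)
  # Poisson kernel (1*0 - 1) + (2*0 - 1) = -2; ICAR and v kernels vanish at
  # tau = 1, u = v = 0; gamma priors contribute -rate * (tau_u + tau_v)
  expected <- -2 - spec$tau_rate * 2
  expect_equal(log_posterior(state, spec, st, lat, NULL), expected,
               tolerance = 1e-12)
})

test_that("vectorised log_posterior equals the naive-loop oracle on random states", {
  dat <- small_bym_dataset(nx = 7, ny = 7, beta = c(0.2, -0.1), seed = 13)
  spec <- regression_spec(c("F1", "F2", dat$areas$soc_names))
  set.seed(14)
  for (r in 1:30) {
    st <- random_state(49, 2, 7)
    expect_equal(log_posterior(st, spec, dat$structure, dat$areas, dat$scores),
                 naive_log_posterior(st, spec, dat$structure, dat$areas,
                                     dat$scores),
                 tolerance = 1e-10)
  }
})

test_that("the tau_u full conditional is the closed-form gamma (density-ratio check)", {
  dat <- small_bym_dataset(nx = 6, ny = 6, beta = c(0.1), seed = 15)
  spec <- regression_spec(c("F1", dat$areas$soc_names))
  set.seed(16)
  st <- random_state(36, 1, 7)
  e <- dat$structure$edges
  q <- sum((st$u[e[, 1]] - st$u[e[, 2]])^2)
  shape <- spec$tau_shape + (36 - dat$structure$n_components) / 2
  rate <- spec$tau_rate + q / 2
  lp_at <- function(tau) {
    s <- st; s$tau_u <- tau
    log_posterior(s, spec, dat$structure, dat$areas, dat$scores)
  }
  for (pair in list(c(0.5, 2), c(1, 7), c(3, 11))) {
    lhs <- lp_at(pair[1]) - lp_at(pair[2])
    rhs <- dgamma(pair[1], shape, rate, log = TRUE) -
      dgamma(pair[2], shape, rate, log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("summarize_rr closed forms and the credibility-interval flag logic", {
  z <- matrix(0, 100, 1, dimnames = list(NULL, "F1"))
  s0 <- summarize_rr(z)
  expect_equal(s0$RR, 1)
  expect_equal(c(s0$ci_low, s0$ci_high), c(1, 1))
  expect_false(s0$significant)

  s2 <- summarize_rr(matrix(log(2), 50, 1, dimnames = list(NULL, "F1")))
  expect_equal(s2$RR, 2)

  # interval shapes mirroring published male/female rows for one factor:
  # [1.009, 1.054] -> significant; [0.987, 1.032] -> not
  mk <- function(lo, hi) {
    qs <- log(c(lo, hi))
    m <- mean(qs); s <- diff(qs) / (2 * qnorm(0.975))
    matrix(qnorm(seq(0.0005, 0.9995, length.out = 4000), m, s),
           dimnames = list(NULL, "F1"))
  }
  sig <- summarize_rr(mk(1.009, 1.054))
  expect_true(sig$significant)
  expect_gt(sig$ci_low, 1)
  ns <- summarize_rr(mk(0.987, 1.032))
  expect_false(ns$significant)
  expect_lt(ns$ci_low, 1)
  expect_gt(ns$ci_high, 1)

  set.seed(17)
  draws <- matrix(rnorm(3000, 0.01, 0.2), 1000, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  s <- summarize_rr(draws)
  expect_true(all(s$ci_low <= s$RR + 1e-12 & s$RR <= s$ci_high + 1e-12))
  expect_equal(s$significant, s$ci_low > 1 | s$ci_high < 1)
})

test_that("split R-hat and ESS behave on reference chains", {
  set.seed(18)
  good <- list(rnorm(2000), rnorm(2000))
  expect_lt(split_rhat(good), 1.02)
  expect_gt(ess_chains(good), 1000)
  apart <- list(rnorm(500), rnorm(500) + 5)
  expect_gt(split_rhat(apart), 2)
  expect_true(is.na(split_rhat(list(rep(1, 100), rep(1, 100)))))
})

test_that("fit_bym recovers an injected effect and keeps u centred in every draw", {
  dat <- small_bym_dataset(nx = 15, ny = 15, beta = c(0.2, 0, 0, 0), seed = 19)
  fit <- fit_quick(dat, iter = 3000, burnin = 1500, seed = 19)
  rr <- fit$summary$rr
  expect_equal(rr$parameter[1:4], paste0("F", 1:4))
  b1 <- rr$coef_mean[rr$parameter == "F1"]
  expect_lt(abs(b1 - 0.2), 0.08)
  expect_true(rr$significant[rr$parameter == "F1"])
  for (ch in fit$u_draws)
    expect_lt(max(abs(rowSums(ch))), 1e-8)
  expect_true(all(fit$summary$lambda > 0))
  expect_equal(nrow(fit$draws[[1]]), (3000 - 1500) / 2)
})

test_that("flipping factor scores inverts the fitted relative risk", {
  dat <- small_bym_dataset(nx = 12, ny = 12, beta = c(0.25), seed = 23)
  fit <- fit_quick(dat, iter = 2500, burnin = 1250, seed = 23)
  datf <- dat
  datf$scores <- -dat$scores
  fitf <- fit_quick(datf, iter = 2500, burnin = 1250, seed = 23)
  b <- fit$summary$rr$coef_mean[1]
  bf <- fitf$summary$rr$coef_mean[1]
  # RR_flipped ~ 1 / RR within Monte-Carlo error
  expect_lt(abs(b + bf), 0.05)
})

test_that("a spike prior on tau_u shrinks the structured effect toward zero", {
  dat <- small_bym_dataset(nx = 10, ny = 10, beta = c(0.1), seed = 25,
                           tau_u = 2)
  loose <- fit_quick(dat, iter = 2000, burnin = 1000, seed = 25)
  tight <- fit_quick(dat, iter = 2000, burnin = 1000, seed = 25,
                     tau_shape = 1e6, tau_rate = 10)
  expect_gt(tight$summary$tau_u, 100 * loose$summary$tau_u)
  expect_lt(max(abs(tight$summary$u)), max(abs(loose$summary$u)))
})

test_that("isolated areas are excluded from the structured effect but kept overall", {
  lat <- generate_area_lattice(4, 4)
  # detach one corner completely
  iso <- 1L
  for (j in lat$neighbors[[iso]])
    lat$neighbors[[j]] <- setdiff(lat$neighbors[[j]], iso)
  lat$neighbors[[iso]] <- integer(0)
  lat$edges <- lat$edges[lat$edges[, 1] != iso & lat$edges[, 2] != iso, ]
  set.seed(26)
  lat$areas$observed <- rpois(16, 50)
  lat$areas$expected <- rep(50, 16)
  st <- build_icar(lat)
  spec <- regression_spec(character(0), chains = 2, iter = 800, burnin = 400,
                          thin = 2, seed = 26)
  expect_message(fit <- suppressWarnings(fit_bym(spec, st, lat, NULL)),
                 "isolated")
  expect_equal(unname(fit$summary$u[iso]), 0)
  expect_gt(max(abs(fit$summary$v)), 0)
})
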