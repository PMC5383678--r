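test_that("empirical semivariogram: constant field, hand-enumerated pairs, scale property", {
  set.seed(1)
  coords <- cbind(runif(30), runif(30))
  emp0 <- empirical_semivariogram(coords, rep(3.7, 30), n_bins = 5)
  expect_true(all(emp0$gamma == 0))

  # 3 collinear points at x = 0, 1, 2 with values 0, 1, 0:
  # pairs at distance 1 -> gamma = (1 + 1) / (2 * 2) = 0.5; at 2 -> 0
  emp <- empirical_semivariogram(cbind(0:2, 0), c(0, 1, 0),
                                 n_bins = 2, max_dist = 2)
  expect_equal(emp$bin_centers, c(1, 2))
  expect_equal(emp$gamma, c(0.5, 0))
  expect_equal(emp$n_pairs, c(2L, 1L))

  v <- rnorm(30)
  e1 <- empirical_semivariogram(coords, v, n_bins = 6)
  e2 <- empirical_semivariogram(coords, 2 * v, n_bins = 6)
  expect_equal(e2$gamma, 4 * e1$gamma)
  expect_true(all(diff(e1$bin_centers) > 0))
  expect_error(empirical_semivariogram(cbind(0:1, 0), c(0, 1), max_dist = 0.5),
               "no point pairs")
})

test_that("WLS variogram fit recovers noiseless exponential parameters to 1e-4", {
  h <- seq(0.05, 1, length.out = 12)
  truth <- structure(list(family = "exponential", nugget = 0.1,
                          partial_sill = 0.9, range = 0.3),
                     class = "variogram_model")
  emp <- structure(list(bin_centers = h, gamma = variogram_gamma(truth, h),
                        n_pairs = rep(50L, 12), max_dist = 1),
                   class = "empirical_semivariogram")
  fit <- fit_variogram_model(emp, "exponential")
  expect_equal(fit$nugget, 0.1, tolerance = 1e-4)
  expect_equal(fit$partial_sill, 0.9, tolerance = 1e-4)
  expect_equal(fit$range, 0.3, tolerance = 1e-4)
  # fitted curve nondecreasing over [0, max_dist]
  g <- variogram_gamma(fit, seq(1e-9, 1, length.out = 200))
  expect_true(all(diff(g) >= -1e-12))
})

test_that("flat empirical variogram yields a flagged pure-nugget model", {
  emp <- structure(list(bin_centers = seq(0.1, 1, 0.1), gamma = rep(0.5, 10),
                        n_pairs = rep(20L, 10), max_dist = 1),
                   class = "empirical_semivariogram")
  expect_warning(fit <- fit_variogram_model(emp), "pure nugget")
  expect_true(fit$pure_nugget)
  expect_lt(fit$partial_sill, 1e-6)
  expect_equal(fit$nugget, 0.5, tolerance = 1e-6)
})

test_that("ordinary kriging is exact at samples, honours constant fields, sums weights to 1", {
  set.seed(2)
  coords <- cbind(runif(8), runif(8))
  z <- rnorm(8)
  m0 <- structure(list(family = "exponential", nugget = 0,
                       partial_sill = 1, range = 0.3),
                  class = "variogram_model")
  at_sample <- ordinary_kriging_predict(coords, z, m0, coords[3, , drop = FALSE],
                                        neighborhood = "all")
  expect_equal(at_sample$predictions, z[3], tolerance = 1e-8)
  expect_lt(at_sample$kriging_variance, 1e-8)

  m1 <- structure(list(family = "exponential", nugget = 0.2,
                       partial_sill = 0.8, range = 0.3),
                  class = "variogram_model")
  targets <- cbind(runif(6), runif(6))
  const <- ordinary_kriging_predict(coords, rep(4.2, 8), m1, targets,
                                    neighborhood = 5)
  expect_equal(const$predictions, rep(4.2, 6), tolerance = 1e-10)
  kw <- ordinary_kriging_predict(coords, z, m1, targets, neighborhood = 5,
                                 return_weights = TRUE)
  for (w in kw$weights) expect_lt(abs(sum(w) - 1), 1e-10)
  expect_true(all(kw$kriging_variance >= 0))
})

test_that("kriging matches a dense augmented-system solve written out directly", {
  set.seed(3)
  coords <- cbind(c(0.1, 0.9, 0.4, 0.6, 0.2), c(0.2, 0.8, 0.7, 0.1, 0.9))
  z <- c(1.2, -0.5, 0.3, 2.1, 0.0)
  m <- structure(list(family = "exponential", nugget = 0.1,
                      partial_sill = 0.7, range = 0.4),
                 class = "variogram_model")
  target <- matrix(c(0.5, 0.5), 1)
  # brute-force oracle: build the augmented system from the gamma matrix
  G <- variogram_gamma(m, as.matrix(dist(coords)))
  A <- rbind(cbind(G, 1), c(rep(1, 5), 0))
  g0 <- variogram_gamma(m, sqrt(rowSums(sweep(coords, 2, target)^2)))
  sol <- solve(A, c(g0, 1))
  pred_oracle <- sum(sol[1:5] * z)
  var_oracle <- sum(sol[1:5] * g0) + sol[6]
  kr <- ordinary_kriging_predict(coords, z, m, target, neighborhood = "all")
  expect_equal(kr$predictions, unname(pred_oracle), tolerance = 1e-10)
  expect_equal(kr$kriging_variance, unname(var_oracle), tolerance = 1e-10)
  # the neighbourhood solver reduces to the dense solve when k >= n
  kr32 <- ordinary_kriging_predict(coords, z, m, target, neighborhood = 32)
  expect_equal(kr32$predictions, unname(pred_oracle), tolerance = 1e-10)
})

test_that("kriging predictions are translation equivariant", {
  set.seed(4)
  coords <- cbind(runif(20), runif(20))
  z <- rnorm(20)
  m <- structure(list(family = "spherical", nugget = 0.1,
                      partial_sill = 0.9, range = 0.5),
                 class = "variogram_model")
  targets <- cbind(runif(5), runif(5))
  k1 <- ordinary_kriging_predict(coords, z, m, targets, neighborhood = 8)
  k2 <- ordinary_kriging_predict(coords, z + 10, m, targets, neighborhood = 8)
  expect_equal(k2$predictions, k1$predictions + 10, tolerance = 1e-8)
})

test_that("duplicate sample coordinates are averaged with a warning", {
  coords <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0))
  z <- c(1, 3, 5, 7)
  m <- structure(list(family = "exponential", nugget = 0,
                      partial_sill = 1, range = 1),
                 class = "variogram_model")
  expect_warning(
    kr <- ordinary_kriging_predict(coords, z, m, matrix(c(0, 0), 1),
                                   neighborhood = "all"),
    "duplicate")
  expect_equal(kr$predictions, 2)  # average of the coincident samples
})

test_that("krige_composition returns a positive table and a range report", {
  set.seed(5)
  sp <- generate_sample_points(120, field = field_params(seed = 5))
  targets <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  kc <- krige_composition(sp, targets, n_bins = 10, neighborhood = 24)
  expect_equal(dim(kc$predictions), c(15L, 10L))
  expect_true(all(kc$predictions > 0))
  expect_equal(colnames(kc$predictions), colnames(sp$concentrations))
  expect_s3_class(kc$variograms[[1]], "variogram_model")
  expect_true(all(c("obs_min", "pred_min", "range_narrowed") %in%
                    names(kc$range_report)))

  # constant composition per element -> constant (pure-nugget) predictions
  spc <- sp
  spc$concentrations <- matrix(rep(c(10, 20), each = 120), 120, 2,
                               dimnames = list(NULL, c("A", "B")))
  kcc <- suppressWarnings(krige_composition(spc, targets, n_bins = 10))
  expect_equal(unname(kcc$predictions[, "A"]), rep(10, 15), tolerance = 1e-8)
  expect_equal(unname(kcc$predictions[, "B"]), rep(20, 15), tolerance = 1e-8)
})
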