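noiseless_data <- function(seed = 5) {
  d <- simulate_from_spec(n_locations = 10, n_years = 8,
                          coefs = c("(Intercept)" = log(4e-4), x1 = -1),
                          sigma_location = 0, sigma_cell = 0,
                          population = 1e6, n_noise_covariates = 1,
                          seed = seed)
  d$deaths <- d$true_rate * d$population  # exact expected deaths
  d$envelope <- d$deaths * 4
  d
}

test_that("the model pool enumerates subsets times response spaces deterministically", {
  pool <- enumerate_models(c("a", "b"))
  expect_length(pool, 6)  # (2^2 - 1) subsets x 2 spaces
  expect_length(enumerate_models("a"), 2)
  capped <- enumerate_models(c("a", "b"), max_models = 4)
  expect_length(capped, 4)
  expect_identical(vapply(capped, function(s) s$id, ""),
                   vapply(enumerate_models(c("a", "b"), max_models = 4),
                          function(s) s$id, ""))
  expect_error(enumerate_models(character(0)), "at least one")
})

test_that("the truth-generating model is near-exact out of sample on noiseless data", {
  d <- noiseless_data()
  pool <- list(model_spec("log_rate", "x1", random_intercept = FALSE),
               model_spec("log_rate", "z1", random_intercept = FALSE))
  pv <- suppressWarnings(holdout_pv(pool, d, folds = 4, seed = 2))
  truth_row <- pv[pv$id == "log_rate:x1", ]
  expect_lt(truth_row$rmse_level, 1e-6)
  expect_lt(truth_row$rmse_trend, 1e-6)
  # a pure-noise covariate cannot beat the generating model
  noise_row <- pv[pv$id == "log_rate:z1", ]
  if (nrow(noise_row)) {
    expect_gte(noise_row$rmse_level, truth_row$rmse_level)
  }
  # deterministic scoring under a fixed seed
  pv2 <- suppressWarnings(holdout_pv(pool, d, folds = 4, seed = 2))
  expect_identical(pv, pv2)
})

test_that("an impossible sign constraint screens out the whole pool", {
  d <- noiseless_data()
  pool <- list(model_spec("log_rate", "x1", random_intercept = FALSE,
                          expected_signs = c(x1 = 1)))  # true slope is -1
  expect_error(suppressWarnings(holdout_pv(pool, d, folds = 4, seed = 2)),
               "screen")
})

test_that("rank-exponential weights normalise and respect symmetry", {
  one <- tibble::tibble(id = "m1", rmse_level = 0.5, rmse_trend = 0.5)
  expect_equal(ensemble_weights(one)$weight, 1)

  two <- tibble::tibble(id = c("m1", "m2"), rmse_level = c(0.5, 0.5),
                        rmse_trend = c(0.5, 0.5))
  expect_equal(ensemble_weights(two)$weight, c(0.5, 0.5))

  three <- tibble::tibble(id = c("m1", "m2", "m3"),
                          rmse_level = c(0.1, 0.2, 0.3),
                          rmse_trend = c(0.1, 0.2, 0.3))
  w <- ensemble_weights(three, temperature = 1)$weight
  expect_equal(w, exp(-(1:3)) / sum(exp(-(1:3))))

  expect_error(ensemble_weights(three, temperature = 0), "positive")
})

test_that("zero-variance fits give identical draws equal to the point prediction", {
  d <- noiseless_data()
  pool <- list(model_spec("log_rate", "x1", random_intercept = FALSE))
  fits <- suppressWarnings(fit_pool(pool, d))
  fits[[1]]$vcov[] <- 0
  fits[[1]]$sigma <- 0
  w <- tibble::tibble(id = "log_rate:x1", combined_rank = 1, weight = 1)
  dc <- predict_draws(fits, w, d, n_draws = 10, seed = 1)
  point <- exp(predict_eta(fits[[1]], d)) * d$population
  expect_equal(dc$draws, matrix(point, nrow(d), 10), tolerance = 1e-12)
})

test_that("draw means converge to the draw-distribution expectation at N=1000", {
  d <- simulate_from_spec(seed = 8)
  d$envelope <- d$deaths * 4
  pool <- list(model_spec("log_rate", "x1", random_intercept = FALSE))
  fits <- fit_pool(pool, d)
  w <- tibble::tibble(id = pool[[1]]$id, combined_rank = 1, weight = 1)
  dc <- predict_draws(fits, w, d, n_draws = 1000, seed = 3)
  f <- fits[[1]]
  X <- stats::model.matrix(~x1, d)
  # lognormal mean: exp(eta + total variance / 2)
  v_tot <- rowSums((X %*% f$vcov) * X) + f$sigma^2
  expected <- exp(as.vector(X %*% f$beta) + v_tot / 2) * d$population
  rel <- abs(rowMeans(dc$draws) - expected) / expected
  expect_lt(stats::median(rel), 0.02)

  # bit-identical under a fixed seed
  dc2 <- predict_draws(fits, w, d, n_draws = 1000, seed = 3)
  expect_identical(dc$draws, dc2$draws)
})

test_that("mixed-model pool members fit, screen, and predict", {
  d <- simulate_from_spec(seed = 12, sigma_location = 0.3)
  d$envelope <- d$deaths * 4
  pool <- list(model_spec("log_rate", "x1", random_intercept = TRUE))
  fits <- fit_pool(pool, d)
  expect_true(fits[[1]]$ok)
  expect_gt(fits[[1]]$sigma_u, 0)
  w <- tibble::tibble(id = pool[[1]]$id, combined_rank = 1, weight = 1)
  dc <- predict_draws(fits, w, d, n_draws = 50, seed = 4)
  expect_equal(dim(dc), c(nrow(d), 50))
  expect_true(all(dc$draws >= 0))
})

test_that("negative binomial fits recover dispersion regimes", {
  # equidispersed counts: dispersion estimate collapses
  n_rep <- 100
  disp <- vapply(seq_len(n_rep), function(i) {
    counts <- withr::with_seed(i, rpois(500, 2))
    fit_negative_binomial(counts, exposure = 1000, n_draws = 10, seed = i)$dispersion
  }, numeric(1))
  expect_gte(mean(disp < 0.1), 0.9)

  # overdispersed counts: the fitted mean matches the sample-mean oracle.
  # With mu = 2 and size = 0.5 at n = 500, the mean estimator has variance
  # (mu + mu^2/size)/n, so the fraction of replicates within 10% of truth
  # has an exact asymptotic target rather than a round number.
  ok <- vapply(seq_len(n_rep), function(i) {
    counts <- withr::with_seed(1000 + i, rnbinom(500, mu = 2, size = 0.5))
    fit <- fit_negative_binomial(counts, exposure = 1000, n_draws = 10,
                                 seed = i)
    abs(fit$rate * 1000 - 2) / 2 < 0.1
  }, logical(1))
  p_theory <- 2 * stats::pnorm(0.2 / sqrt((2 + 4 / 0.5) / 500)) - 1
  expect_lt(abs(mean(ok) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / n_rep))

  # constant counts with constant exposure give the exact rate
  fit_k <- fit_negative_binomial(rep(4L, 20), exposure = 1000)
  expect_equal(fit_k$rate, 4 / 1000, tolerance = 1e-6)

  expect_warning(out <- fit_negative_binomial(rep(0L, 20), exposure = 1000),
                 "zero")
  expect_equal(out$draws, rep(0, 1000))
  expect_error(fit_negative_binomial(c(-1, 2), 10), "non-negative")
})

test_that("data-rich fits never see data from low-star locations", {
  d <- simulate_from_spec(n_locations = 6, seed = 3)
  stars <- stats::setNames(c(5L, 5L, 4L, 2L, 1L, 0L), unique(d$location))
  sp <- split_data_rich(d, stars, threshold = 4)
  expect_setequal(unique(sp$rich$location), names(stars)[stars >= 4])
  expect_equal(nrow(sp$poor), nrow(d))
})
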