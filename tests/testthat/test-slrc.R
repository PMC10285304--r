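test_that("ensemble tuning curves meet the rate constraints", {
  ens <- build_ensemble(1, 80, 75, 250, radius = 1.2, seed = 1)
  # silent at the intercept, max rate within range at the preferred radius
  for (i in seq_len(ens$n)) {
    r_icpt <- ensemble_rates(ens, ens$intercepts[i] * ens$encoders[i, 1])
    expect_equal(r_icpt[1, i], 0, tolerance = 1e-10)
    r_pref <- ensemble_rates(ens, ens$radius * ens$encoders[i, 1])
    expect_gte(r_pref[1, i], 75 - 1e-9)
    expect_lte(r_pref[1, i], 250 + 1e-9)
  }
  # rates are zero below the intercept
  below <- ensemble_rates(ens, (ens$intercepts[1] - 0.1) * ens$encoders[1, 1])
  expect_equal(below[1, 1], 0)
  expect_error(build_ensemble(1, 10, 250, 75, 1), "fr_min < fr_max")
})

test_that("identity decoding is accurate and improves with population size", {
  rmse_for <- function(n, seed) {
    ens <- build_ensemble(1, n, 75, 250, 1, seed = seed)
    D <- compute_decoders(ens, identity)
    x <- matrix(seq(-0.9, 0.9, length.out = 50), ncol = 1)
    xhat <- ensemble_rates(ens, x) %*% D
    sqrt(mean((xhat - x)^2))
  }
  expect_lt(rmse_for(100, 1), 0.05)
  m50 <- mean(vapply(1:5, function(s) rmse_for(50, s), numeric(1)))
  m100 <- mean(vapply(1:5, function(s) rmse_for(100, s + 10), numeric(1)))
  m200 <- mean(vapply(1:5, function(s) rmse_for(200, s + 20), numeric(1)))
  expect_lt(m100, m50)
  expect_lt(m200, m100)
})

test_that("ridge decoders obey the regularization limits", {
  ens <- build_ensemble(1, 40, 75, 250, 1, seed = 3)
  D_big <- compute_decoders(ens, identity, ridge_lambda = 1e12)
  expect_lt(max(abs(D_big)), 1e-4)
  # near-zero penalty with ample neurons: near interpolation at the points
  pts <- matrix(seq(-0.8, 0.8, length.out = 20), ncol = 1)
  D0 <- compute_decoders(ens, identity, ridge_lambda = 1e-8,
                         eval_points = pts)
  fit <- ensemble_rates(ens, pts) %*% D0
  expect_lt(max(abs(fit - pts)), 1e-4)
})

test_that("rate-mode reservoir tracks the exact LDN state", {
  cfg <- slrc_config(d = 4, theta = 0.1, n_sn = 100, seed = 2)
  model <- build_slrc(cfg)
  # zero input stays near zero
  z <- simulate_slrc(model, numeric(300))
  expect_lt(max(abs(z$decoded)), 0.05)

  u <- bandlimited_noise(800, 0.001, 10, seed = 7)
  sim <- simulate_slrc(model, u)
  x_exact <- unclass(extract_features(u, model$ldn))
  for (i in seq_len(cfg$d)) {
    expect_lt(nrmse(sim$decoded[, i], x_exact[, i]), 0.2)
  }
  expect_error(simulate_slrc(model, c(1, NA)), "non-finite")
})

test_that("inter-sample inhibition clears the reservoir memory", {
  cfg <- slrc_config(d = 4, theta = 0.1, n_sn = 100, seed = 4)
  model <- build_slrc(cfg)
  u <- bandlimited_noise(400, 0.001, 10, seed = 9)
  sim <- simulate_slrc(model, u)              # leaves residual state
  expect_gt(max(abs(sim$decoded[400, ])), 0.05)
  sim2 <- simulate_slrc(model, numeric(10), inhibit_before = TRUE,
                        state = sim$state)
  expect_lt(max(abs(sim2$inhib_decoded)), 0.1)
})

test_that("spiking mode reproduces the rate-mode state more coarsely", {
  cfg <- slrc_config(d = 3, theta = 0.1, n_sn = 150, seed = 5,
                     mode = "spiking")
  model <- build_slrc(cfg)
  u <- bandlimited_noise(500, 0.001, 10, seed = 11)
  sim <- simulate_slrc(model, u)
  x_exact <- unclass(extract_features(u, model$ldn))
  # the first (highest-power) dimension must track within a loose band
  expect_lt(nrmse(sim$decoded[100:500, 1], x_exact[100:500, 1]), 0.5)
  sim2 <- simulate_slrc(model, numeric(10), inhibit_before = TRUE,
                        state = sim$state)
  expect_lt(max(abs(sim2$inhib_decoded)), 0.1)
})

test_that("readout regression separates, saturates, and deduplicates", {
  set.seed(6)
  A0 <- matrix(rnorm(30 * 10, mean = 3), 30, 10)   # class 0 summaries
  A1 <- matrix(rnorm(20 * 10, mean = -1), 20, 10)  # class 1 summaries
  A <- rbind(A0, A1)
  y <- c(rep(0L, 30), rep(1L, 20))
  ro <- fit_readout(A, y, ridge_lambda = 1e-6)
  expect_equal(mean(classify_slrc(ro, A) == y), 1)

  # huge penalty drives the weights toward zero ...
  ro_big <- fit_readout(A, y, ridge_lambda = 1e12)
  expect_lt(max(abs(ro_big$W)), 1e-8)
  # ... and in the exact zero-weight limit every score ties, class 0 is
  # always predicted, and accuracy collapses to the majority-class rate
  ro0 <- structure(list(W = matrix(0, 10, 2), n_classes = 2L),
                   class = "slrc_readout")
  pred <- classify_slrc(ro0, A)
  expect_true(all(pred == 0L))
  expect_equal(mean(pred == y), 30 / 50)

  # duplicating every sample with lambda doubled leaves the weights fixed
  ro1 <- fit_readout(A, y, ridge_lambda = 0.5)
  ro2 <- fit_readout(rbind(A, A), c(y, y), ridge_lambda = 1)
  expect_equal(ro1$W, ro2$W, tolerance = 1e-10)
  expect_error(fit_readout(A, y[-1]), "mismatch")
})

test_that("rounded-score classification follows the documented tie rules", {
  ro <- structure(list(W = diag(2), n_classes = 2L), class = "slrc_readout")
  expect_identical(classify_slrc(ro, c(0.9, 0.1)), 0L)
  expect_identical(classify_slrc(ro, c(0.49, 0.51)), 1L)
  expect_identical(classify_slrc(ro, c(0.5, 0.5)), 0L)
  expect_identical(classify_slrc(ro, rbind(c(0.9, 0.1), c(0.1, 0.9))),
                   c(0L, 1L))
})

test_that("SLRC neuron counts and end-to-end classification behave", {
  expect_identical(slrc_neuron_count(10, 100), 1250L)
  expect_identical(slrc_neuron_count(6, 100), 750L)

  sets <- generate_synth(synth_spec(n_train = 24, n_test = 12, seed = 12))
  cfg <- slrc_config(d = 6, theta = 0.12, n_sn = 50, seed = 13)
  fit <- slrc_fit(cfg, sets$train, sets$test)
  expect_gte(fit$train_acc, 90)
  expect_gte(fit$test_acc, 75)

  # readout fit is deterministic given activities
  model <- build_slrc(cfg)
  A <- slrc_activity_summaries(model, sets$train$signals[1:6, ])
  r1 <- fit_readout(A, sets$train$labels[1:6], 0.1)
  r2 <- fit_readout(A, sets$train$labels[1:6], 0.1)
  expect_identical(r1$W, r2$W)
})
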