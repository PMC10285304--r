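test_that("closed-form state matrices match hand evaluation and examples", {
  m1 <- make_state_matrices(1)
  expect_equal(m1$A, matrix(-1, 1, 1))
  expect_equal(m1$B, 1)

  m2 <- make_state_matrices(2)
  expect_equal(m2$A, matrix(c(-1, 3, -1, -3), 2, 2))
  expect_equal(m2$B, c(1, -3))

  for (d in c(3, 7, 16)) {
    ref <- ldn_matrices_by_loop(d)
    got <- make_state_matrices(d)
    expect_identical(got$A, ref$A)
    expect_identical(got$B, ref$B)
    # every entry of row i has absolute value 2i+1
    expect_equal(abs(got$A), matrix(rep(2 * (0:(d - 1)) + 1, d), d, d))
    expect_equal(abs(got$B), 2 * (0:(d - 1)) + 1)
    expect_equal(sign(got$B), (-1)^(0:(d - 1)))
  }

  expect_error(make_state_matrices(0), "positive integer")
  expect_error(make_state_matrices(2.5), "positive integer")
})

test_that("window scaling divides the dynamics by theta", {
  m <- make_state_matrices(3)
  s1 <- scale_by_window(m$A, m$B, 1)
  expect_equal(s1$A, m$A)
  expect_equal(s1$B, m$B)
  s2 <- scale_by_window(m$A, m$B, 0.5)
  expect_equal(s2$A, 2 * m$A)
  s3 <- scale_by_window(matrix(-1, 1, 1), 1, 0.1)
  expect_equal(s3$A, matrix(-10, 1, 1))
  expect_equal(s3$B, 10)
  expect_error(scale_by_window(m$A, m$B, 0), "positive")
})

test_that("neural mapping gives A' = tau*A + I, B' = tau*B", {
  nm <- neural_mapping(matrix(-10, 1, 1), 10, 0.1)
  expect_equal(nm$A_prime, matrix(0, 1, 1))
  expect_equal(nm$B_prime, 1)
  # tau -> 0 limit
  nm0 <- neural_mapping(matrix(c(-1, 3, -1, -3), 2, 2), c(1, -3), 0)
  expect_equal(nm0$A_prime, diag(2))
  expect_equal(nm0$B_prime, c(0, 0))
  expect_error(neural_mapping(matrix(1, 2, 3), c(1, 1), 0.1), "square")
})

test_that("ZOH discretization matches closed forms and the Euler oracle", {
  z0 <- discretize_zoh(matrix(0, 2, 2), c(1, 2), 0.01)
  expect_equal(z0$A_d, diag(2))
  expect_equal(z0$B_d, 0.01 * c(1, 2))

  z1 <- discretize_zoh(matrix(-10, 1, 1), 10, 0.001)
  expect_equal(z1$A_d[1, 1], exp(-0.01))

  for (k in 1:5) {
    d <- sample(2:12, 1)
    sys <- random_stable_system(d, seed = 100 + k)
    u <- sin(seq(0, 3, length.out = 100))
    zd <- discretize_zoh(sys$A, sys$B, 0.001)
    x_zoh <- unclass(extract_features(u, zd$A_d, zd$B_d))
    x_eul <- euler_sim(sys$A, sys$B, u, 0.001, substeps = 1000)
    rel <- max(abs(x_zoh - x_eul)) / max(abs(x_zoh))
    expect_lt(rel, 1e-6)
  }
})

test_that("feature extraction follows the discrete state recursion", {
  spec <- ldn_spec(4, 0.1)
  # zero input, zero state stays zero
  expect_equal(max(abs(extract_features(numeric(50), spec))), 0)
  # first row applies the update at t = 1 already
  u <- c(0.3, -0.2, 0.5)
  x0 <- c(1, -1, 0.5, 0)
  X <- extract_features(u, spec$A_d, spec$B_d, x0 = x0)
  expect_equal(X[1, ], as.numeric(spec$A_d %*% x0 + spec$B_d * u[1]),
               ignore_attr = TRUE)
  # constant input steady state solves A_c x = -B_c c  (d = 1: x -> c)
  s1 <- ldn_spec(1, 0.1)
  xs <- extract_features(rep(0.7, 1000), s1)
  expect_equal(xs[1000, 1], 0.7, tolerance = 1e-3, ignore_attr = TRUE)
  # linearity
  u1 <- bandlimited_noise(200, 0.001, 20, seed = 1)
  u2 <- bandlimited_noise(200, 0.001, 20, seed = 2)
  lhs <- extract_features(2 * u1 - 3 * u2, spec)
  rhs <- 2 * unclass(extract_features(u1, spec)) -
    3 * unclass(extract_features(u2, spec))
  expect_equal(unclass(lhs), rhs, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(extract_features(c(1, NA, 2), spec), "non-finite")
})

test_that("impulse response matches the matrix-exponential form", {
  spec <- ldn_spec(3, 1, dt = 1e-5)
  u <- c(1, numeric(100))
  X <- unclass(extract_features(u, spec))
  for (k in c(1, 10, 50, 100)) {
    ref <- as.numeric(Matrix::expm(spec$A_c * k * spec$dt) %*%
                        (spec$B_c * spec$dt))
    expect_lt(max(abs(X[k + 1, ] - ref)), 1e-8)
  }
})

test_that("filtered neural form converges to the ZOH simulation", {
  m <- make_state_matrices(4)
  cs <- scale_by_window(m$A, m$B, 0.1)
  nm <- neural_mapping(cs$A, cs$B, 0.1)
  errs <- vapply(c(1e-3, 1e-4), function(dt) {
    n <- round(1 / dt)
    u <- bandlimited_noise(n, dt, 10, seed = 5)
    zd <- discretize_zoh(cs$A, cs$B, dt)
    xz <- unclass(extract_features(u, zd$A_d, zd$B_d))
    xf <- simulate_filtered(nm$A_prime, nm$B_prime, 0.1, u, dt)
    max(abs(xz - xf))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("delay decoder reconstructs delayed inputs", {
  spec <- ldn_spec(10, 0.1)
  # constant probe: delayed constant is the constant
  fd_const <- fit_delay_decoder(spec, 0.05, rep(0.4, 500))
  expect_lt(fd_const$nrmse, 1e-6)
  # band-limited probe at phi = theta/2
  probe <- bandlimited_noise(5000, 0.001, 10, seed = 3)
  fd <- fit_delay_decoder(spec, 0.05, probe)
  expect_lt(fd$nrmse, 0.2)
  expect_length(fd$weights, 10)
  expect_error(fit_delay_decoder(spec, 0.2, probe), "phi")
  expect_error(fit_delay_decoder(spec, 0, probe), "phi")
})

test_that("feature traces export as plain CSV", {
  spec <- ldn_spec(3, 0.05)
  X <- extract_features(sin(1:30 / 5), spec)
  path <- tempfile(fileext = ".csv")
  write_feature_csv(X, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("x0", "x1", "x2"))
  expect_equal(as.matrix(back), unclass(X), tolerance = 1e-12,
               ignore_attr = TRUE)
})
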