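test_that("layer sizes follow the neuron-count laws", {
  for (d in c(1L, 10L, 24L)) {
    m <- build_lsnn(lsnn_config(d = d))
    expect_identical(n_spiking_neurons(m), 5L * d)
    expect_equal(dim(m$W1), c(2 * d, 3 * d))
    expect_equal(dim(m$W2), c(3 * d, 2))
  }
  expect_identical(n_spiking_neurons(build_lsnn(lsnn_config(d = 10))), 50L)
  expect_identical(n_spiking_neurons(build_lsnn(lsnn_config(d = 24))), 120L)

  mn <- build_lsnn_nhdn(lsnn_config(d = 10))
  expect_identical(n_spiking_neurons(mn), 20L)
  expect_equal(dim(mn$W1), c(20, 2))
  expect_length(trainable_weights(mn), 1)

  ms <- build_lsnn_nspk(lsnn_config(d = 10))
  expect_equal(dim(ms$W1), c(10, 30))   # hidden ReLU width 3*d
  expect_identical(n_spiking_neurons(ms), 0L)

  expect_error(lsnn_config(d = 0), "positive integer")
  expect_error(lsnn_config(n_classes = 1), ">= 2")
})

test_that("zero input with zero bias produces a zero trace and class 0", {
  m <- build_lsnn(lsnn_config(d = 4, iota = 0))
  out <- lsnn_forward(m, numeric(60))
  expect_equal(max(abs(out$V_otp_trace)), 0)
  expect_identical(out$prediction, 0L)   # tie broken to the lowest class
})

test_that("forward is deterministic and matches the per-step API", {
  cfg <- lsnn_config(d = 3, seed = 9, rho = 3)
  m <- build_lsnn(cfg)
  u <- sin(seq(0, 4 * pi, length.out = 80)) + 0.2
  o1 <- lsnn_forward(m, u)
  o2 <- lsnn_forward(m, u)
  expect_identical(o1, o2)

  # independent route: drive the public single-step functions
  X <- unclass(extract_features(u, m$ldn))
  p <- m$params
  st_e <- layer_state(2 * 3)
  st_h <- layer_state(3 * 3)
  st_o <- layer_state(2)
  V_trace <- matrix(0, length(u), 2)
  for (t in seq_along(u)) {
    e <- enc_step(X[t, ], p, st_e); st_e <- e$state
    h <- hdn_step(e$spikes, m$W1, p, st_h); st_h <- h$state
    st_o <- otp_step(h$spikes, m$W2, p, st_o)
    V_trace[t, ] <- st_o$V
  }
  expect_equal(o1$V_otp_trace, V_trace, tolerance = 1e-12)
})

test_that("a three-step toy network matches manual enumeration", {
  cfg <- lsnn_config(d = 1, theta = 0.02, rho = 1, iota = 0,
                     tau_cur = 10e-3, tau_vol = 20e-3, v_thr = 1)
  m <- build_lsnn(cfg)
  # hand-set weights: one live hidden neuron, printed values
  m$W1 <- matrix(c(0.8, 0, 0,
                   0.5, 0, 0), 2, 3, byrow = TRUE)
  m$W2 <- matrix(c(0.7, -0.4,
                   0, 0,
                   0, 0), 3, 2, byrow = TRUE)
  u <- c(1, 1, -1)
  out <- lsnn_forward(m, u)

  # manual step-by-step enumeration in plain scalar arithmetic
  x <- numeric(3)
  xprev <- 0
  for (t in 1:3) {
    xprev <- m$ldn$A_d[1, 1] * xprev + m$ldn$B_d[1] * u[t]
    x[t] <- xprev
  }
  a <- exp(-0.001 / 10e-3)
  b <- exp(-0.001 / 20e-3)
  Vp <- Vn <- 0        # ENC pair voltages
  Ih <- Vh <- 0        # the single live hidden neuron
  Io1 <- Io2 <- Vo1 <- Vo2 <- 0
  Vref <- matrix(0, 3, 2)
  for (t in 1:3) {
    Ip <- x[t]; In <- -x[t]
    Vp <- max(Vp + Ip, 0); Vn <- max(Vn + In, 0)
    Sp <- as.numeric(Vp >= 1); Sn <- as.numeric(Vn >= 1)
    if (Sp) Vp <- 0
    if (Sn) Vn <- 0
    Ih <- a * Ih + 0.8 * Sp + 0.5 * Sn
    Vh <- Vh + Ih
    Sh <- as.numeric(Vh >= 1)
    if (Sh) Vh <- 0
    Io1 <- a * Io1 + 0.7 * Sh
    Io2 <- a * Io2 - 0.4 * Sh
    Vo1 <- b * Vo1 + Io1
    Vo2 <- b * Vo2 + Io2
    Vref[t, ] <- c(Vo1, Vo2)
  }
  expect_equal(out$V_otp_trace, Vref, tolerance = 1e-14)
  expect_identical(out$prediction,
                   if (max(Vref[, 1]) >= max(Vref[, 2])) 0L else 1L)
})

test_that("max-voltage softmax loss has the expected closed forms", {
  # equal maxima across two classes -> ln 2
  tr <- matrix(0, 10, 2)
  tr[5, ] <- c(1, 1)
  expect_equal(classification_loss(tr, 0L), log(2))
  # dominant true class -> loss ~ 0
  tr2 <- matrix(0, 10, 2)
  tr2[5, ] <- c(50, 1)
  expect_lt(classification_loss(tr2, 0L), 1e-10)
  # shift invariance
  traces <- lapply(1:4, function(i) matrix(rnorm(20), 10, 2))
  y <- c(0L, 1L, 0L, 1L)
  l1 <- classification_loss(traces, y)
  l2 <- classification_loss(lapply(traces, function(m) m + 3.7), y)
  expect_equal(l1, l2, tolerance = 1e-12)
  # permuting class indices in traces and labels leaves the loss unchanged
  perm <- lapply(traces, function(m) m[, c(2, 1)])
  expect_equal(classification_loss(perm, 1L - y), l1, tolerance = 1e-12)
  expect_error(classification_loss(traces, c(0L, 2L, 0L, 1L)),
               "class range")
})

test_that("the non-spiking variant is differentiable and zero maps to zero", {
  m <- build_lsnn_nspk(lsnn_config(d = 4, seed = 2))
  out <- lsnn_forward(m, numeric(50))
  expect_equal(max(abs(out$V_otp_trace)), 0)

  set.seed(7)
  X <- matrix(rnorm(2 * 30, sd = 0.5), 2, 30)
  y <- c(0L, 1L)
  g <- lsnn_loss_grads(m, X, y)
  h <- 1e-5
  for (wk in c("W1", "W2")) {
    idx <- sample(length(m[[wk]]), 5)
    for (i in idx) {
      mp <- m; mp[[wk]][i] <- mp[[wk]][i] + h
      mm <- m; mm[[wk]][i] <- mm[[wk]][i] - h
      fd <- (lsnn_loss_grads(mp, X, y)$loss -
               lsnn_loss_grads(mm, X, y)$loss) / (2 * h)
      an <- g$grads[[wk]][i]
      expect_equal(an, fd, tolerance = 1e-5)
    }
  }
})

test_that("models round-trip through the plain-text archive", {
  for (builder in list(build_lsnn, build_lsnn_nhdn, build_lsnn_nspk)) {
    m <- builder(lsnn_config(d = 3, seed = 5, rho = 1.5))
    dir <- tempfile("model")
    save_lsnn(m, dir)
    m2 <- load_lsnn(dir)
    expect_equal(m2$W1, m$W1, tolerance = 1e-15)
    expect_equal(m2$W2, m$W2, tolerance = 1e-15)
    expect_identical(m2$variant, m$variant)
    u <- cos(1:40 / 3)
    expect_equal(lsnn_forward(m2, u), lsnn_forward(m, u))
  }
})
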