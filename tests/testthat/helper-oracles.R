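# Independent numerical oracles used across test files.

# Forward-Euler integration of dx/dt = A x + B u with `substeps` Euler
# sub-steps per coarse ZOH step (input constant within each coarse step).
euler_sim <- function(A, B, u, dt, substeps = 1000) {
  h <- dt / substeps
  x <- numeric(nrow(A))
  X <- matrix(0, length(u), nrow(A))
  for (t in seq_along(u)) {
    for (k in seq_len(substeps)) {
      x <- x + h * (A %*% x + B * u[t])
    }
    X[t, ] <- x
  }
  X
}

# Random stable continuous system of order d with unit-order dynamics:
# the raw matrix is scaled to spectral norm 1 before the stabilizing
# eigenvalue shift, keeping the Euler reference's own O(h^2 ||A||^2)
# truncation error well below the comparison tolerance.
random_stable_system <- function(d, seed) {
  set.seed(seed)
  R <- matrix(rnorm(d * d), d, d)
  R <- R / norm(R, "2")
  shift <- max(Re(eigen(R, only.values = TRUE)$values)) + 0.5
  list(A = R - shift * diag(d), B = rnorm(d))
}

# Double-loop evaluation of the LDN closed forms, written independently of
# make_state_matrices.
ldn_matrices_by_loop <- function(d) {
  A <- matrix(0, d, d)
  B <- numeric(d)
  for (i in 0:(d - 1)) {
    for (j in 0:(d - 1)) {
      A[i + 1, j + 1] <- (2 * i + 1) * (if (i < j) -1 else (-1)^(i - j + 1))
    }
    B[i + 1] <- (2 * i + 1) * (-1)^i
  }
  list(A = A, B = B)
}

# Tiny balanced two-class dataset with hand-made separable signals.
toy_dataset <- function(n = 8, T_len = 40, split = "train") {
  labels <- rep(c(0L, 1L), length.out = n)
  X <- t(vapply(labels, function(y) {
    s <- numeric(T_len)
    s[10:20] <- if (y == 0) 1 else -1
    s
  }, numeric(T_len)))
  ts_dataset(X, labels, c("0", "1"), split)
}
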