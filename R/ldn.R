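#' Legendre Delay Network state-space matrices
#'
#' Closed-form continuous-time state matrices of the LDN, the LTI system
#' whose order-`d` state vector optimally approximates a pure delay of its
#' scalar input. With 0-based indices `i, j` in `0:(d-1)`:
#' `A[i,j] = (2i+1) * (-1)` for `i < j` and `(2i+1) * (-1)^(i-j+1)` for
#' `i >= j`; `B[i] = (2i+1) * (-1)^i`. These are the unscaled matrices; the
#' delay-window length enters through [scale_by_window()].
#'
#' @param d positive integer order of the state vector.
#' @return list with `A` (d x d matrix) and `B` (length-d vector).
#' @examples
#' make_state_matrices(2)
#' @export
make_state_matrices <- function(d) {
  if (length(d) != 1 || !is.numeric(d) || is.na(d) || d < 1 || d != round(d)) {
    stop_invalid("`d` must be a single positive integer")
  }
  d <- as.integer(d)
  i <- 0:(d - 1)
  A <- matrix(0, d, d)
  for (jj in i) {
    col <- ifelse(i < jj, -1, (-1)^(i - jj + 1))
    A[, jj + 1] <- (2 * i + 1) * col
  }
  B <- (2 * i + 1) * (-1)^i
  list(A = A, B = B)
}

#' Scale LDN matrices by the delay window
#'
#' The delay transfer function `exp(-theta * s)` requires the dynamics to
#' run at rate `1/theta`: `A_c = A/theta`, `B_c = B/theta`. Applied before
#' both the neural mapping and discretization.
#'
#' @param A_raw,B_raw unscaled matrices from [make_state_matrices()].
#' @param theta window length in seconds (> 0).
#' @return list with `A` and `B` scaled by `1/theta`.
#' @export
scale_by_window <- function(A_raw, B_raw, theta) {
  if (length(theta) != 1 || !is.numeric(theta) || is.na(theta) || theta <= 0) {
    stop_invalid("`theta` must be a single positive number")
  }
  list(A = A_raw / theta, B = B_raw / theta)
}

#' Map a continuous LTI system into its neural (filtered) form
#'
#' Rewrites `dx/dt = A x + B u` as `x = h * (A' x + B' u)` where `h` is a
#' first-order low-pass filter with time constant `tau`; equating Laplace
#' transforms gives `A' = tau * A + I` and `B' = tau * B`.
#'
#' @param A_c square continuous state matrix.
#' @param B_c input vector.
#' @param tau filter time constant in seconds (> 0).
#' @return list with `A_prime` and `B_prime`.
#' @export
neural_mapping <- function(A_c, B_c, tau) {
  if (!is.matrix(A_c) || nrow(A_c) != ncol(A_c)) {
    stop_invalid("`A_c` must be a square matrix")
  }
  if (length(tau) != 1 || !is.numeric(tau) || tau < 0) {
    stop_invalid("`tau` must be a single non-negative number")
  }
  list(A_prime = tau * A_c + diag(nrow(A_c)), B_prime = tau * B_c)
}

#' Zero-order-hold discretization of a continuous LTI system
#'
#' `A_d = expm(A_c * dt)`; `B_d = A_c^{-1} (A_d - I) B_c`. Computed via the
#' augmented-matrix exponential so singular `A_c` is handled exactly:
#' `expm(dt * [[A, B], [0, 0]])` has `A_d` in the top-left block and `B_d`
#' in the top-right column.
#'
#' @param A_c continuous state matrix.
#' @param B_c input vector.
#' @param dt step size in seconds (> 0).
#' @return list with `A_d` (matrix) and `B_d` (vector).
#' @export
discretize_zoh <- function(A_c, B_c, dt) {
  if (length(dt) != 1 || !is.numeric(dt) || dt <= 0) {
    stop_invalid("`dt` must be a single positive number")
  }
  d <- nrow(A_c)
  M <- rbind(cbind(A_c, matrix(B_c, ncol = 1)), matrix(0, 1, d + 1))
  E <- as.matrix(Matrix::expm(M * dt))
  list(A_d = E[seq_len(d), seq_len(d), drop = FALSE], B_d = E[seq_len(d), d + 1])
}

#' Construct a fully specified LDN
#'
#' Bundles the raw, window-scaled, neural-mapped, and ZOH-discretized
#' matrices of an order-`d` Legendre Delay Network with window `theta`.
#'
#' @param d positive integer order.
#' @param theta window length in seconds.
#' @param tau low-pass filter constant in seconds (used by the neural form
#'   and the reservoir model; default 0.1).
#' @param dt simulation step in seconds (default 0.001).
#' @return object of class `ldn_spec`.
#' @examples
#' spec <- ldn_spec(d = 4, theta = 0.1)
#' dim(spec$A_d)
#' @export
ldn_spec <- function(d, theta, tau = 0.1, dt = 0.001) {
  if (length(theta) != 1 || !is.numeric(theta) || theta <= 0) {
    stop_invalid("`theta` must be positive")
  }
  if (length(dt) != 1 || !is.numeric(dt) || dt <= 0 || dt > theta) {
    stop_invalid("`dt` must satisfy 0 < dt <= theta")
  }
  raw <- make_state_matrices(d)
  cs <- scale_by_window(raw$A, raw$B, theta)
  nm <- neural_mapping(cs$A, cs$B, tau)
  zd <- discretize_zoh(cs$A, cs$B, dt)
  structure(
    list(d = as.integer(d), theta = theta, tau = tau, dt = dt,
         A_raw = raw$A, B_raw = raw$B,
         A_c = cs$A, B_c = cs$B,
         A_prime = nm$A_prime, B_prime = nm$B_prime,
         A_d = zd$A_d, B_d = zd$B_d),
    class = "ldn_spec")
}

#' @export
print.ldn_spec <- function(x, ...) {
  cat(sprintf("<ldn_spec> d=%d theta=%gs tau=%gs dt=%gs\n",
              x$d, x$theta, x$tau, x$dt))
  invisible(x)
}

#' Extract LDN temporal features from a signal
#'
#' Runs the discretized state update `x[t] = A_d x[t-1] + B_d u[t]` over a
#' scalar signal, the update being applied at `t = 1` already (row 1 of the
#' result equals `A_d x0 + B_d u[1]`).
#'
#' @param u numeric signal of length T.
#' @param A_d,B_d discrete matrices, or pass an `ldn_spec` as `A_d`.
#' @param x0 initial state (default all zeros).
#' @return `T x d` matrix of class `feature_trace`; row t is the state after
#'   consuming `u[t]`. Attribute `dt` carries the step size when a spec is
#'   supplied.
#' @export
extract_features <- function(u, A_d, B_d = NULL, x0 = NULL) {
  dt <- NA_real_
  if (inherits(A_d, "ldn_spec")) {
    spec <- A_d
    dt <- spec$dt
    A_d <- spec$A_d
    B_d <- spec$B_d
  }
  u <- as.numeric(u)
  if (length(u) < 1) stop_invalid("signal must have length >= 1")
  if (any(!is.finite(u))) stop_invalid("signal contains non-finite values")
  d <- nrow(A_d)
  if (is.null(x0)) x0 <- numeric(d)
  if (length(x0) != d) stop_invalid("`x0` has wrong length")
  T_len <- length(u)
  X <- matrix(0, T_len, d)
  x <- x0
  for (t in seq_len(T_len)) {
    x <- A_d %*% x + B_d * u[t]
    X[t, ] <- x
  }
  colnames(X) <- paste0("x", 0:(d - 1))
  structure(X, dt = dt, class = c("feature_trace", "matrix", "array"))
}

#' Simulate the neural (filtered) form of an LTI system
#'
#' Discrete simulation of `x = h * (A' x + B' u)` with a first-order
#' low-pass `h` of constant `tau`: the filter state is updated with its own
#' ZOH coefficient `a = exp(-dt/tau)`. Converges to the ZOH simulation of
#' the underlying `(A_c, B_c)` system as `dt -> 0`.
#'
#' @param A_prime,B_prime neural-mapped matrices (see [neural_mapping()]).
#' @param tau filter constant in seconds.
#' @param u signal.
#' @param dt step size in seconds.
#' @return `T x d` state matrix.
#' @export
simulate_filtered <- function(A_prime, B_prime, tau, u, dt) {
  a <- exp(-dt / tau)
  d <- nrow(A_prime)
  T_len <- length(u)
  X <- matrix(0, T_len, d)
  x <- numeric(d)
  for (t in seq_len(T_len)) {
    drive <- A_prime %*% x + B_prime * u[t]
    x <- a * x + (1 - a) * drive
    X[t, ] <- x
  }
  X
}

#' Fit a linear delay decoder on LDN features
#'
#' Least-squares weights `w` such that `w' x[t]` approximates the input
#' delayed by `phi` seconds, `0 < phi <= theta`. The first
#' `ceiling(theta/dt)` samples are discarded as transient (the window is
#' not yet filled), and the NRMSE is reported on the remaining probe.
#'
#' @param spec an [ldn_spec()].
#' @param phi delay to decode, in seconds.
#' @param probe probe signal (longer than `theta/dt` samples).
#' @return list with `weights` (length-d), `nrmse`, and `decoded` (aligned
#'   decoded signal on the evaluation region).
#' @export
fit_delay_decoder <- function(spec, phi, probe) {
  stopifnot(inherits(spec, "ldn_spec"))
  if (length(phi) != 1 || !is.numeric(phi) || phi <= 0 || phi > spec$theta) {
    stop_invalid("`phi` must lie in (0, theta]")
  }
  k <- round(phi / spec$dt)
  skip <- ceiling(spec$theta / spec$dt)
  T_len <- length(probe)
  if (T_len <= skip + k) stop_invalid("probe too short for the requested delay")
  X <- unclass(extract_features(probe, spec))
  idx <- (skip + 1):T_len
  target <- probe[idx - k]
  Xe <- X[idx, , drop = FALSE]
  w <- qr.solve(qr(Xe), target)
  dec <- as.numeric(Xe %*% w)
  list(weights = as.numeric(w), nrmse = nrmse(dec, target), decoded = dec)
}

#' Write a feature trace to CSV
#'
#' Plain CSV with one row per time-step and header `x0..x{d-1}`.
#'
#' @param trace matrix from [extract_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(unclass(trace)), path, row.names = FALSE)
  invisible(path)
}
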