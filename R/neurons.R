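#' Integrate-and-fire neuron parameters
#'
#' Discrete-time IF parameters shared by the encoding (ENC), hidden (HDN)
#' and output (OTP) layers. The current decay is `alpha = exp(-dt/tau_cur)`
#' and the voltage decay `beta = exp(-dt/tau_vol)`; ENC and HDN neurons have
#' no voltage decay (`beta = 1`). Membrane resistance is fixed at 1.
#'
#' @param v_thr spike threshold voltage (dimensionless, > 0).
#' @param rho encoder gain (ENC layer).
#' @param iota bias current (ENC layer).
#' @param tau_cur current time constant in seconds (HDN/OTP current decay).
#' @param tau_vol voltage time constant in seconds (OTP voltage decay);
#'   `Inf` gives `beta = 1` (no decay).
#' @param dt simulation step in seconds.
#' @param clamp_enc clamp ENC membrane voltage below at 0; keeps the
#'   inactive member of an encoder pair from accumulating unbounded negative
#'   voltage, preserving per-pair spike exclusivity (default TRUE).
#' @return object of class `neuron_params` with derived `alpha`, `beta`.
#' @export
neuron_params <- function(v_thr = 1, rho = 2, iota = 0,
                          tau_cur = 10e-3, tau_vol = 20e-3,
                          dt = 0.001, clamp_enc = TRUE) {
  stopifnot(v_thr > 0, tau_cur > 0, tau_vol > 0, dt > 0)
  structure(
    list(v_thr = v_thr, rho = rho, iota = iota,
         tau_cur = tau_cur, tau_vol = tau_vol,
         alpha = exp(-dt / tau_cur), beta = exp(-dt / tau_vol),
         R = 1, dt = dt, clamp_enc = clamp_enc),
    class = "neuron_params")
}

#' Fresh layer state
#'
#' Zero-initialized membrane voltage `V`, current `I`, and binary spike
#' vector `S` for `n` neurons.
#'
#' @param n number of neurons.
#' @return list with components `V`, `I`, `S`.
#' @export
layer_state <- function(n) {
  list(V = numeric(n), I = numeric(n), S = integer(n))
}

#' Heaviside spike function
#'
#' `S_i = 1` iff `V_i >= v_thr`: the neuron spikes at exact threshold
#' equality (the reset rule fires at `V >= V_thr`).
#'
#' @param V voltage vector.
#' @param v_thr threshold.
#' @return integer 0/1 vector.
#' @export
heaviside_spike <- function(V, v_thr) {
  as.integer(V >= v_thr)
}

#' Surrogate spike derivative
#'
#' The derivative of the negative half of the fast sigmoid,
#' `f'(x) = 1 / (1 + |x|)^2` with `x = V - v_thr`, substituted for the
#' undefined Heaviside derivative in the backward pass.
#'
#' @param x voltage minus threshold (any shape).
#' @return same shape as `x`.
#' @export
surrogate_grad <- function(x) {
  1 / (1 + abs(x))^2
}

#' One ENC-layer step
#'
#' Paired rate encoders: neuron `2k` (1-based: odd) carries the positive
#' encoder of feature `k`, neuron `2k+1` the negative. Currents are
#' `I_i = rho * eps_(i mod 2) * x_(floor(i/2)) + iota` with `eps_0 = +1`,
#' `eps_1 = -1`; voltage accumulates without decay, is optionally clamped
#' below at 0, and hard-resets to 0 on a spike.
#'
#' @param x_t length-d feature vector.
#' @param params a [neuron_params()].
#' @param state layer state of 2d neurons from [layer_state()].
#' @return list with `spikes` (length 2d) and `state`.
#' @export
enc_step <- function(x_t, params, state) {
  d <- length(x_t)
  if (length(state$V) != 2 * d) stop_invalid("ENC state must have 2*d neurons")
  eps <- rep(c(1, -1), d)
  x2 <- rep(x_t, each = 2)
  I <- params$rho * eps * x2 + params$iota
  V <- state$V + I
  if (isTRUE(params$clamp_enc)) V <- pmax(V, 0)
  S <- heaviside_spike(V, params$v_thr)
  V[S == 1] <- 0
  list(spikes = S, state = list(V = V, I = I, S = S))
}

#' One HDN-layer step
#'
#' Spiking hidden neurons: `I[t] = alpha I[t-1] + W' S_prev[t]`, voltage
#' accumulates with no decay, spikes at threshold with hard reset.
#'
#' @param S_prev binary spike vector from the upstream layer (length m).
#' @param W `m x n` weight matrix (inputs in rows).
#' @param params a [neuron_params()].
#' @param state layer state of n neurons.
#' @return list with `spikes` (length n) and `state`.
#' @export
hdn_step <- function(S_prev, W, params, state) {
  if (length(S_prev) != nrow(W) || length(state$V) != ncol(W)) {
    stop_invalid("shape mismatch between spikes, weights, and state")
  }
  I <- params$alpha * state$I + as.numeric(crossprod(W, S_prev))
  V <- state$V + I
  S <- heaviside_spike(V, params$v_thr)
  V[S == 1] <- 0
  list(spikes = S, state = list(V = V, I = I, S = S))
}

#' One OTP-layer step
#'
#' Non-spiking output integrators: same current law as the hidden layer but
#' the voltage decays by `beta` each step and is never reset; no spikes are
#' emitted.
#'
#' @param S_prev binary spike vector from the upstream layer.
#' @param W `m x n` weight matrix.
#' @param params a [neuron_params()].
#' @param state layer state of n nodes.
#' @return updated state (component `S` stays zero).
#' @export
otp_step <- function(S_prev, W, params, state) {
  if (length(S_prev) != nrow(W) || length(state$V) != ncol(W)) {
    stop_invalid("shape mismatch between spikes, weights, and state")
  }
  I <- params$alpha * state$I + as.numeric(crossprod(W, S_prev))
  V <- params$beta * state$V + I
  list(V = V, I = I, S = integer(length(V)))
}

#' Write a spike raster to CSV
#'
#' Dense 0/1 matrix, one row per time-step and one column per neuron.
#'
#' @param spikes `T x N` 0/1 matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  utils::write.csv(as.data.frame(spikes), path, row.names = FALSE)
  invisible(path)
}
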