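#' Build an NEF neuron ensemble
#'
#' A population of `n` integrate-and-fire neurons representing a
#' `dim`-dimensional value within `radius`. Each neuron has a preferred
#' direction (encoder): random sign for scalar ensembles, random unit
#' direction otherwise; a maximum firing rate drawn uniformly from
#' `[fr_min, fr_max]` attained at its preferred input of magnitude
#' `radius`; and an intercept drawn uniformly from `(-radius, radius)`
#' below which it is silent. Gains and biases are solved from the
#' rectified-linear rate model of the non-leaky IF neuron: with normalized
#' current `J = gain * <e, x> + bias`, the rate is `max_rate * max(0, J)`,
#' `J = 0` at the intercept and `J = 1` at the preferred radius.
#'
#' @param dim represented dimensionality.
#' @param n number of neurons (>= 1).
#' @param fr_min,fr_max firing-rate range in Hz (`fr_min < fr_max`).
#' @param radius representational radius.
#' @param seed integer seed.
#' @return object of class `nef_ensemble`.
#' @export
build_ensemble <- function(dim, n, fr_min, fr_max, radius, seed = 1) {
  if (!(fr_min < fr_max) || fr_min <= 0) {
    stop_invalid("need 0 < fr_min < fr_max")
  }
  if (n < 1 || dim < 1 || radius <= 0) {
    stop_invalid("need n >= 1, dim >= 1, radius > 0")
  }
  with_seed(seed, {
    enc <- if (dim == 1) {
      matrix(sample(c(-1, 1), n, replace = TRUE), n, 1)
    } else {
      E <- matrix(stats::rnorm(n * dim), n, dim)
      E / sqrt(rowSums(E^2))
    }
    max_rates <- stats::runif(n, fr_min, fr_max)
    # intercepts in represented units; keep away from +radius so the
    # max-rate constraint stays solvable
    icpt <- stats::runif(n, -radius, 0.95 * radius)
    cnorm <- icpt / radius
    structure(
      list(dim = as.integer(dim), n = as.integer(n),
           fr_min = fr_min, fr_max = fr_max, radius = radius,
           encoders = enc, max_rates = max_rates, intercepts = icpt,
           gains = 1 / (radius * (1 - cnorm)), biases = -cnorm / (1 - cnorm),
           seed = seed),
      class = "nef_ensemble")
  })
}

#' @export
print.nef_ensemble <- function(x, ...) {
  cat(sprintf("<nef_ensemble> %d neurons, dim %d, rates [%g, %g] Hz, radius %g\n",
              x$n, x$dim, x$fr_min, x$fr_max, x$radius))
  invisible(x)
}

#' Instantaneous firing rates of an ensemble
#'
#' @param ens a [build_ensemble()] object.
#' @param X `m x dim` matrix of represented values (or a length-dim
#'   vector).
#' @param extra_current additive normalized current (scalar or length-n),
#'   used for inhibition.
#' @return `m x n` matrix of rates in Hz.
#' @export
ensemble_rates <- function(ens, X, extra_current = 0) {
  if (!is.matrix(X)) X <- matrix(X, ncol = ens$dim)
  J <- sweep(X %*% t(ens$encoders), 2, ens$gains, `*`)
  J <- sweep(J, 2, ens$biases, `+`)
  J <- sweep(J, 2, rep_len(extra_current, ens$n), `+`)
  sweep(pmax(J, 0), 2, ens$max_rates, `*`)
}

#' Least-squares decoders with L2 regularization
#'
#' Solves `argmin_D ||A D - Y||^2 + lambda ||D||^2` where `A` holds the
#' ensemble's firing rates at evaluation points spanning the represented
#' range and `Y` the target function values there. The default `lambda` is
#' `0.1 *` the ensemble's mean maximum rate.
#'
#' @param ens a [build_ensemble()] object.
#' @param target_fn function mapping an `m x dim` matrix of points to an
#'   `m x k` target matrix (or vector); `identity` decodes the represented
#'   value itself.
#' @param ridge_lambda L2 penalty (`NULL` for the default).
#' @param n_eval number of evaluation points.
#' @param eval_points optional explicit `m x dim` evaluation points.
#' @return `n x k` decoder matrix.
#' @export
compute_decoders <- function(ens, target_fn = identity, ridge_lambda = NULL,
                             n_eval = 500, eval_points = NULL) {
  if (is.null(ridge_lambda)) ridge_lambda <- 0.1 * mean(ens$max_rates)
  if (is.null(eval_points)) {
    eval_points <- if (ens$dim == 1) {
      matrix(seq(-ens$radius, ens$radius, length.out = n_eval), ncol = 1)
    } else {
      with_seed(derive_seed(ens$seed, 101), {
        P <- matrix(stats::rnorm(n_eval * ens$dim), n_eval, ens$dim)
        len <- sqrt(rowSums(P^2))
        scale <- ens$radius * stats::runif(n_eval)^(1 / ens$dim)
        P * (scale / len)
      })
    }
  }
  A <- ensemble_rates(ens, eval_points)
  Y <- target_fn(eval_points)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = nrow(eval_points))
  G <- crossprod(A) + ridge_lambda * diag(ens$n)
  solve(G, crossprod(A, Y))
}

#' SLRC model configuration
#'
#' The Spiking Legendre Reservoir Computing model: an input node drives a
#' reservoir of `d` scalar ensembles (one per LDN state dimension) with
#' connection weight `tau * B`, the reservoir is recurrently connected with
#' weight `tau * A + I`, and an aggregating ensemble of `n_sn * d / 4`
#' neurons represents the full d-dimensional state for the readout. All
#' connections are static except the readout, which is learned by
#' L2-regularized least squares. Between independent samples a negative
#' current can be injected into the reservoir neurons to clear its memory.
#'
#' @param d LDN order.
#' @param theta LDN window in seconds.
#' @param tau recurrent low-pass filter constant in seconds (default 0.1).
#' @param n_sn neurons per reservoir ensemble.
#' @param fr_min,fr_max firing-rate range in Hz.
#' @param r_res,r_ens representational radii of the reservoir ensembles and
#'   the aggregating ensemble.
#' @param inhibit_magnitude normalized inhibitory current (default 8).
#' @param inhibit_duration inhibition length in steps (default 50).
#' @param ridge_lambda readout/decoder L2 penalty (`NULL` for the
#'   per-ensemble default).
#' @param seed integer seed.
#' @param mode `"rate"` (instantaneous rates) or `"spiking"` (binary
#'   spikes, low-pass filtered before decoding).
#' @param dt simulation step in seconds.
#' @param tau_readout synapse constant in seconds for the
#'   reservoir-to-ensemble connection and activity filtering (default
#'   0.01).
#' @return object of class `slrc_config`.
#' @export
slrc_config <- function(d = 10, theta = 0.12, tau = 0.1, n_sn = 100,
                        fr_min = 75, fr_max = 250, r_res = 1, r_ens = 1,
                        inhibit_magnitude = 8, inhibit_duration = 50,
                        ridge_lambda = NULL, seed = 1,
                        mode = c("rate", "spiking"), dt = 0.001,
                        tau_readout = 0.01) {
  mode <- match.arg(mode)
  if (d < 1 || n_sn < 1) stop_invalid("need d >= 1 and n_sn >= 1")
  structure(
    list(d = as.integer(d), theta = theta, tau = tau,
         n_sn = as.integer(n_sn), fr_min = fr_min, fr_max = fr_max,
         r_res = r_res, r_ens = r_ens,
         inhibit_magnitude = inhibit_magnitude,
         inhibit_duration = as.integer(inhibit_duration),
         ridge_lambda = ridge_lambda, seed = seed, mode = mode, dt = dt,
         tau_readout = tau_readout),
    class = "slrc_config")
}

#' Total spiking neurons in an SLRC model
#'
#' `d` reservoir ensembles of `n_sn` neurons each plus the aggregating
#' ensemble of `n_sn * d / 4` neurons.
#'
#' @param d LDN order.
#' @param n_sn neurons per reservoir ensemble.
#' @return integer count.
#' @examples
#' slrc_neuron_count(10, 100)  # 1250
#' @export
slrc_neuron_count <- function(d, n_sn) {
  as.integer(d * n_sn + round(n_sn * d / 4))
}

#' Build an SLRC model
#'
#' Instantiates the LDN (window-scaled, neurally mapped matrices), the `d`
#' reservoir ensembles, the aggregating ensemble, and their identity
#' decoders.
#'
#' @param config an [slrc_config()].
#' @return object of class `slrc_model`.
#' @export
build_slrc <- function(config) {
  stopifnot(inherits(config, "slrc_config"))
  d <- config$d
  ldn <- ldn_spec(d, config$theta, tau = config$tau, dt = config$dt)
  res <- lapply(seq_len(d), function(i) {
    build_ensemble(1, config$n_sn, config$fr_min, config$fr_max,
                   config$r_res, seed = derive_seed(config$seed, i))
  })
  n_ens <- max(1L, as.integer(round(config$n_sn * d / 4)))
  ens <- build_ensemble(d, n_ens, config$fr_min, config$fr_max,
                        config$r_ens, seed = derive_seed(config$seed, 1000))
  res_dec <- lapply(res, function(e) {
    compute_decoders(e, identity, config$ridge_lambda)
  })
  ens_dec <- compute_decoders(ens, identity, config$ridge_lambda)
  structure(
    list(config = config, ldn = ldn, res = res, ens = ens,
         res_decoders = res_dec, ens_decoders = ens_dec),
    class = "slrc_model")
}

#' @export
print.slrc_model <- function(x, ...) {
  cat(sprintf("<slrc_model %s> d=%d n_sn=%d (+%d ENS) tau=%g theta=%g\n",
              x$config$mode, x$config$d, x$config$n_sn, x$ens$n,
              x$config$tau, x$config$theta))
  invisible(x)
}

# internal persistent simulation state
slrc_state <- function(model) {
  d <- model$config$d
  list(w_res = numeric(d),            # filtered drive per reservoir dim
       w_ens = numeric(d),            # filtered input to the aggregator
       v_res = numeric(d * model$config$n_sn),  # spiking-mode voltages
       v_ens = numeric(model$ens$n))
}

# one reservoir step; returns decoded states, ENS activities, new state
slrc_step <- function(model, state, u_t, inhibit = FALSE) {
  cfg <- model$config
  d <- cfg$d
  af <- exp(-cfg$dt / cfg$tau)
  ar <- exp(-cfg$dt / cfg$tau_readout)
  inh <- if (inhibit) -cfg$inhibit_magnitude else 0
  # decode current reservoir state from each scalar ensemble
  xhat <- numeric(d)
  rates_res <- vector("list", d)
  for (i in seq_len(d)) {
    r <- ensemble_rates(model$res[[i]], state$w_res[i], inh)
    if (cfg$mode == "spiking") {
      n <- model$res[[i]]$n
      vidx <- ((i - 1) * cfg$n_sn + 1):((i - 1) * cfg$n_sn + n)
      v <- state$v_res[vidx] + as.numeric(r) * cfg$dt
      s <- as.numeric(v >= 1)
      state$v_res[vidx] <- v - s
      r <- matrix(s / cfg$dt, 1)   # spike impulses, filtered downstream
    }
    rates_res[[i]] <- as.numeric(r)
    xhat[i] <- as.numeric(r %*% model$res_decoders[[i]])
  }
  # recurrent + input drive, filtered by the tau synapse
  drive <- as.numeric(model$ldn$A_prime %*% xhat) + model$ldn$B_prime * u_t
  state$w_res <- af * state$w_res + (1 - af) * drive
  # aggregating ensemble: identity connection with the readout synapse
  state$w_ens <- ar * state$w_ens + (1 - ar) * xhat
  a_ens <- ensemble_rates(model$ens, matrix(state$w_ens, 1))
  if (cfg$mode == "spiking") {
    v <- state$v_ens + as.numeric(a_ens) * cfg$dt
    s <- as.numeric(v >= 1)
    state$v_ens <- v - s
    a_ens <- matrix(s / cfg$dt, 1)
  }
  list(state = state, xhat = xhat, ens_rates = as.numeric(a_ens))
}

#' Simulate the SLRC reservoir over one signal
#'
#' Steps the neural LDN for each sample of the signal and collects the
#' aggregating ensemble's activities together with the decoded reservoir
#' state. When `inhibit_before` is set, a negative current of the
#' configured magnitude is first injected into all reservoir neurons (with
#' zero input) for the configured duration, clearing residual memory of the
#' previous sample. In spiking mode the ensemble activities are binary
#' spike trains low-pass filtered with the readout synapse before use.
#'
#' @param model an [build_slrc()] model (an [slrc_config()] is accepted and
#'   built on the fly).
#' @param signal numeric input signal.
#' @param inhibit_before apply the inter-sample inhibition window first.
#' @param state optional persistent state from a previous call.
#' @return list with `ens_activity` (`T x N_ens` Hz), `decoded`
#'   (`T x d` decoded reservoir state), `inhib_decoded` (decoded state at
#'   the end of the inhibition window, or `NULL`), and `state`.
#' @export
simulate_slrc <- function(model, signal, inhibit_before = FALSE,
                          state = NULL) {
  if (inherits(model, "slrc_config")) model <- build_slrc(model)
  stopifnot(inherits(model, "slrc_model"))
  signal <- as.numeric(signal)
  if (any(!is.finite(signal))) stop_invalid("signal contains non-finite values")
  cfg <- model$config
  if (is.null(state)) state <- slrc_state(model)
  ar <- exp(-cfg$dt / cfg$tau_readout)
  spiking <- cfg$mode == "spiking"
  inhib_decoded <- NULL
  filt_ens <- numeric(model$ens$n)
  filt_dec <- numeric(cfg$d)
  if (inhibit_before && cfg$inhibit_duration > 0) {
    for (k in seq_len(cfg$inhibit_duration)) {
      st <- slrc_step(model, state, 0, inhibit = TRUE)
      state <- st$state
      filt_ens <- ar * filt_ens + (1 - ar) * st$ens_rates
      filt_dec <- ar * filt_dec + (1 - ar) * st$xhat
    }
    inhib_decoded <- if (spiking) filt_dec else st$xhat
  }
  T_len <- length(signal)
  acts <- matrix(0, T_len, model$ens$n)
  dec <- matrix(0, T_len, cfg$d)
  for (t in seq_len(T_len)) {
    st <- slrc_step(model, state, signal[t])
    state <- st$state
    if (spiking) {
      # spike impulses are low-pass filtered with the readout synapse
      # before they are used as activities or decoded state
      filt_ens <- ar * filt_ens + (1 - ar) * st$ens_rates
      filt_dec <- ar * filt_dec + (1 - ar) * st$xhat
      acts[t, ] <- filt_ens
      dec[t, ] <- filt_dec
    } else {
      acts[t, ] <- st$ens_rates
      dec[t, ] <- st$xhat
    }
  }
  list(ens_activity = acts, decoded = dec,
       inhib_decoded = inhib_decoded, state = state)
}

#' Per-sample reservoir activity summaries
#'
#' Runs every signal of a dataset through the reservoir (with the
#' inter-sample inhibition window between samples when `inhibit_between`)
#' and summarizes each sample as the mean aggregating-ensemble activity
#' over the last `ceiling(T/4)` steps of its window — one regression row
#' per sample for [fit_readout()].
#'
#' @param model an `slrc_model` (or `slrc_config`).
#' @param signals `n x T` signal matrix.
#' @param inhibit_between inhibit the reservoir before each sample.
#' @return `n x N_ens` summary matrix.
#' @export
slrc_activity_summaries <- function(model, signals, inhibit_between = TRUE) {
  if (inherits(model, "slrc_config")) model <- build_slrc(model)
  n <- nrow(signals)
  T_len <- ncol(signals)
  tail_idx <- (T_len - ceiling(T_len / 4) + 1):T_len
  out <- matrix(0, n, model$ens$n)
  state <- NULL
  for (i in seq_len(n)) {
    sim <- simulate_slrc(model, signals[i, ],
                         inhibit_before = inhibit_between && i > 1,
                         state = state)
    state <- sim$state
    out[i, ] <- colMeans(sim$ens_activity[tail_idx, , drop = FALSE])
  }
  out
}

#' Fit the SLRC readout by ridge regression
#'
#' Learns the static-to-output connection: L2-regularized least squares
#' from per-sample activity summaries to one-hot class targets.
#'
#' @param activity_summaries `n x N` matrix from
#'   [slrc_activity_summaries()].
#' @param labels 0-based integer labels, length n.
#' @param ridge_lambda L2 penalty (default `0.1 *` mean summary magnitude,
#'   matching the decoder convention).
#' @return object of class `slrc_readout` with `W` (`N x n_classes`).
#' @export
fit_readout <- function(activity_summaries, labels, ridge_lambda = NULL) {
  A <- as.matrix(activity_summaries)
  labels <- as.integer(labels)
  if (nrow(A) != length(labels)) stop_invalid("label count mismatch")
  n_classes <- max(labels) + 1L
  if (n_classes < 2L) n_classes <- 2L
  Y <- matrix(0, nrow(A), n_classes)
  Y[cbind(seq_len(nrow(A)), labels + 1L)] <- 1
  if (is.null(ridge_lambda)) ridge_lambda <- 0.1 * mean(abs(A))
  G <- crossprod(A) + ridge_lambda * diag(ncol(A))
  W <- solve(G, crossprod(A, Y))
  structure(list(W = W, n_classes = n_classes, ridge_lambda = ridge_lambda),
            class = "slrc_readout")
}

#' Classify from a readout score vector
#'
#' Class prediction scores are rounded to the nearest integer; the
#' predicted class is the node with the highest rounded score, ties broken
#' by the raw score, remaining ties by the lowest class index.
#'
#' @param readout an [fit_readout()] object.
#' @param activity_summary one summary row, or an `n x N` matrix.
#' @return 0-based predicted class (vector for a matrix input).
#' @export
classify_slrc <- function(readout, activity_summary) {
  A <- if (is.matrix(activity_summary)) activity_summary
       else matrix(activity_summary, 1)
  scores <- A %*% readout$W
  apply(scores, 1, function(s) {
    r <- round(s)
    cand <- which(r == max(r))
    cand[which.max(s[cand])] - 1L
  })
}

#' Train and evaluate an SLRC classifier
#'
#' Convenience wrapper: summarizes the training and test sets, fits the
#' readout, and reports accuracies with the rounded-score rule.
#'
#' @param model an `slrc_model` or `slrc_config`.
#' @param train_set,test_set [ts_dataset()] objects.
#' @param inhibit_between inhibit the reservoir between samples.
#' @param ridge_lambda readout L2 penalty.
#' @return list with `readout`, `train_acc`, `test_acc` (percent), and the
#'   predicted test labels.
#' @export
slrc_fit <- function(model, train_set, test_set, inhibit_between = TRUE,
                     ridge_lambda = NULL) {
  if (inherits(model, "slrc_config")) model <- build_slrc(model)
  A_tr <- slrc_activity_summaries(model, train_set$signals, inhibit_between)
  A_te <- slrc_activity_summaries(model, test_set$signals, inhibit_between)
  readout <- fit_readout(A_tr, train_set$labels, ridge_lambda)
  pred_tr <- classify_slrc(readout, A_tr)
  pred_te <- classify_slrc(readout, A_te)
  list(readout = readout,
       train_acc = 100 * mean(pred_tr == train_set$labels),
       test_acc = 100 * mean(pred_te == test_set$labels),
       test_pred = pred_te)
}
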