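#' LSNN configuration
#'
#' Hyper-parameters of the Legendre Spiking Neural Network: an LDN feature
#' extractor of order `d` and window `theta`, a rate-encoding layer of
#' `2*d` paired IF neurons, one spiking hidden layer of `3*d` IF neurons,
#' and `n_classes` non-spiking output integrators — `5*d` spiking neurons
#' in total.
#'
#' @param d LDN order (>= 1).
#' @param theta LDN window in seconds.
#' @param rho encoder gain.
#' @param iota encoder bias current.
#' @param tau_cur current time constant in seconds (hidden/output current
#'   decay `alpha`).
#' @param tau_vol voltage time constant in seconds (output voltage decay
#'   `beta`).
#' @param v_thr spike threshold.
#' @param n_classes number of classes (>= 2).
#' @param dt simulation step in seconds; one input sample advances the
#'   simulation by one step.
#' @param seed integer seed for weight initialization.
#' @param clamp_enc clamp ENC voltages below at 0 (see [neuron_params()]).
#' @return object of class `lsnn_config`.
#' @export
lsnn_config <- function(d = 10, theta = 0.12, rho = 2, iota = 0,
                        tau_cur = 10e-3, tau_vol = 20e-3, v_thr = 1,
                        n_classes = 2, dt = 0.001, seed = 1,
                        clamp_enc = TRUE) {
  if (length(d) != 1 || d < 1 || d != round(d)) {
    stop_invalid("`d` must be a positive integer")
  }
  if (length(n_classes) != 1 || n_classes < 2 || n_classes != round(n_classes)) {
    stop_invalid("`n_classes` must be an integer >= 2")
  }
  structure(
    list(d = as.integer(d), theta = theta, rho = rho, iota = iota,
         tau_cur = tau_cur, tau_vol = tau_vol, v_thr = v_thr,
         n_classes = as.integer(n_classes), dt = dt, seed = seed,
         clamp_enc = clamp_enc),
    class = "lsnn_config")
}

init_weight <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

lsnn_params_from_config <- function(cfg) {
  neuron_params(v_thr = cfg$v_thr, rho = cfg$rho, iota = cfg$iota,
                tau_cur = cfg$tau_cur, tau_vol = cfg$tau_vol,
                dt = cfg$dt, clamp_enc = cfg$clamp_enc)
}

#' Build the full LSNN model
#'
#' Layer sizes are fixed by the order: `N_ENC = 2*d`, `N_HDN = 3*d`,
#' `N_OTP = n_classes`. Only the ENC-to-HDN and HDN-to-OTP matrices are
#' trainable; the LDN and encoder connections are static. Weights are
#' initialized uniformly on `(-1/sqrt(fan_in), +1/sqrt(fan_in))` from the
#' config seed.
#'
#' @param config an [lsnn_config()].
#' @return object of class `lsnn_model` with `variant = "full"`.
#' @examples
#' m <- build_lsnn(lsnn_config(d = 10))
#' n_spiking_neurons(m)  # 50
#' @export
build_lsnn <- function(config) {
  stopifnot(inherits(config, "lsnn_config"))
  d <- config$d
  W <- with_seed(config$seed, list(
    W1 = init_weight(2 * d, 3 * d),
    W2 = init_weight(3 * d, config$n_classes)))
  structure(
    list(config = config,
         ldn = ldn_spec(d, config$theta, dt = config$dt),
         params = lsnn_params_from_config(config),
         W1 = W$W1, W2 = W$W2, variant = "full"),
    class = "lsnn_model")
}

#' Build the no-hidden-layer LSNN variant
#'
#' Ablation with the spiking hidden layer removed: the `2*d` encoding
#' neurons connect directly to the output integrators through a single
#' trainable `2d x n_classes` matrix, mirroring a conventional reservoir
#' readout.
#'
#' @param config an [lsnn_config()].
#' @return `lsnn_model` with `variant = "nhdn"`.
#' @export
build_lsnn_nhdn <- function(config) {
  stopifnot(inherits(config, "lsnn_config"))
  d <- config$d
  W <- with_seed(config$seed, list(
    W1 = init_weight(2 * d, config$n_classes)))
  structure(
    list(config = config,
         ldn = ldn_spec(d, config$theta, dt = config$dt),
         params = lsnn_params_from_config(config),
         W1 = W$W1, W2 = NULL, variant = "nhdn"),
    class = "lsnn_model")
}

#' Build the non-spiking LSNN counterpart
#'
#' Ablation replacing spiking neurons with rectified-linear units: an input
#' layer of `d` nodes fed the LDN features directly, a hidden ReLU layer of
#' width `3*d`, and the same leaky output integrators with the
#' max-then-softmax negative-log-likelihood loss. Fully differentiable, so
#' its gradients admit finite-difference checks.
#'
#' @param config an [lsnn_config()].
#' @return `lsnn_model` with `variant = "nspk"`.
#' @export
build_lsnn_nspk <- function(config) {
  stopifnot(inherits(config, "lsnn_config"))
  d <- config$d
  W <- with_seed(config$seed, list(
    W1 = init_weight(d, 3 * d),
    W2 = init_weight(3 * d, config$n_classes)))
  structure(
    list(config = config,
         ldn = ldn_spec(d, config$theta, dt = config$dt),
         params = lsnn_params_from_config(config),
         W1 = W$W1, W2 = W$W2, variant = "nspk"),
    class = "lsnn_model")
}

#' @export
print.lsnn_model <- function(x, ...) {
  cat(sprintf("<lsnn_model variant=%s> d=%d theta=%g classes=%d spiking neurons=%d\n",
              x$variant, x$config$d, x$config$theta, x$config$n_classes,
              n_spiking_neurons(x)))
  invisible(x)
}

#' Count spiking neurons in a model
#'
#' The full LSNN uses `2*d` encoding plus `3*d` hidden neurons, i.e. `5*d`
#' spiking neurons; the no-hidden-layer variant uses `2*d`; the non-spiking
#' variant none.
#'
#' @param model an `lsnn_model`.
#' @return integer count.
#' @export
n_spiking_neurons <- function(model) {
  stopifnot(inherits(model, "lsnn_model"))
  d <- model$config$d
  switch(model$variant,
         full = 5L * d,
         nhdn = 2L * d,
         nspk = 0L)
}

#' Trainable weight matrices of a model
#'
#' @param model an `lsnn_model`.
#' @return named list of matrices (`W1`, and `W2` where present).
#' @export
trainable_weights <- function(model) {
  if (is.null(model$W2)) list(W1 = model$W1) else list(W1 = model$W1, W2 = model$W2)
}

# ---- batched simulation engine ------------------------------------------

# ENC spike trains for a batch: Farr is a B x T x d feature array; returns
# a length-T list of B x 2d spike matrices. The ENC layer has no trainable
# upstream parameters, so its spikes can be computed once and cached for a
# whole training run.
enc_spikes_batch <- function(Farr, params) {
  B <- dim(Farr)[1]; T_len <- dim(Farr)[2]; d <- dim(Farr)[3]
  pos <- seq(1, 2 * d, by = 2)
  neg <- seq(2, 2 * d, by = 2)
  V <- matrix(0, B, 2 * d)
  S_list <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    X <- matrix(Farr[, t, ], B, d)
    I <- matrix(0, B, 2 * d)
    I[, pos] <- params$rho * X + params$iota
    I[, neg] <- -params$rho * X + params$iota
    V <- V + I
    if (isTRUE(params$clamp_enc)) V[V < 0] <- 0
    S <- (V >= params$v_thr) * 1
    V[S == 1] <- 0
    S_list[[t]] <- S
  }
  S_list
}

# Batched forward pass. `inputs` is a length-T list of B x m matrices
# (ENC spikes for spiking variants, raw features for nspk). Returns output
# voltage trace (B x C x T) plus the caches needed for the backward pass.
lsnn_forward_cache <- function(model, inputs, keep_cache = TRUE) {
  p <- model$params
  T_len <- length(inputs)
  B <- nrow(inputs[[1]])
  C <- model$config$n_classes
  a <- p$alpha; b <- p$beta
  Vo_arr <- array(0, c(B, C, T_len))
  Io <- Vo <- matrix(0, B, C)
  cache <- NULL
  if (model$variant == "full") {
    nh <- ncol(model$W1)
    Ih <- Vh <- matrix(0, B, nh)
    Sh_list <- if (keep_cache) vector("list", T_len)
    pre_list <- if (keep_cache) vector("list", T_len)
    for (t in seq_len(T_len)) {
      Ih <- a * Ih + inputs[[t]] %*% model$W1
      Vh_pre <- Vh + Ih
      Sh <- (Vh_pre >= p$v_thr) * 1
      Vh <- Vh_pre * (1 - Sh)
      Io <- a * Io + Sh %*% model$W2
      Vo <- b * Vo + Io
      Vo_arr[, , t] <- Vo
      if (keep_cache) {
        Sh_list[[t]] <- Sh
        pre_list[[t]] <- Vh_pre - p$v_thr
      }
    }
    if (keep_cache) cache <- list(Sh = Sh_list, pre = pre_list)
  } else if (model$variant == "nhdn") {
    for (t in seq_len(T_len)) {
      Io <- a * Io + inputs[[t]] %*% model$W1
      Vo <- b * Vo + Io
      Vo_arr[, , t] <- Vo
    }
  } else { # nspk
    H_list <- if (keep_cache) vector("list", T_len)
    pre_list <- if (keep_cache) vector("list", T_len)
    for (t in seq_len(T_len)) {
      pre <- inputs[[t]] %*% model$W1
      H <- pmax(pre, 0)
      Io <- a * Io + H %*% model$W2
      Vo <- b * Vo + Io
      Vo_arr[, , t] <- Vo
      if (keep_cache) {
        H_list[[t]] <- H
        pre_list[[t]] <- pre
      }
    }
    if (keep_cache) cache <- list(H = H_list, pre = pre_list)
  }
  list(Vo = Vo_arr, cache = cache)
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# Maxima over time of the output voltage trace plus per-(sample, class)
# argmax step (first maximum wins), used by the loss and its gradient.
voltage_maxima <- function(Vo_arr) {
  B <- dim(Vo_arr)[1]; C <- dim(Vo_arr)[2]
  M <- matrix(0, B, C)
  Tstar <- matrix(0L, B, C)
  for (cc in seq_len(C)) {
    Vc <- matrix(Vo_arr[, cc, ], B)
    Tstar[, cc] <- max.col(Vc, ties.method = "first")
    M[, cc] <- Vc[cbind(seq_len(B), Tstar[, cc])]
  }
  list(M = M, Tstar = Tstar)
}

# Backward pass through time; surrogate derivative replaces the Heaviside
# derivative at hidden spikes, and the hard-reset assignment is excluded
# from the gradient path (the (1 - S) gate is treated as a constant).
lsnn_backward <- function(model, inputs, fwd, y) {
  p <- model$params
  a <- p$alpha; b <- p$beta
  T_len <- length(inputs)
  B <- dim(fwd$Vo)[1]; C <- dim(fwd$Vo)[2]
  vm <- voltage_maxima(fwd$Vo)
  P <- softmax_rows(vm$M)
  Yh <- matrix(0, B, C)
  Yh[cbind(seq_len(B), y + 1L)] <- 1
  G <- (P - Yh) / B
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y + 1L)], 1e-300)))
  gVo <- gIo <- matrix(0, B, C)
  if (model$variant == "full") {
    gW1 <- matrix(0, nrow(model$W1), ncol(model$W1))
    gW2 <- matrix(0, nrow(model$W2), ncol(model$W2))
    nh <- ncol(model$W1)
    gIh <- matrix(0, B, nh)
    carry <- matrix(0, B, nh)
    for (t in rev(seq_len(T_len))) {
      gVo <- G * (vm$Tstar == t) + b * gVo
      gIo <- gVo + a * gIo
      Sh <- fwd$cache$Sh[[t]]
      gW2 <- gW2 + crossprod(Sh, gIo)
      gSh <- gIo %*% t(model$W2)
      gVh_pre <- gSh * surrogate_grad(fwd$cache$pre[[t]]) + carry * (1 - Sh)
      gIh <- gVh_pre + a * gIh
      gW1 <- gW1 + crossprod(inputs[[t]], gIh)
      carry <- gVh_pre
    }
    list(loss = loss, grads = list(W1 = gW1, W2 = gW2), P = P, M = vm$M)
  } else if (model$variant == "nhdn") {
    gW1 <- matrix(0, nrow(model$W1), ncol(model$W1))
    for (t in rev(seq_len(T_len))) {
      gVo <- G * (vm$Tstar == t) + b * gVo
      gIo <- gVo + a * gIo
      gW1 <- gW1 + crossprod(inputs[[t]], gIo)
    }
    list(loss = loss, grads = list(W1 = gW1), P = P, M = vm$M)
  } else { # nspk
    gW1 <- matrix(0, nrow(model$W1), ncol(model$W1))
    gW2 <- matrix(0, nrow(model$W2), ncol(model$W2))
    for (t in rev(seq_len(T_len))) {
      gVo <- G * (vm$Tstar == t) + b * gVo
      gIo <- gVo + a * gIo
      H <- fwd$cache$H[[t]]
      gW2 <- gW2 + crossprod(H, gIo)
      gH <- (gIo %*% t(model$W2)) * (fwd$cache$pre[[t]] > 0)
      gW1 <- gW1 + crossprod(inputs[[t]], gH)
    }
    list(loss = loss, grads = list(W1 = gW1, W2 = gW2), P = P, M = vm$M)
  }
}

# Convert a B x T x d feature array into the per-step input list the engine
# consumes for the given variant (ENC spikes, or raw features for nspk).
lsnn_inputs_from_features <- function(model, Farr) {
  if (model$variant == "nspk") {
    T_len <- dim(Farr)[2]
    lapply(seq_len(T_len), function(t) {
      matrix(Farr[, t, ], dim(Farr)[1], dim(Farr)[3])
    })
  } else {
    enc_spikes_batch(Farr, model$params)
  }
}

# LDN features for every row of an n x T signal matrix -> B x T x d array.
features_array <- function(signals, ldn) {
  B <- nrow(signals); T_len <- ncol(signals); d <- ldn$d
  Farr <- array(0, c(B, T_len, d))
  for (i in seq_len(B)) {
    Farr[i, , ] <- unclass(extract_features(signals[i, ], ldn))
  }
  Farr
}

#' LSNN forward pass on a single signal
#'
#' Extracts LDN features for the whole signal first, then steps the spiking
#' network (ENC, HDN, OTP for the full variant) from zero states for `T`
#' steps. The prediction is the class whose output node attains the largest
#' maximum-over-time voltage; ties break to the lowest class index.
#'
#' @param model an `lsnn_model`.
#' @param u numeric signal.
#' @return list with `V_otp_trace` (`T x n_classes` matrix), `prediction`
#'   (0-based class index), and `max_V` (per-class maxima).
#' @export
lsnn_forward <- function(model, u) {
  stopifnot(inherits(model, "lsnn_model"))
  u <- as.numeric(u)
  if (any(!is.finite(u))) stop_invalid("signal contains non-finite values")
  Farr <- features_array(matrix(u, 1), model$ldn)
  inputs <- lsnn_inputs_from_features(model, Farr)
  fwd <- lsnn_forward_cache(model, inputs, keep_cache = FALSE)
  Vt <- t(matrix(fwd$Vo[1, , ], dim(fwd$Vo)[2]))
  maxV <- apply(Vt, 2, max)
  list(V_otp_trace = Vt,
       prediction = which.max(maxV) - 1L,
       max_V = maxV)
}

#' Batched LSNN prediction
#'
#' @param model an `lsnn_model`.
#' @param signals `n x T` matrix, one signal per row.
#' @return integer vector of 0-based predicted classes.
#' @export
lsnn_predict <- function(model, signals) {
  Farr <- features_array(signals, model$ldn)
  inputs <- lsnn_inputs_from_features(model, Farr)
  fwd <- lsnn_forward_cache(model, inputs, keep_cache = FALSE)
  vm <- voltage_maxima(fwd$Vo)
  max.col(vm$M, ties.method = "first") - 1L
}

#' Max-voltage softmax classification loss
#'
#' Mean over the batch of the negative log-likelihood of
#' `log(softmax(max_t V[t]))` at the true class: each class node's score is
#' the maximum of its output voltage over all simulation steps.
#'
#' @param V_otp_traces a `B x C x T` array, or a list of `T x C` matrices
#'   (one per sample), or a single `T x C` matrix.
#' @param y_true integer 0-based labels.
#' @return scalar loss.
#' @export
classification_loss <- function(V_otp_traces, y_true) {
  if (is.list(V_otp_traces)) {
    B <- length(V_otp_traces)
    C <- ncol(V_otp_traces[[1]])
    arr <- array(0, c(B, C, nrow(V_otp_traces[[1]])))
    for (i in seq_len(B)) arr[i, , ] <- t(V_otp_traces[[i]])
    V_otp_traces <- arr
  } else if (is.matrix(V_otp_traces)) {
    arr <- array(0, c(1, ncol(V_otp_traces), nrow(V_otp_traces)))
    arr[1, , ] <- t(V_otp_traces)
    V_otp_traces <- arr
  }
  B <- dim(V_otp_traces)[1]
  C <- dim(V_otp_traces)[2]
  y_true <- as.integer(y_true)
  if (length(y_true) != B) stop_invalid("label count does not match batch size")
  if (any(y_true < 0 | y_true >= C)) stop_invalid("label outside class range")
  vm <- voltage_maxima(V_otp_traces)
  P <- softmax_rows(vm$M)
  -mean(log(pmax(P[cbind(seq_len(B), y_true + 1L)], 1e-300)))
}

#' Save an LSNN model as plain text
#'
#' Writes a directory containing `config.txt` (key=value lines) and one CSV
#' per weight matrix; [load_lsnn()] restores it.
#'
#' @param model an `lsnn_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_lsnn <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  keys <- c("d", "theta", "rho", "iota", "tau_cur", "tau_vol", "v_thr",
            "n_classes", "dt", "seed", "clamp_enc")
  lines <- c(paste0("variant=", model$variant),
             vapply(keys, function(k) {
               paste0(k, "=", format(cfg[[k]], digits = 17))
             }, character(1)))
  writeLines(lines, file.path(dir, "config.txt"))
  write_mat <- function(W, path) {
    # %.17g keeps the text round-trip exact in double precision
    writeLines(apply(W, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = ",")
    }), path)
  }
  write_mat(model$W1, file.path(dir, "W1.csv"))
  if (!is.null(model$W2)) write_mat(model$W2, file.path(dir, "W2.csv"))
  invisible(dir)
}

#' Load an LSNN model saved by [save_lsnn()]
#'
#' @param dir directory written by [save_lsnn()].
#' @return an `lsnn_model`.
#' @export
load_lsnn <- function(dir) {
  lines <- readLines(file.path(dir, "config.txt"))
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  num <- function(k) as.numeric(vals[[k]])
  cfg <- lsnn_config(d = num("d"), theta = num("theta"), rho = num("rho"),
                     iota = num("iota"), tau_cur = num("tau_cur"),
                     tau_vol = num("tau_vol"), v_thr = num("v_thr"),
                     n_classes = num("n_classes"), dt = num("dt"),
                     seed = num("seed"),
                     clamp_enc = as.logical(vals[["clamp_enc"]]))
  builder <- switch(vals[["variant"]],
                    full = build_lsnn, nhdn = build_lsnn_nhdn,
                    nspk = build_lsnn_nspk)
  model <- builder(cfg)
  model$W1 <- as.matrix(utils::read.table(file.path(dir, "W1.csv"), sep = ","))
  dimnames(model$W1) <- NULL
  w2 <- file.path(dir, "W2.csv")
  if (file.exists(w2)) {
    model$W2 <- as.matrix(utils::read.table(w2, sep = ","))
    dimnames(model$W2) <- NULL
  }
  model
}
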