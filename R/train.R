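#' Training configuration
#'
#' @param eta Adam learning rate.
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size; the training-set size must be
#'   divisible by it (see [trim_to_batch()]).
#' @param shuffle_every epochs between reshuffles of the training data
#'   (default 20).
#' @param seeds integer seeds, one training run per seed.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return object of class `train_config`.
#' @export
train_config <- function(eta = 0.01, epochs = 50, batch_size = 50,
                         shuffle_every = 20, seeds = c(6, 9, 100),
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(epochs >= 1, batch_size >= 1, shuffle_every >= 1,
            length(seeds) >= 1)
  structure(
    list(eta = eta, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         shuffle_every = as.integer(shuffle_every),
         seeds = as.integer(seeds),
         beta1 = beta1, beta2 = beta2, eps = eps),
    class = "train_config")
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_update <- function(weights, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (k in names(weights)) {
    state$m[[k]] <- cfg$beta1 * state$m[[k]] + (1 - cfg$beta1) * grads[[k]]
    state$v[[k]] <- cfg$beta2 * state$v[[k]] + (1 - cfg$beta2) * grads[[k]]^2
    weights[[k]] <- weights[[k]] -
      cfg$eta * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + cfg$eps)
  }
  list(weights = weights, state = state)
}

set_weights <- function(model, weights) {
  model$W1 <- weights$W1
  if (!is.null(weights$W2)) model$W2 <- weights$W2
  model
}

# Precompute everything about a dataset that is static during training:
# LDN features and, for spiking variants, ENC spike trains.
prepare_inputs <- function(model, dataset) {
  Farr <- features_array(dataset$signals, model$ldn)
  lsnn_inputs_from_features(model, Farr)
}

subset_inputs <- function(inputs, idx) {
  lapply(inputs, function(m) m[idx, , drop = FALSE])
}

#' Train an LSNN model
#'
#' Backpropagation through time with the fast-sigmoid surrogate derivative
#' substituted for the Heaviside derivative at hidden-layer spikes, using
#' the Adam optimizer. LDN features (and ENC spike trains, which do not
#' depend on any trainable weight) are extracted once for the whole
#' training and test set before the epochs begin. The training data are
#' reshuffled every `cfg$shuffle_every` epochs; batches are contiguous
#' slices after shuffling; test accuracy is evaluated on the entire test
#' set every epoch, and the run's reported accuracy is the best epoch's.
#'
#' @param model an `lsnn_model` (any variant).
#' @param train_set,test_set `ts_dataset` objects (see [ts_dataset()]).
#' @param cfg a [train_config()]; the first seed is used for this run
#'   unless `seed` is given.
#' @param seed run seed controlling shuffling (defaults to `cfg$seeds[1]`).
#' @param log_file optional path: one line per epoch (epoch, train loss,
#'   test accuracy) is appended.
#' @return list of class `train_result` with `test_acc` (per-epoch
#'   percentages), `train_loss`, `max_acc`, `best_epoch`, `best_weights`,
#'   and the trained `model` (best weights installed).
#' @export
train_lsnn <- function(model, train_set, test_set, cfg, seed = NULL,
                       log_file = NULL) {
  stopifnot(inherits(model, "lsnn_model"), inherits(cfg, "train_config"))
  n <- n_samples(train_set)
  if (n %% cfg$batch_size != 0) {
    stop_invalid("training-set size ", n, " is not divisible by batch_size ",
                 cfg$batch_size, "; trim it with trim_to_batch()")
  }
  if (is.null(seed)) seed <- cfg$seeds[1]
  train_inputs <- prepare_inputs(model, train_set)
  test_inputs <- prepare_inputs(model, test_set)
  y_train <- train_set$labels
  y_test <- test_set$labels
  weights <- trainable_weights(model)
  opt <- adam_init(weights)
  n_batches <- n %/% cfg$batch_size
  order_idx <- seq_len(n)
  test_acc <- numeric(cfg$epochs)
  train_loss <- numeric(cfg$epochs)
  best_acc <- -Inf
  best_weights <- weights
  best_epoch <- 0L
  with_seed(derive_seed(seed, 77), {
    for (epoch in seq_len(cfg$epochs)) {
      if ((epoch - 1) %% cfg$shuffle_every == 0) {
        order_idx <- sample.int(n)
      }
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        idx <- order_idx[((bi - 1) * cfg$batch_size + 1):(bi * cfg$batch_size)]
        inputs <- subset_inputs(train_inputs, idx)
        model <- set_weights(model, weights)
        fwd <- lsnn_forward_cache(model, inputs, keep_cache = TRUE)
        bwd <- lsnn_backward(model, inputs, fwd, y_train[idx])
        epoch_loss <- epoch_loss + bwd$loss
        upd <- adam_update(weights, bwd$grads, opt, cfg)
        weights <- upd$weights
        opt <- upd$state
      }
      model <- set_weights(model, weights)
      fwd <- lsnn_forward_cache(model, test_inputs, keep_cache = FALSE)
      vm <- voltage_maxima(fwd$Vo)
      pred <- max.col(vm$M, ties.method = "first") - 1L
      acc <- 100 * mean(pred == y_test)
      test_acc[epoch] <- acc
      train_loss[epoch] <- epoch_loss / n_batches
      if (acc > best_acc) {
        best_acc <- acc
        best_weights <- weights
        best_epoch <- epoch
      }
      if (!is.null(log_file)) {
        cat(sprintf("epoch %d train_loss %.6f test_acc %.4f\n",
                    epoch, train_loss[epoch], acc),
            file = log_file, append = TRUE)
      }
    }
  })
  model <- set_weights(model, best_weights)
  structure(
    list(test_acc = test_acc, train_loss = train_loss,
         max_acc = best_acc, best_epoch = best_epoch,
         best_weights = best_weights, model = model, seed = seed),
    class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs, max test accuracy %.2f%% (epoch %d)\n",
              length(x$test_acc), x$max_acc, x$best_epoch))
  invisible(x)
}

#' Aggregate per-run maxima into Max/Mean accuracy
#'
#' `Max_acc` is the maximum test accuracy over all hyper-parameter
#' combinations and seeds; `Mean_acc` is the mean, with its sample standard
#' deviation (n-1 denominator), of the per-seed maxima (each seed's best
#' accuracy over all combinations).
#'
#' @param runs data.frame with columns `combo`, `seed`, `max_acc`.
#' @return list with `max_acc`, `mean_acc`, `sd_acc`, `per_seed_max`.
#' @export
aggregate_grid <- function(runs) {
  stopifnot(all(c("combo", "seed", "max_acc") %in% names(runs)))
  per_seed <- tapply(runs$max_acc, runs$seed, max)
  list(max_acc = max(runs$max_acc),
       mean_acc = mean(per_seed),
       sd_acc = if (length(per_seed) > 1) stats::sd(per_seed) else 0,
       per_seed_max = per_seed)
}

#' Exhaustive hyper-parameter grid search
#'
#' Trains one model per element of the Cartesian product of `grid` values
#' crossed with `cfg$seeds`, with a fresh weight initialization per run,
#' and aggregates per the Max/Mean accuracy accounting of
#' [aggregate_grid()].
#'
#' @param builder model builder taking an [lsnn_config()] (e.g.
#'   [build_lsnn()]).
#' @param base_config an [lsnn_config()] supplying values not in the grid.
#' @param train_set,test_set datasets.
#' @param cfg a [train_config()]; `eta` may appear in the grid.
#' @param grid named list of value vectors over [lsnn_config()] fields
#'   and/or `eta`.
#' @param summary_csv optional path for a per-run summary table
#'   (combo id, seed, max accuracy).
#' @return list of class `grid_result` with `runs` (data.frame), `max_acc`,
#'   `mean_acc`, `sd_acc`, `best_run`.
#' @export
grid_search <- function(builder, base_config, train_set, test_set, cfg,
                        grid, summary_csv = NULL) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop_invalid("grid must be a non-empty named list of value vectors")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- list()
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    for (seed in cfg$seeds) {
      run_cfg <- base_config
      run_trn <- cfg
      for (k in names(combos)) {
        if (k == "eta") run_trn$eta <- combos[ci, k]
        else run_cfg[[k]] <- combos[ci, k]
      }
      run_cfg$seed <- derive_seed(seed, ci)
      model <- builder(run_cfg)
      res <- train_lsnn(model, train_set, test_set, run_trn, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        combo = ci, seed = seed, max_acc = res$max_acc)
      if (is.null(best) || res$max_acc > best$max_acc) {
        best <- list(combo = ci, seed = seed, max_acc = res$max_acc,
                     result = res)
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- aggregate_grid(runs)
  if (!is.null(summary_csv)) {
    utils::write.csv(runs, summary_csv, row.names = FALSE)
  }
  structure(
    list(runs = runs, combos = combos,
         max_acc = agg$max_acc, mean_acc = agg$mean_acc,
         sd_acc = agg$sd_acc, per_seed_max = agg$per_seed_max,
         best_run = best),
    class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d runs; Max_acc %.2f%%, Mean_acc %.2f +/- %.2f%%\n",
              nrow(x$runs), x$max_acc, x$mean_acc, x$sd_acc))
  invisible(x)
}

#' Analytic gradients for finite-difference checking
#'
#' Computes the loss and analytic weight gradients of a model on a batch,
#' as used by the trainer; intended for gradient verification on the
#' differentiable (`nspk`) variant.
#'
#' @param model an `lsnn_model`.
#' @param signals `n x T` signal matrix.
#' @param y 0-based labels.
#' @return list with `loss` and `grads`.
#' @export
lsnn_loss_grads <- function(model, signals, y) {
  Farr <- features_array(signals, model$ldn)
  inputs <- lsnn_inputs_from_features(model, Farr)
  fwd <- lsnn_forward_cache(model, inputs, keep_cache = TRUE)
  bwd <- lsnn_backward(model, inputs, fwd, y)
  list(loss = bwd$loss, grads = bwd$grads)
}
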