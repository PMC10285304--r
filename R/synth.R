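#' Synthetic binary-class signal specification
#'
#' Defines a two-class univariate fixture generator whose defaults mirror
#' the shape of the ECG5000 task (140-step signals, two balanced classes)
#' so the same model grids run unchanged on fixtures. Two morphology modes:
#' `bump_polarity` — class 0 carries an upward Gaussian bump at a uniformly
#' random latency and class 1 a downward bump (an ECG-like morphology
#' difference); `frequency` — sinusoids whose two frequencies are separated
#' by `class_gap`. Gaussian noise of sd `noise_sigma` is added to every
#' sample.
#'
#' @param n_train,n_test sample counts (class balance is exactly 50/50, the
#'   extra sample of an odd count going to class 0).
#' @param T_len signal length in steps (default 140).
#' @param noise_sigma additive Gaussian noise sd (default 0.1).
#' @param class_gap morphological separation in `[0, 1]`: the bump
#'   amplitude, or the fractional frequency separation (default 1).
#' @param mode `"bump_polarity"` or `"frequency"`.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_train = 200, n_test = 100, T_len = 140,
                       noise_sigma = 0.1, class_gap = 1,
                       mode = c("bump_polarity", "frequency"), seed = 1) {
  mode <- match.arg(mode)
  if (n_train < 2 || n_test < 2 || T_len < 20) {
    stop_invalid("need n_train, n_test >= 2 and T_len >= 20")
  }
  if (class_gap < 0 || class_gap > 1) {
    stop_invalid("`class_gap` must lie in [0, 1]")
  }
  structure(
    list(n_train = as.integer(n_train), n_test = as.integer(n_test),
         T_len = as.integer(T_len), noise_sigma = noise_sigma,
         class_gap = class_gap, mode = mode, seed = as.integer(seed)),
    class = "synth_spec")
}

balanced_labels <- function(n) {
  n0 <- ceiling(n / 2)
  c(rep(0L, n0), rep(1L, n - n0))
}

synth_signals <- function(spec, labels) {
  T_len <- spec$T_len
  n <- length(labels)
  tt <- seq_len(T_len)
  X <- matrix(0, n, T_len)
  if (spec$mode == "bump_polarity") {
    width <- T_len / 12
    centers <- stats::runif(n, 0.2 * T_len, 0.8 * T_len)
    amp <- spec$class_gap
    for (i in seq_len(n)) {
      bump <- amp * exp(-(tt - centers[i])^2 / (2 * width^2))
      X[i, ] <- if (labels[i] == 0L) bump else -bump
    }
  } else {
    # frequencies in cycles per signal; zero-mean sinusoids
    f0 <- 2
    f1 <- f0 * (1 + spec$class_gap)
    phases <- stats::runif(n, 0, 2 * pi)
    for (i in seq_len(n)) {
      f <- if (labels[i] == 0L) f0 else f1
      X[i, ] <- sin(2 * pi * f * tt / T_len + phases[i])
    }
  }
  X + matrix(stats::rnorm(n * T_len, sd = spec$noise_sigma), n, T_len)
}

#' Generate synthetic train/test datasets
#'
#' @param spec a [synth_spec()].
#' @return list with `train` and `test` [ts_dataset()] objects.
#' @examples
#' sets <- generate_synth(synth_spec(n_train = 20, n_test = 10))
#' table(sets$train$labels)
#' @export
generate_synth <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    lab_tr <- balanced_labels(spec$n_train)
    lab_te <- balanced_labels(spec$n_test)
    X_tr <- synth_signals(spec, lab_tr)
    X_te <- synth_signals(spec, lab_te)
    list(train = ts_dataset(X_tr, lab_tr, c("0", "1"), "train"),
         test = ts_dataset(X_te, lab_te, c("0", "1"), "test"))
  })
}

#' Threshold oracle classifier for bump-polarity fixtures
#'
#' Classifies each signal by the sign of its extremum of largest absolute
#' value: positive extremum predicts class 0 (upward bump), negative
#' class 1. Independent of every model in the package; used to verify
#' fixture separability.
#'
#' @param signals `n x T` matrix.
#' @return integer 0/1 predictions.
#' @export
signed_extremum_classifier <- function(signals) {
  ext <- apply(signals, 1, function(s) s[which.max(abs(s))])
  as.integer(ext < 0)
}
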