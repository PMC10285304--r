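#' Run an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so package internals never
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 2654435761 + as.numeric(k) * 40503) %% 2147483647
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the standard deviation of the reference signal, the
#' usual figure of merit for delay-decoder and reservoir-tracking accuracy.
#'
#' @param est estimated values.
#' @param ref reference values (same length/shape).
#' @return scalar NRMSE.
#' @export
nrmse <- function(est, ref) {
  s <- stats::sd(as.numeric(ref))
  if (s == 0) {
    return(sqrt(mean((est - ref)^2)))
  }
  sqrt(mean((est - ref)^2)) / s
}

#' Band-limited Gaussian noise probe
#'
#' White Gaussian noise with all Fourier components above `cutoff` Hz
#' removed, rescaled to unit standard deviation. Used as a probe signal
#' for delay-decoder fitting and reservoir-fidelity checks.
#'
#' @param n number of samples.
#' @param dt sampling step in seconds.
#' @param cutoff cutoff frequency in Hz.
#' @param seed integer seed.
#' @return numeric vector of length `n`, zero mean, unit sd.
#' @export
bandlimited_noise <- function(n, dt, cutoff = 10, seed = 1) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    f <- stats::fft(x)
    freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / (n * dt)
    f[abs(freqs) > cutoff] <- 0
    y <- Re(stats::fft(f, inverse = TRUE)) / n
    y <- y - mean(y)
    y / stats::sd(y)
  })
}

#' Relative accuracy improvement in percent
#'
#' `100 * (new - baseline) / baseline`, the arithmetic used to compare a
#' model's accuracy against a published baseline.
#'
#' @param new new accuracy (percent).
#' @param baseline baseline accuracy (percent).
#' @return improvement in percent of the baseline.
#' @export
relative_improvement <- function(new, baseline) {
  stopifnot(is.numeric(new), is.numeric(baseline), all(baseline > 0))
  100 * (new - baseline) / baseline
}

#' Published benchmark accuracies
#'
#' Test accuracies (percent) on five univariate UCR-archive binary
#' classification datasets: the best LSNN / no-hidden-layer variant results
#' reported for this architecture family, alongside the liquid-state-machine
#' spiking baseline accuracies they are compared against. Stored as a small
#' CSV under `inst/extdata`.
#'
#' @return data.frame with columns `dataset`, `lsnn_max_acc`,
#'   `lsnn_nhdn_max_acc`, `lsm_baseline_acc` (NA where no spiking baseline
#'   exists).
#' @export
benchmark_accuracies <- function() {
  path <- system.file("extdata", "benchmark_accuracies.csv",
                      package = "ldnspike", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
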