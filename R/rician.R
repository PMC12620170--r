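# Rician magnitude noise.
#
# Magnitude images built from two quadrature channels with independent
# Gaussian noise of SD sigma have Rician-distributed intensities. With S0
# normalized to 1, sigma = 1/SNR, and the zero-signal mean -- the noise
# floor -- is sigma * sqrt(pi/2).

#' Rician noise model
#'
#' @param snr signal-to-noise ratio (S0 normalized to 1), > 0.
#' @param seed integer base seed for reproducible replicate streams.
#' @return An object of class `"noise_model"` with fields `snr`, `sigma`
#'   (= 1/snr), `seed`.
#' @examples
#' nm <- noise_model(snr = 20)
#' noise_floor(nm)
#' @export
noise_model <- function(snr, seed = 1L) {
  stopifnot(is.numeric(snr), length(snr) == 1L)
  if (snr <= 0) stop("snr must be > 0")
  structure(list(snr = snr, sigma = 1 / snr, seed = as.integer(seed)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Rician noise model: SNR = %g, sigma = %g, noise floor = %.4f\n",
              x$snr, x$sigma, noise_floor(x)))
  invisible(x)
}

#' Rician noise floor
#'
#' Mean magnitude when the true signal is zero (Rayleigh mean):
#' `sigma * sqrt(pi/2)`. At SNR 20 this is 0.0627, the lowest level a
#' magnitude DWI measurement can be expected to plateau at.
#'
#' @param model a [noise_model()], or a numeric SNR.
#' @return dimensionless noise floor.
#' @export
noise_floor <- function(model) {
  sigma <- if (inherits(model, "noise_model")) model$sigma else 1 / model
  sigma * sqrt(pi / 2)
}

#' Apply Rician noise to a true magnitude
#'
#' Each replicate is `sqrt((s + g1)^2 + g2^2)` with independent zero-mean
#' Gaussians g1, g2 of SD sigma. Reproducible: the stream is derived from
#' the model's seed plus `stream`, without disturbing the caller's RNG.
#'
#' @param true_magnitude true normalized signal(s), >= 0. If a vector, `n`
#'   replicates are drawn for each element (returned as a matrix with one
#'   column per signal).
#' @param model a [noise_model()].
#' @param n number of replicates per signal.
#' @param stream integer offset added to the model seed, for independent
#'   substreams (e.g. one per Monte Carlo trial).
#' @return numeric vector (single signal) or `n x length(signal)` matrix.
#' @export
apply_rician <- function(true_magnitude, model, n = 1L, stream = 0L) {
  stopifnot(inherits(model, "noise_model"), all(true_magnitude >= 0), n >= 1)
  m <- length(true_magnitude)
  out <- local_seed(model$seed + as.integer(stream), {
    g1 <- matrix(stats::rnorm(n * m, sd = model$sigma), n, m)
    g2 <- matrix(stats::rnorm(n * m, sd = model$sigma), n, m)
    sqrt(sweep(g1, 2, true_magnitude, "+")^2 + g2^2)
  })
  if (m == 1L) as.numeric(out) else out
}
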