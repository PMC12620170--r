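# Voxel signal magnitude and ADC for diffusing, flowing fluid.
#
# The normalized voxel signal is |S/S0| = exp(-b D) |F(k)|, where F is the
# characteristic function of the centered intravoxel velocity distribution
# and k follows from (b, delta, Delta) via k^2 = b Delta^2 / tau_d. The ADC
# decomposes as D - ln|F(k)|/b, i.e. molecular diffusion plus a flow term
# that depends only on the velocity dispersion within the voxel.

#' Default diffusion coefficient of cerebrospinal fluid
#'
#' Molecular diffusion coefficient of pure water at 37 degrees C,
#' 3.0e-3 mm^2/s, used as the CSF default throughout.
#' @export
D_CSF <- 3.0e-3

#' Signal attenuation of a flowing voxel
#'
#' Computes the normalized signal magnitude `exp(-b D) |F(k)|` for a
#' Stejskal-Tanner acquisition described by (b, delta, Delta) and a
#' centered intravoxel velocity distribution. The signed characteristic
#' function is retained alongside the magnitude so that sign changes of the
#' sinc factors remain visible.
#'
#' @param b diffusion weighting, s/mm^2 (vectorized).
#' @param delta pulse duration, s.
#' @param Delta pulse separation, s.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param dist a [velocity_distribution()].
#' @param complex_signal if `TRUE`, also return the complex normalized
#'   signal including the mean-velocity phase factor `exp(-i k v0)`.
#' @return A data.frame with columns `b`, `k`, `magnitude`, `signed_cf`,
#'   `adc` (NA where undefined), and optionally `signal` (complex).
#' @examples
#' d0 <- velocity_distribution()                       # no flow
#' attenuation(100, 0.02, 0.04, D = D_CSF, dist = d0)  # exp(-0.3)
#' @export
attenuation <- function(b, delta, Delta, D = D_CSF,
                        dist = velocity_distribution(),
                        complex_signal = FALSE) {
  stopifnot(inherits(dist, "velocity_distribution"), D > 0)
  k <- k_from_b(b, delta, Delta)
  cf <- flow_cf(dist, k)
  mag <- exp(-b * D) * abs(cf)
  adc <- ifelse(b > 0 & abs(cf) > 0, D - log(abs(cf)) / b, NA_real_)
  out <- data.frame(b = b, k = k, magnitude = mag, signed_cf = cf, adc = adc)
  if (complex_signal)
    out$signal <- exp(-b * D) * cf * exp(-1i * k * dist$v0)
  out
}

#' Apparent diffusion coefficient at a given b
#'
#' `ADC = -ln|S/S0| / b = D - ln|F(k)| / b`. Always at least `D`, since
#' `|F| <= 1`. Undefined at `b = 0` (use [adc_low_b_limit()]) and at zeros
#' of the characteristic function, where an error of class
#' `"flowdwi_singular_adc"` is raised.
#'
#' @inheritParams attenuation
#' @return ADC, mm^2/s.
#' @export
adc <- function(b, delta, Delta, D = D_CSF, dist = velocity_distribution()) {
  if (any(b <= 0))
    stop("adc() requires b > 0; use adc_low_b_limit() for the b -> 0 limit")
  k <- k_from_b(b, delta, Delta)
  cf <- flow_cf(dist, k)
  if (any(abs(cf) < 1e-15))
    stop(structure(class = c("flowdwi_singular_adc", "error", "condition"),
                   list(message = "characteristic function vanishes: ADC is singular",
                        call = sys.call())))
  D - log(abs(cf)) / b
}

#' Low-b limit of the ADC
#'
#' `lim_{b -> 0} ADC = D + sigma_v^2 Delta^2 / (2 tau_d)`, valid for any
#' centered velocity distribution with variance `sigma_v^2`. For the
#' Gaussian model the limit is exact at every b.
#'
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param sigma_v intravoxel velocity standard deviation, mm/s.
#' @param delta pulse duration, s.
#' @param Delta pulse separation, s.
#' @return limiting ADC, mm^2/s.
#' @export
adc_low_b_limit <- function(D, sigma_v, delta, Delta) {
  td <- tau_d(delta, Delta)
  if (td <= 0) stop("tau_d must be positive")
  D + sigma_v^2 * Delta^2 / (2 * td)
}

#' Velocity dispersion for a given flow-scaling factor
#'
#' The flow-scaling factor alpha relates the flow term of the low-b ADC to
#' molecular diffusion: `sigma_v^2 Delta^2 / (2 tau_d) = alpha D`, so the
#' limiting ADC is `(1 + alpha) D`. This inverts that relation:
#' `sigma_v = sqrt(2 alpha D tau_d) / Delta`.
#'
#' @param alpha dimensionless flow-scaling factor, >= 0.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param delta pulse duration, s.
#' @param Delta pulse separation, s.
#' @return sigma_v, mm/s.
#' @export
sigma_v_for_alpha <- function(alpha, D, delta, Delta) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  td <- tau_d(delta, Delta)
  if (td <= 0) stop("tau_d must be positive")
  sqrt(2 * alpha * D * td) / Delta
}

#' Flow-scaling factor for a given velocity dispersion
#'
#' Inverse of [sigma_v_for_alpha()]:
#' `alpha = sigma_v^2 Delta^2 / (2 tau_d D)`.
#'
#' @inheritParams sigma_v_for_alpha
#' @param sigma_v intravoxel velocity standard deviation, mm/s.
#' @return alpha, dimensionless.
#' @export
alpha_for_sigma_v <- function(sigma_v, D, delta, Delta) {
  td <- tau_d(delta, Delta)
  if (td <= 0) stop("tau_d must be positive")
  sigma_v^2 * Delta^2 / (2 * td * D)
}

#' Alpha-parameterized signal attenuation
#'
#' Because `k^2 sigma_v^2 = 2 alpha D b` for any pulse timing consistent
#' with (b, alpha), the attenuation curve parameterized by alpha is
#' independent of (delta, Delta): for the isotropic three-component model
#' (equal voxel edges and velocity gradients, so each sinc half-width
#' equals sigma_v) the magnitude is
#' `exp(-b D) |sinc(sqrt(2 alpha D b))|^3`, and for the Gaussian model
#' exactly `exp(-b D (1 + alpha))`.
#'
#' @param b diffusion weighting, s/mm^2 (vectorized).
#' @param alpha flow-scaling factor, >= 0.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param model `"isotropic3box"` (default) or `"gaussian"`.
#' @param signed if `TRUE`, return the signed value
#'   `exp(-b D) F(k)` instead of the magnitude.
#' @return normalized signal magnitude (or signed value).
#' @examples
#' alpha_attenuation(1, alpha = 1000)   # below the SNR-20 noise floor
#' @export
alpha_attenuation <- function(b, alpha, D = D_CSF,
                              model = c("isotropic3box", "gaussian"),
                              signed = FALSE) {
  model <- match.arg(model)
  if (any(b < 0)) stop("b must be >= 0")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (model == "gaussian") return(exp(-b * D * (1 + alpha)))
  ksv <- sqrt(2 * alpha * D * b)   # = k * sigma_v = k * c for equal components
  val <- exp(-b * D) * .sinc(ksv)^3
  if (signed) val else abs(val)
}

#' Tabulate a signal attenuation curve
#'
#' Convenience wrapper around [attenuation()] producing one row per b.
#'
#' @inheritParams attenuation
#' @param b_values vector of b, s/mm^2.
#' @return data.frame with columns `b_s_per_mm2`, `magnitude`, `signed_cf`,
#'   `adc`.
#' @export
signal_curve <- function(b_values, delta, Delta, D = D_CSF,
                         dist = velocity_distribution()) {
  a <- attenuation(b_values, delta, Delta, D = D, dist = dist)
  data.frame(b_s_per_mm2 = a$b, magnitude = a$magnitude,
             signed_cf = a$signed_cf, adc = a$adc)
}
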