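# Diffusion-encoding attributes of pulsed-gradient experiments.
# Units throughout: s, mm, T; b in s/mm^2, k in s/mm, gradients in T/mm.

#' Gyromagnetic ratio of the proton
#'
#' Default gyromagnetic ratio used when converting gradient amplitudes to
#' encoding attributes, in rad s^-1 T^-1.
#' @export
GAMMA_1H <- 2.67513e8

#' Stejskal-Tanner pulse pair
#'
#' Describes a pair of rectangular diffusion gradients of amplitude `G`
#' (T/mm) and duration `delta` (s), separated by `Delta` (s).
#'
#' @param G gradient amplitude, T/mm (non-negative).
#' @param delta pulse duration \eqn{\delta}, s.
#' @param Delta pulse separation \eqn{\Delta}, s; must satisfy
#'   `Delta >= delta`.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return An object of class `"st_pulse"`.
#' @examples
#' p <- st_pulse(G = 1e-5, delta = 0.02, Delta = 0.04)
#' st_b(p)
#' @export
st_pulse <- function(G, delta, Delta, gamma = GAMMA_1H) {
  stopifnot(is.numeric(G), is.numeric(delta), is.numeric(Delta),
            length(G) == 1L, length(delta) == 1L, length(Delta) == 1L)
  if (G < 0) stop("gradient amplitude G must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (delta < 0 || Delta < delta)
    stop("pulse timings must satisfy Delta >= delta >= 0")
  structure(list(G = G, delta = delta, Delta = Delta, gamma = gamma),
            class = "st_pulse")
}

#' @export
print.st_pulse <- function(x, ...) {
  cat(sprintf(
    "Stejskal-Tanner pulse: G = %g T/mm, delta = %g ms, Delta = %g ms\n",
    x$G, 1e3 * x$delta, 1e3 * x$Delta))
  cat(sprintf("  b = %g s/mm^2, k = %g s/mm, tau_d = %g ms\n",
              st_b(x), st_k(x), 1e3 * tau_d(x$delta, x$Delta)))
  invisible(x)
}

#' Effective diffusion time of a Stejskal-Tanner pair
#'
#' `tau_d = Delta - delta/3`, the effective diffusion time entering
#' `b = gamma^2 G^2 delta^2 tau_d`.
#'
#' @param delta pulse duration, s.
#' @param Delta pulse separation, s.
#' @return Effective diffusion time, s.
#' @export
tau_d <- function(delta, Delta) {
  if (any(delta < 0) || any(Delta < delta))
    stop("pulse timings must satisfy Delta >= delta >= 0")
  Delta - delta / 3
}

#' Diffusion weighting b of a Stejskal-Tanner pulse
#'
#' `b = gamma^2 G^2 delta^2 (Delta - delta/3)`, in s/mm^2.
#'
#' @param pulse an [st_pulse()].
#' @return b-value, s/mm^2.
#' @export
st_b <- function(pulse) {
  stopifnot(inherits(pulse, "st_pulse"))
  (pulse$gamma * pulse$G * pulse$delta)^2 * tau_d(pulse$delta, pulse$Delta)
}

#' First-moment weighting k of a Stejskal-Tanner pulse
#'
#' `k = gamma G delta Delta`, in s/mm. k couples the signal to velocity:
#' the flow attenuation factor is the characteristic function evaluated
#' at k.
#'
#' @param pulse an [st_pulse()].
#' @return first-moment weighting, s/mm.
#' @export
st_k <- function(pulse) {
  stopifnot(inherits(pulse, "st_pulse"))
  pulse$gamma * pulse$G * pulse$delta * pulse$Delta
}

#' First-moment weighting from (b, delta, Delta)
#'
#' Uses the identity `k^2 = b Delta^2 / tau_d`, so that flow models can be
#' driven by the routinely reported triple (b, delta, Delta) without knowing
#' the gradient amplitude. `k(b = 0) = 0` by continuity.
#'
#' @param b diffusion weighting, s/mm^2 (vectorized).
#' @param delta pulse duration, s.
#' @param Delta pulse separation, s.
#' @return first-moment weighting, s/mm.
#' @examples
#' k_from_b(100, 0.02, 0.04)
#' @export
k_from_b <- function(b, delta, Delta) {
  if (any(b < 0)) stop("b must be >= 0")
  td <- tau_d(delta, Delta)
  if (td <= 0 && any(b > 0))
    stop("tau_d <= 0: b > 0 is unattainable with these timings")
  ifelse(b == 0, 0, Delta * sqrt(b / td))
}

#' Sampled gradient waveform
#'
#' A single-axis gradient waveform sampled on a time grid, for numerical
#' evaluation of the encoding integrals when the pulse is not a
#' Stejskal-Tanner pair.
#'
#' @param times sample times, s; strictly increasing, starting at 0.
#' @param values gradient amplitude at each time, T/mm.
#' @return An object of class `"gradient_waveform"`.
#' @export
gradient_waveform <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 2L) stop("waveform needs at least 2 samples")
  if (times[1] != 0) stop("waveform must start at time 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values, T = times[length(times)]),
            class = "gradient_waveform")
}

#' Read a gradient waveform from CSV
#'
#' Expects a header and two columns: time in seconds and gradient amplitude
#' in T/mm.
#'
#' @param path CSV file path.
#' @return A [gradient_waveform()].
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("waveform CSV needs two columns (time_s, gradient_T_per_mm)")
  gradient_waveform(d[[1]], d[[2]])
}

# cumulative trapezoid integral of y over x, same length as x;
# exact when y is the piecewise-linear interpolant
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Encoding attributes of an arbitrary gradient waveform
#'
#' Computes the diffusion weighting
#' \eqn{b = \gamma^2 \int_0^T (\int_0^t G(\tau) d\tau)^2 dt} and the first
#' moment \eqn{k = \gamma \int_0^T t\,G(t)\,dt}, treating the samples as
#' the piecewise-linear interpolant of G(t). Both integrals are then
#' evaluated in closed form per interval (the inner cumulative integral is
#' piecewise quadratic, its square piecewise quartic), so the result is
#' exact for the interpolant; discretization error comes only from how
#' well the samples represent the true waveform. Represent jumps by two
#' samples a negligible time apart. A waveform whose zeroth moment does
#' not vanish carries a net phase ramp; a warning is emitted since the
#' pure-attenuation reading then does not apply.
#'
#' @param wave a [gradient_waveform()].
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return A list with elements `b` (s/mm^2), `k` (s/mm), `Delta` (NA; not
#'   defined for general waveforms).
#' @examples
#' # rectangular bipolar pair == Stejskal-Tanner
#' tt <- seq(0, 0.06, by = 1e-5)
#' G <- 1e-5 * (tt < 0.02) - 1e-5 * (tt >= 0.04)
#' waveform_bk(gradient_waveform(tt, G))
#' @export
waveform_bk <- function(wave, gamma = GAMMA_1H) {
  stopifnot(inherits(wave, "gradient_waveform"))
  tt <- wave$times
  G <- wave$values
  m0 <- .cumtrapz(tt, G)
  gmax <- max(abs(G))
  if (gmax > 0 && abs(m0[length(m0)]) > 1e-6 * gmax * wave$T)
    warning("waveform zeroth moment does not vanish; ",
            "attenuation-only interpretation is invalid")
  n <- length(tt)
  h <- diff(tt)
  g0 <- G[-n]; g1 <- G[-1]
  m00 <- m0[-n]
  cc <- (g1 - g0) / (2 * h)          # m0(tau) = m00 + g0 tau + cc tau^2
  # integral of m0^2 over each interval (quartic, closed form)
  int_m0sq <- m00^2 * h + m00 * g0 * h^2 + (g0^2 + 2 * m00 * cc) * h^3 / 3 +
    g0 * cc * h^4 / 2 + cc^2 * h^5 / 5
  # integral of t G(t) over each interval (quadratic, closed form)
  t0 <- tt[-n]
  int_tG <- t0 * g0 * h + (g0 / 2 + cc * t0) * h^2 + 2 * cc * h^3 / 3
  b <- gamma^2 * sum(int_m0sq)
  k <- gamma * sum(int_tG)
  list(b = b, k = abs(k), Delta = NA_real_)
}
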