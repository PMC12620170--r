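# Parameter-sweep drivers: b-value sweeps per flow-scaling factor,
# velocity-dispersion sensitivity per (b, delta, Delta), pulse-timing
# surfaces at fixed b, and the IVIM Monte Carlo experiment. Each driver
# returns plain data.frames and can optionally write CSV/JSON plus a
# manifest sufficient to reproduce the run.

.write_manifest <- function(out_dir, name, config, seed = NA_integer_) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) return(invisible(NULL))
  manifest <- list(experiment = name, config = config, seed = seed,
                   package = "flowdwi",
                   version = as.character(utils::packageVersion("flowdwi")))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' b-value sweep of flow-scaled attenuation curves
#'
#' Evaluates the alpha-parameterized attenuation (isotropic laminar-flow
#' model) on a log-spaced b grid, one curve per alpha. alpha = 0 is the
#' pure-diffusion reference exp(-b D).
#'
#' @param alphas flow-scaling factors (default the study set 0, 0.1, 1,
#'   10, 100, 1000).
#' @param b_range log10 range of b, s/mm^2.
#' @param points_per_decade b-grid density.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param snr SNR used only to annotate the noise-floor reference column.
#' @param out_dir optional directory; writes `sweep_b.csv` and a manifest.
#' @return data.frame with one row per (alpha, b): columns `alpha`,
#'   `b_s_per_mm2`, `magnitude`, `signed`, `noise_floor`.
#' @export
run_sweep_b <- function(alphas = c(0, 0.1, 1, 10, 100, 1000),
                        b_range = c(-2, 3.5), points_per_decade = 60,
                        D = D_CSF, snr = 20, out_dir = NULL) {
  stopifnot(length(alphas) >= 1)
  nb <- ceiling(diff(b_range) * points_per_decade) + 1
  b <- 10^seq(b_range[1], b_range[2], length.out = nb)
  out <- do.call(rbind, lapply(alphas, function(a) {
    data.frame(alpha = a, b_s_per_mm2 = b,
               magnitude = alpha_attenuation(b, a, D = D),
               signed = alpha_attenuation(b, a, D = D, signed = TRUE))
  }))
  out$noise_floor <- noise_floor(snr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep_b.csv"), row.names = FALSE)
    .write_manifest(out_dir, "sweep_b",
                    list(alphas = alphas, b_range = b_range,
                         points_per_decade = points_per_decade, D = D, snr = snr))
  }
  out
}

#' Half-attenuation velocity dispersion
#'
#' The sigma_v at which the flow factor of the isotropic model drops to
#' `level` (default 0.5), i.e. the root of `sinc(k sigma_v)^3 = level`
#' with k from (b, delta, Delta). One operationalization of "detectable"
#' dispersion; the threshold is configurable.
#'
#' @param b diffusion weighting, s/mm^2.
#' @param delta,Delta pulse timings, s.
#' @param level flow-factor threshold in (0, 1).
#' @return sigma_v, mm/s.
#' @export
sigma_v_half <- function(b, delta, Delta, level = 0.5) {
  stopifnot(level > 0, level < 1)
  k <- k_from_b(b, delta, Delta)
  f <- function(s) .sinc(k * s)^3 - level
  # bracket: sinc^3 falls below any level in (0,1) before its first zero
  stats::uniroot(f, lower = 0, upper = pi / k, tol = 1e-12)$root
}

#' Velocity-dispersion sensitivity sweep
#'
#' Attenuation magnitude versus sigma_v for each requested b and pulse
#' timing, isotropic laminar-flow model, with the Rician noise floor as a
#' reference column, plus a per-(b, timing) detectability summary: the
#' sigma_v at which the flow factor reaches 0.5.
#'
#' @param b_values b grid, s/mm^2 (default the study list).
#' @param timings_ms list of c(delta, Delta) pairs in ms.
#' @param sigma_range log10 range of sigma_v, mm/s.
#' @param points_per_decade sigma grid density.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param snr SNR for the noise-floor reference.
#' @param out_dir optional output directory.
#' @return list with `curves` (alpha rows per (b, timing, sigma_v)) and
#'   `detectability` (one row per (b, timing) with `sigma_v_half`).
#' @export
run_sweep_sigma <- function(b_values = c(1, 10, 50, 100, 200, 500, 1000),
                            timings_ms = list(c(20, 40), c(20, 100)),
                            sigma_range = c(-2, 2), points_per_decade = 50,
                            D = D_CSF, snr = 20, out_dir = NULL) {
  ns <- ceiling(diff(sigma_range) * points_per_decade) + 1
  sv <- 10^seq(sigma_range[1], sigma_range[2], length.out = ns)
  rows <- list(); det <- list()
  for (tm in timings_ms) {
    delta <- tm[1] / 1e3; Delta <- tm[2] / 1e3
    for (b in b_values) {
      k <- k_from_b(b, delta, Delta)
      mag <- exp(-b * D) * abs(.sinc(k * sv))^3
      rows[[length(rows) + 1L]] <- data.frame(
        delta_ms = tm[1], Delta_ms = tm[2], b_s_per_mm2 = b,
        sigma_v = sv, magnitude = mag, noise_floor = noise_floor(snr))
      det[[length(det) + 1L]] <- data.frame(
        delta_ms = tm[1], Delta_ms = tm[2], b_s_per_mm2 = b,
        sigma_v_half = sigma_v_half(b, delta, Delta))
    }
  }
  out <- list(curves = do.call(rbind, rows),
              detectability = do.call(rbind, det))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$curves, file.path(out_dir, "sweep_sigma.csv"),
                     row.names = FALSE)
    utils::write.csv(out$detectability,
                     file.path(out_dir, "sweep_sigma_detectability.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "sweep_sigma",
                    list(b_values = b_values, timings_ms = timings_ms,
                         sigma_range = sigma_range,
                         points_per_decade = points_per_decade, D = D, snr = snr))
  }
  out
}

#' Pulse-timing sensitivity surface at fixed b
#'
#' Attenuation magnitude over the triangular (delta, Delta) domain
#' (Delta >= delta) at fixed b and sigma_v, isotropic laminar-flow model.
#' The degenerate origin delta = Delta = 0 is excluded: a positive b is
#' unattainable there.
#'
#' @param b diffusion weighting, s/mm^2.
#' @param sigma_v velocity dispersion, mm/s.
#' @param delta_max_ms,step_ms grid extent and step in ms.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param out_dir optional output directory.
#' @return data.frame with `delta_ms`, `Delta_ms`, `k_s_per_mm`,
#'   `magnitude`; attributes `max` and `min` hold the surface extremes.
#' @export
run_sweep_pulse <- function(b = 100, sigma_v = 0.4, delta_max_ms = 60,
                            step_ms = 1, D = D_CSF, out_dir = NULL) {
  g <- expand.grid(delta_ms = seq(0, delta_max_ms, by = step_ms),
                   Delta_ms = seq(0, delta_max_ms, by = step_ms))
  g <- g[g$Delta_ms >= g$delta_ms & g$Delta_ms > 0, ]
  delta <- g$delta_ms / 1e3; Delta <- g$Delta_ms / 1e3
  k <- mapply(k_from_b, b = b, delta = delta, Delta = Delta)
  mag <- exp(-b * D) * abs(.sinc(k * sigma_v))^3
  out <- data.frame(delta_ms = g$delta_ms, Delta_ms = g$Delta_ms,
                    k_s_per_mm = k, magnitude = mag)
  attr(out, "max") <- max(mag)
  attr(out, "min") <- min(mag)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep_pulse.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, "sweep_pulse",
                    list(b = b, sigma_v = sigma_v, delta_max_ms = delta_max_ms,
                         step_ms = step_ms, D = D))
  }
  out
}

#' IVIM Monte Carlo experiment across flow-scaling factors
#'
#' Runs [monte_carlo_ivim()] for each alpha and collects noise-free
#' curves, mean noisy curves, fits to both, and per-parameter summaries.
#'
#' @param alphas flow-scaling factors (default 0.1, 1, 10).
#' @param b_values acquisition b-values, s/mm^2.
#' @param D molecular diffusion coefficient, mm^2/s.
#' @param snr signal-to-noise ratio.
#' @param n_trials trials per alpha.
#' @param seed integer base seed; alpha index shifts the stream so the
#'   cases are independent.
#' @param out_dir optional output directory; writes per-trial CSVs and a
#'   JSON summary.
#' @return named list of `"ivim_mc"` objects, one per alpha.
#' @export
run_ivim_mc <- function(alphas = c(0.1, 1, 10),
                        b_values = c(0, 50, 100, 250, 500, 1000),
                        D = D_CSF, snr = 20, n_trials = 1000, seed = 1L,
                        out_dir = NULL) {
  out <- list()
  for (j in seq_along(alphas)) {
    out[[as.character(alphas[j])]] <-
      monte_carlo_ivim(alphas[j], D = D, b_values = b_values, snr = snr,
                       n_trials = n_trials,
                       seed = as.integer(seed) + (j - 1L) * n_trials)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]]$trials,
                       file.path(out_dir, paste0("ivim_trials_alpha", nm, ".csv")),
                       row.names = FALSE)
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      summ <- lapply(out, function(m) list(
        alpha = m$alpha, n_trials = m$n_trials, n_converged = m$n_converged,
        summary_all = as.data.frame(m$summary$all),
        fit_mean = as.list(coef(m$fit_mean)),
        fit_noise_free = as.list(coef(m$fit_noise_free))))
      jsonlite::write_json(summ, file.path(out_dir, "ivim_mc_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    .write_manifest(out_dir, "ivim_mc",
                    list(alphas = alphas, b_values = b_values, D = D,
                         snr = snr, n_trials = n_trials), seed = seed)
  }
  out
}
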