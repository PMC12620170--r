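---
title: "Modelling diffusion-weighted signal attenuation from intravoxel laminar flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diffusion-weighted signal attenuation from intravoxel laminar flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowdwi)
```

## The model

Diffusion-weighted imaging (DWI) attenuates the MR signal of moving spins.
For a voxel filled with a single fluid that both diffuses (coefficient $D$,
mm$^2$/s) and flows slowly enough that the velocity field is laminar and
steady over the gradient pulse, the normalized magnitude signal is

$$\left|\frac{S}{S_0}\right| = e^{-bD}\,\bigl|\hat F(k)\bigr|,$$

where $b$ (s/mm$^2$) is the diffusion weighting, $k = \gamma\int_0^T t\,G(t)\,dt$
(s/mm) is the first moment of the gradient waveform, and $\hat F$ is the
characteristic function (Fourier transform) of the probability density of
the intravoxel velocity component along the encoding axis, after removing
the voxel-mean velocity. The mean velocity only contributes a phase
$e^{-ikv_0}$, which the magnitude discards — DWI is blind to bulk motion and
sensitive only to intravoxel velocity *dispersion*.

For the Stejskal–Tanner pulse pair (duration $\delta$, separation $\Delta$)
the encoding attributes have closed forms, $b=\gamma^2G^2\delta^2\tau_d$
with $\tau_d=\Delta-\delta/3$ and $k=\gamma G\delta\Delta$, linked by
$k^2 = b\Delta^2/\tau_d$. This identity is how most of the package is
driven: from the routinely reported triple $(b,\delta,\Delta)$, via
`k_from_b()`, without ever knowing the gradient amplitude. `waveform_bk()`
covers non-rectangular encodings by integrating a sampled waveform; it
treats the samples as a piecewise-linear interpolant and integrates each
interval in closed form (the inner cumulative integral is piecewise
quadratic, its square quartic), so the only error is in how well the
samples represent the true waveform — jumps should be represented by two
samples a negligible time apart.

The apparent diffusion coefficient decomposes as

$$\mathrm{ADC} = -\tfrac{1}{b}\ln\left|\tfrac{S}{S_0}\right|
  = D - \tfrac{1}{b}\ln\bigl|\hat F(k)\bigr| \;\ge\; D,$$

and in the low-$b$ limit every velocity distribution with variance
$\sigma_v^2$ gives the same flow term,
$\lim_{b\to0}\mathrm{ADC} = D + \sigma_v^2\Delta^2/(2\tau_d)$
(`adc_low_b_limit()`). For a Gaussian velocity distribution that expression
is exact at every $b$.

## Velocity distributions of linear laminar flow

Within a box voxel $[-L_1,L_1]\times[-L_2,L_2]\times[-L_3,L_3]$, a linear
velocity field $v = v_0 + a_1x + a_2y + a_3z$ induces a velocity
distribution that is the convolution of up to three centered uniform
densities with half-widths $c_i=|a_iL_i|$ (mm/s): a box for one nonzero
component, a trapezoid or triangle for two, a piecewise quadratic for
three. The characteristic function is the product
$\hat F(k)=\prod_i \mathrm{sinc}(kc_i)$ with $\mathrm{sinc}(x)=\sin(x)/x$,
and the variance is $\sigma_v^2=\sum_i c_i^2/3$.

`flow_pdf()` evaluates the density exactly via the inclusion–exclusion
formula for box convolutions (an Irwin–Hall construction generalized to
unequal widths), rather than by FFT, so oracle tests can compare against
numerical convolution at tight tolerance. `flow_cf()` guards the
$\mathrm{sinc}$ singularity with a series expansion below $|x|<10^{-4}$.
Signs of the velocity gradients are irrelevant — only $|a_iL_i|$ enters —
and zero components are dropped before classification, so the
two-component case (gradient negligible along one axis) falls out as the
standard trapezoid without special handling.

The matched-variance Gaussian (`gaussian_surrogate()`) tracks the sinc
product closely while $\hat F > 0.5$; for three equal components the
largest discrepancy over the decay region $k\sigma_v\in[0,\pi]$ is 4% of
the normalized signal (computed by `scripts/acceptance.R` and asserted in
the test suite). This is the central limit theorem at work: each
additional comparable velocity-gradient component brings the convolution
closer to a Gaussian, which the tests check by extending the product
beyond three factors.

## The flow-scaling factor $\alpha$

To place flow dispersion on the same scale as molecular diffusion the
package uses $\sigma_v^2\Delta^2/(2\tau_d)=\alpha D$, so that
$\lim_{b\to0}\mathrm{ADC}=(1+\alpha)D$. Substituting the encoding identity
gives $k^2\sigma_v^2 = 2\alpha Db$: the $\alpha$-parameterized attenuation
curve depends on $(b,\alpha)$ only and is invariant to the specific
$(\delta,\Delta)$ used to realize it (`alpha_attenuation()`, checked to
$10^{-12}$ over random timings). That invariance is why $b$-sweep figures
need no stated pulse timings. The default experimental model is the
isotropic three-component case ($L_1=L_2=L_3$, $a_1=a_2=a_3$, so each
$c_i = \sigma_v$); the Gaussian variant collapses to the single
exponential $e^{-bD(1+\alpha)}$.

## Noise model

Magnitude images formed from two quadrature channels with independent
Gaussian noise of SD $\sigma$ are Rician. With $S_0$ normalized to 1,
$\sigma = 1/\mathrm{SNR}$, and the zero-signal mean — the noise floor — is
$\bar\epsilon=\sigma\sqrt{\pi/2}$, which at the representative SNR of 20
equals 0.0627. Signals attenuated below this level are indistinguishable
from background, which is what makes strongly flow-attenuated curves
plateau. Noise is applied independently per $b$-value and per trial
(including $b=0$; an option pins $S(0)=1$ instead); nothing in the model
couples noise across acquisitions. Each Monte Carlo trial uses a
deterministic substream (base seed + trial index), so any individual trial
is reproducible in isolation and the RNG state of the calling session is
never disturbed.

## IVIM fitting

The intravoxel incoherent motion model
$S/S_0 = f_\mathrm{VOF}e^{-bD_p}+(1-f_\mathrm{VOF})e^{-bD_d}$ is fitted by
unweighted nonlinear least squares under the constraint set
$f_\mathrm{VOF}\in[0,1]$, $D_p>D_d\ge 5\times10^{-5}$ mm$^2$/s.
`fit_ivim()` enforces the constraints structurally through a smooth
logistic reparameterization — $D_p$ is expressed as $D_d$ plus a positive
bounded increment, so the ordering can never be violated, rather than
through box bounds an optimizer could sit on. Minimization uses
Levenberg–Marquardt (`minpack.lm::nls.lm`) from a segmented log-linear
start (the two largest $b$ fix $D_d$ and the diffusion intercept, the
residual low-$b$ slope fixes $D_p$) plus two fixed fallback starts; the
lowest residual sum of squares wins. Upper bounds $D_d\le0.1$,
$D_p\le10$ mm$^2$/s are configuration, not science. Non-convergent fits
are flagged and retained, never dropped.

Two behaviours of this estimator are worth knowing. First, the model nests
a single exponential along a ridge ($f\to0$, or $D_p\to D_d$), so when the
data are effectively mono-exponential the fitted curve is stable but
individual parameters on the ridge are arbitrary; tests assert on the
curve, not the coordinates, in that regime. Second, when $D_p$ is barely
identified its sampling distribution under noise is heavily right-tailed,
so the package reports full distributional summaries (mean, SD, 2.5/50/97.5
percentiles) rather than a single moment; across flow strengths the
*median* $D_p$ and the fit to the mean signal are the orderly summaries,
while the mean $D_p$ is dominated by boundary outliers. The mean is the
natural summary for the bounded fraction $f_\mathrm{VOF}$.

`monte_carlo_ivim()` implements the full protocol: noise-free isotropic
attenuation at a given $\alpha$, Rician corruption at each of
$b = 0, 50, 100, 250, 500, 1000$ s/mm$^2$, fit per trial, plus the fit to
the trial-mean signal and the fit to the noise-free curve. Both
fit-to-mean and mean-of-fits are reported; they need not agree and the
package asserts nothing about their agreement.

## Defaults and problem sizes

* $D = 3.0\times10^{-3}$ mm$^2$/s — pure water at 37 °C, the standard CSF
  value; SNR 20 as a representative clinical magnitude SNR.
* Study $\alpha$ set $\{0, 0.1, 1, 10, 100, 1000\}$; IVIM cases
  $\{0.1, 1, 10\}$.
* Sweep grids: $b$ log-spaced $10^{-2}$–$10^{3.5}$ s/mm$^2$ at 60
  points/decade; $\sigma_v$ log-spaced $10^{-2}$–$10^{2}$ mm/s at 50
  points/decade; pulse timings on $[0,60]$ ms at 1 ms steps with
  $\Delta\ge\delta$ (the origin $\delta=\Delta=0$ is excluded because a
  positive $b$ is unattainable there).
* Monte Carlo size: the package default is $10^3$ trials per $\alpha$,
  the size used throughout the test suite; the full $10^4$-trial protocol
  is a single `n_trials` argument away and is what the bundled CLI runs
  without `--fast`.

## Detectability

"Detectable" flow dispersion has no canonical threshold. The package
exposes one operationalization — the $\sigma_v$ at which the flow factor
alone halves the signal, `sigma_v_half()` (root of
$\mathrm{sinc}^3(k\sigma_v)=0.5$) — as a configurable summary, not a
claim. Under practical settings ($b$ from 1 to 1000 s/mm$^2$, timings of
tens of ms) it lands in the 0.1–10 mm/s decade, e.g. 5.25 mm/s at
$b=1$ s/mm$^2$, $(\delta,\Delta)=(20,40)$ ms.

## What the simulations do and do not emulate

The generator produces exactly the idealized study conditions: steady
linear velocity fields, isotropic voxels, rectangular gradient pulses,
spatially uncorrelated single-coil Rician noise. Real CSF acquisitions add
pulsatile (cardiac-synchronized) flow, nonlinear velocity profiles,
magnetization advection during long repetition times, multi-coil
noise statistics, and $T_2$ decay (which cancels from $S/S_0$ and is
therefore not modelled). Passing tests validate the mathematics and the
estimator behaviour under the stated assumptions; they are not evidence
about scanner data.

## Numerical choices

* sinc convention $\sin(x)/x$, series-guarded near 0.
* ADC at characteristic-function zeros: the magnitude is a legitimate 0,
  but the ADC is singular; `adc()` raises a distinct
  `flowdwi_singular_adc` error rather than returning infinity.
* `fit_ivim` tolerances: `ftol = ptol = 1e-14`, 200 iterations — tight
  enough that noise-free recovery is limited by conditioning, not the
  stopping rule.
* Waveform encoding: exact closed-form integration of the
  piecewise-linear interpolant (no quadrature error term, no adaptive
  refinement; the user's sampling grid is the only approximation).
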