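test_that("pure-diffusion attenuation is exp(-b D)", {
  a <- attenuation(100, 0.02, 0.04, D = 3e-3)
  expect_equal(a$magnitude, exp(-0.3))
  expect_equal(a$signed_cf, 1)
  expect_equal(attenuation(0, 0.02, 0.04)$magnitude, 1)
})

test_that("isotropic flow at long timings attenuates toward 0.3", {
  # b = 100, delta = Delta = 60 ms, sigma_v = 0.4: k = 3 s/mm
  d <- velocity_distribution(half_widths = rep(0.4, 3))
  a <- attenuation(100, 0.06, 0.06, D = 3e-3, dist = d)
  sinc <- function(x) sin(x) / x
  expect_equal(a$magnitude, exp(-0.3) * sinc(1.2)^3, tolerance = 1e-12)
  expect_equal(a$magnitude, 0.3471, tolerance = 1e-4)
})

test_that("complex signal carries the mean-velocity phase", {
  d <- velocity_distribution(half_widths = rep(0.4, 3), v0 = 2)
  a <- attenuation(100, 0.02, 0.04, dist = d, complex_signal = TRUE)
  expect_equal(Mod(a$signal), a$magnitude)
  expect_equal(Arg(a$signal), Arg(exp(-1i * a$k * 2) * sign(a$signed_cf)))
})

test_that("ADC decomposes into diffusion plus a flow term", {
  # no flow: ADC = D at any b
  expect_equal(adc(c(10, 100, 1000), 0.02, 0.04, D = 3e-3), rep(3e-3, 3))
  # gaussian model: ADC = D + sigma_v^2 Delta^2 / (2 tau_d), b-independent
  g <- velocity_distribution(sigma_v = 0.3)
  expected <- 3e-3 + 0.3^2 * 0.04^2 / (2 * tau_d(0.02, 0.04))
  expect_equal(adc(c(1, 10, 100), 0.02, 0.04, D = 3e-3, dist = g),
               rep(expected, 3), tolerance = 1e-12)
  expect_equal(adc_low_b_limit(3e-3, 0.3, 0.02, 0.04), expected)
  # ADC never below D
  d3 <- velocity_distribution(half_widths = rep(0.5, 3))
  expect_true(all(adc(c(1, 10, 100, 500), 0.02, 0.04, dist = d3) >= 3e-3))
})

test_that("three-box ADC converges to the low-b limit at order b", {
  d <- velocity_distribution(half_widths = rep(0.4, 3))
  lim <- adc_low_b_limit(3e-3, sigma_v(d), 0.02, 0.04)
  expect_equal(adc(1e-6, 0.02, 0.04, D = 3e-3, dist = d), lim,
               tolerance = 1e-3)
  errs <- sapply(c(4, 2, 1), function(b)
    abs(adc(b, 0.02, 0.04, D = 3e-3, dist = d) - lim))
  ratios <- errs[-3] / errs[-1]
  expect_equal(ratios, c(2, 2), tolerance = 0.1)   # halving b halves the error
})

test_that("ADC is singular at characteristic-function zeros", {
  d <- velocity_distribution(half_widths = 0.4)
  # pick b so that k * c = pi exactly
  delta <- 0.02; Delta <- 0.04
  b <- (pi / 0.4)^2 * tau_d(delta, Delta) / Delta^2
  expect_error(adc(b, delta, Delta, dist = d), class = "flowdwi_singular_adc")
  expect_equal(attenuation(b, delta, Delta, dist = d)$magnitude, 0,
               tolerance = 1e-15)
  expect_error(adc(0, delta, Delta), "b > 0")
})

test_that("alpha and sigma_v interconvert through the flow-scaling relation", {
  expect_equal(sigma_v_for_alpha(0, 3e-3, 0.02, 0.04), 0)
  sv <- sigma_v_for_alpha(1, 3e-3, 0.02, 0.04)
  expect_equal(sv, sqrt(2 * tau_d(0.02, 0.04) * 3e-3) / 0.04)
  expect_equal(sv, 0.35355, tolerance = 1e-4)
  expect_equal(adc_low_b_limit(3e-3, sv, 0.02, 0.04), 2 * 3e-3)  # (1+alpha) D
  # round trip
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0, 100)
    s <- sigma_v_for_alpha(a, 3e-3, 0.02, 0.05)
    expect_equal(alpha_for_sigma_v(s, 3e-3, 0.02, 0.05), a, tolerance = 1e-12)
  }
})

test_that("alpha-parameterized attenuation is invariant to pulse timings", {
  set.seed(11)
  for (i in 1:100) {
    delta <- runif(1, 1e-3, 0.05)
    Delta <- delta + runif(1, 1e-3, 0.05)
    alpha <- 10^runif(1, -1, 3)
    b <- 10^runif(1, -2, 3)
    sv <- sigma_v_for_alpha(alpha, D_CSF, delta, Delta)
    d <- velocity_distribution(half_widths = rep(sv, 3))
    expect_equal(attenuation(b, delta, Delta, D = D_CSF, dist = d)$magnitude,
                 alpha_attenuation(b, alpha), tolerance = 1e-12)
  }
})

test_that("gaussian alpha model collapses to a single exponential", {
  b <- c(0.5, 5, 50, 500)
  for (alpha in c(0, 0.1, 1, 10, 100)) {
    mag <- alpha_attenuation(b, alpha, model = "gaussian")
    expect_equal(-log(mag) / b, rep(D_CSF * (1 + alpha), length(b)),
                 tolerance = 1e-12)
  }
  expect_equal(alpha_attenuation(b, 0), exp(-b * D_CSF))
})

test_that("strong flow pushes the signal under the noise floor by b = 1", {
  expect_equal(alpha_attenuation(1, 1000), 0.01763, tolerance = 1e-3)
  expect_lt(alpha_attenuation(1, 1000), noise_floor(20))
})

test_that("magnitudes stay in [0, 1] across the alpha-b grid", {
  b <- 10^seq(-2, 3.5, length.out = 120)
  for (alpha in c(0, 0.1, 1, 10, 100, 1000)) {
    m <- alpha_attenuation(b, alpha)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("signal_curve tabulates with NA ADC where undefined", {
  d <- velocity_distribution(half_widths = rep(0.3, 3))
  sc <- signal_curve(c(0, 10, 100), 0.02, 0.04, dist = d)
  expect_equal(names(sc), c("b_s_per_mm2", "magnitude", "signed_cf", "adc"))
  expect_true(is.na(sc$adc[1]))
  expect_equal(sc$magnitude[1], 1)
})
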