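test_that("flow fields classify by their nonzero velocity-gradient products", {
  expect_equal(from_voxel(voxel_flow_field(c(0, 0, 0), c(1, 1, 1)))$kind,
               "degenerate")
  d1 <- from_voxel(voxel_flow_field(c(0.5, 0, 0), c(2, 1, 1)))
  expect_equal(d1$kind, "uniform1d")
  expect_equal(d1$half_widths, 1)
  d3 <- from_voxel(voxel_flow_field(c(1, 1, 1), c(1, 1, 1), v0 = 2))
  expect_equal(d3$kind, "convolved_uniform")
  expect_equal(d3$v0, 2)
  expect_equal(sigma_v(d3), 1)   # three equal unit boxes: sigma_v = c
  # negative gradients: only magnitudes matter
  dneg <- from_voxel(voxel_flow_field(c(-1, 1, -1), c(1, 1, 1)))
  expect_equal(flow_cf(dneg, 1:5), flow_cf(d3, 1:5))
})

test_that("sigma_v follows the generalized variance formula", {
  expect_equal(sigma_v(voxel_flow_field(c(0, 0, 0), c(1, 1, 1))), 0)
  expect_equal(sigma_v(velocity_distribution(half_widths = c(3, 4, 0))),
               sqrt(25 / 3))
  expect_equal(sigma_v(velocity_distribution(sigma_v = 0.7)), 0.7)
})

test_that("box-convolution densities match their closed forms", {
  d1 <- velocity_distribution(half_widths = 1)
  expect_equal(flow_pdf(d1, 0), 0.5)
  expect_equal(flow_pdf(d1, c(-1.001, 1.001)), c(0, 0))
  d2 <- velocity_distribution(half_widths = c(1, 1))
  expect_equal(flow_pdf(d2, 0), 0.5)        # triangle peak 1/(2c)
  expect_equal(flow_pdf(d2, c(-2, 2)), c(0, 0))
  expect_equal(flow_pdf(d2, 1), 0.25)       # halfway down the triangle
})

test_that("three-box density matches a numerical convolution oracle", {
  cw <- c(1.3, 0.8, 0.5)
  d3 <- velocity_distribution(half_widths = cw)
  d2 <- velocity_distribution(half_widths = cw[1:2])
  c3 <- cw[3]
  # f3(v) = integral of f2(v - u) * box(u) du over [-c3, c3]
  oracle <- function(v) stats::integrate(function(u) flow_pdf(d2, v - u) / (2 * c3),
                                         -c3, c3, rel.tol = 1e-10)$value
  for (v in c(0, 0.3, 1.1, 2.0, 2.55)) {
    expect_equal(flow_pdf(d3, v), oracle(v), tolerance = 1e-6)
  }
})

test_that("densities integrate to one and have the stated variance", {
  set.seed(7)
  for (i in 1:200) {
    ncomp <- sample(1:3, 1)
    cw <- runif(ncomp, 0.1, 3)
    d <- velocity_distribution(half_widths = cw)
    vd <- vd_max(d)
    mass <- stats::integrate(function(v) flow_pdf(d, v), -vd, vd,
                             rel.tol = 1e-9, subdivisions = 500)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    vr <- stats::integrate(function(v) v^2 * flow_pdf(d, v), -vd, vd,
                           rel.tol = 1e-9, subdivisions = 500)$value
    expect_equal(vr, sum(cw^2) / 3, tolerance = 1e-6)
  }
})

test_that("characteristic functions are even, bounded, and 1 at zero", {
  kk <- seq(-30, 30, length.out = 601)
  dists <- list(velocity_distribution(),
                velocity_distribution(half_widths = 0.7),
                velocity_distribution(half_widths = c(0.7, 1.3)),
                velocity_distribution(half_widths = c(0.5, 1, 2)),
                velocity_distribution(sigma_v = 0.9))
  for (d in dists) {
    cf <- flow_cf(d, kk)
    expect_true(all(abs(cf) <= 1 + 1e-12))
    expect_equal(flow_cf(d, 0), 1)
    expect_equal(cf, rev(cf))
  }
  # first zero of the 1D sinc at k * c = pi
  d1 <- velocity_distribution(half_widths = 0.7)
  expect_equal(flow_cf(d1, pi / 0.7), 0, tolerance = 1e-15)
})

test_that("cf equals the cosine transform of the density", {
  d <- velocity_distribution(half_widths = c(0.6, 1.1, 0.9))
  vd <- vd_max(d)
  for (k in seq(0, 10 / sigma_v(d), length.out = 9)) {
    num <- stats::integrate(function(v) cos(k * v) * flow_pdf(d, v), -vd, vd,
                            rel.tol = 1e-10, subdivisions = 1000)$value
    expect_equal(flow_cf(d, k), num, tolerance = 1e-5)
  }
})

test_that("small-k expansion of the cf is 1 - k^2 sigma_v^2 / 2", {
  d <- velocity_distribution(half_widths = c(1, 0.5, 0.25))
  sv <- sigma_v(d)
  vd <- vd_max(d)
  m4 <- stats::integrate(function(v) v^4 * flow_pdf(d, v), -vd, vd,
                         rel.tol = 1e-10)$value
  for (k in c(0.001, 0.01, 0.05, 0.1) / sv) {
    err <- abs(flow_cf(d, k) - (1 - k^2 * sv^2 / 2))
    expect_lte(err, k^4 * m4 / 24 + 1e-15)
  }
})

test_that("gaussian surrogate keeps sigma_v and is within 4% for equal boxes", {
  d <- velocity_distribution(half_widths = c(1, 1, 1))
  g <- gaussian_surrogate(d)
  expect_equal(g$kind, "gaussian")
  expect_equal(sigma_v(g), sigma_v(d))
  kk <- seq(0, pi / sigma_v(d), length.out = 20001)
  gap <- max(abs(flow_cf(d, kk) - flow_cf(g, kk)))
  expect_lt(gap, 0.045)
  expect_gt(gap, 0.035)
  # degenerate surrogate stays flat
  g0 <- gaussian_surrogate(velocity_distribution())
  expect_equal(flow_cf(g0, c(0, 5, 50)), c(1, 1, 1))
})

test_that("more equal components brings the cf closer to the gaussian", {
  # generalize the box count beyond 3: sum of n uniforms with fixed total
  # variance, cf = sinc(k c_n)^n with c_n = sigma_v * sqrt(3/n)
  kk <- seq(0, pi, length.out = 2001)    # sigma_v = 1 units
  gauss <- exp(-kk^2 / 2)
  gaps <- sapply(1:6, function(n) {
    cn <- sqrt(3 / n)
    cf <- ifelse(kk == 0, 1, (sin(kk * cn) / (kk * cn))^n)
    max(abs(cf - gauss))
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("sampled velocities reproduce mean, variance, and the cf", {
  fld <- voxel_flow_field(c(0.8, -0.5, 0.3), c(1.5, 1, 0.5), v0 = 1.2)
  n <- 1e6
  v <- sample_velocities(fld, n, seed = 99)
  sv <- sigma_v(fld)
  expect_equal(mean(v), 1.2, tolerance = 4 * sv / sqrt(n) / 1.2)
  expect_equal(var(v), sv^2, tolerance = 0.01)
  d <- from_voxel(fld)
  for (k in c(0.5, 1, 2, 5) / sv) {
    ecf <- mean(cos(k * (v - mean(v))))
    expect_lt(abs(ecf - flow_cf(d, k)), 5 / sqrt(n))
  }
  # determinism
  expect_identical(v, sample_velocities(fld, n, seed = 99))
})

test_that("distributions serialize to JSON and back", {
  skip_if_not_installed("jsonlite")
  d <- velocity_distribution(half_widths = c(2, 1), v0 = 0.5)
  j <- jsonlite::fromJSON(distribution_json(d))
  expect_equal(j$kind, "convolved_uniform")
  expect_equal(j$half_widths, c(2, 1))
  expect_equal(j$v0, 0.5)
})
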