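test_that("expectation estimates carry the O(N^(-1/2)) standard error", {
  expect_error(estimate_expectation(1), "2 samples")
  est <- estimate_expectation(rep(3.2, 50))
  expect_equal(est$mean, 3.2); expect_equal(est$se, 0)

  x <- glymphuq:::with_seed(8L, stats::rnorm(1e4))
  est <- estimate_expectation(x)
  expect_lt(abs(est$mean), 4 / sqrt(1e4))

  # quadrupling N halves the standard error
  x4 <- glymphuq:::with_seed(9L, stats::rnorm(4e4))
  r <- estimate_expectation(x)$se / estimate_expectation(x4)$se
  expect_gt(r, 1.7); expect_lt(r, 2.4)
})

test_that("prediction intervals are central empirical quantiles", {
  # order-statistics oracle for the linear-interpolation quantile rule
  N <- 1000L
  s <- as.numeric(1:N)
  pi <- prediction_interval(s, coverage = 0.9973)
  oracle <- function(p) { h <- 1 + (N - 1) * p; fl <- floor(h); s[fl] + (h - fl) * (s[min(fl + 1, N)] - s[fl]) }
  expect_equal(pi[["lo"]], oracle(0.00135), tolerance = 1e-12)
  expect_equal(pi[["hi"]], oracle(0.99865), tolerance = 1e-12)

  # Gaussian samples: the 99.73% interval approximates +-3 sigma
  x <- glymphuq:::with_seed(12L, stats::rnorm(1e5))
  pig <- prediction_interval(x)
  expect_lt(abs(pig[["lo"]] + 3), 0.15)
  expect_lt(abs(pig[["hi"]] - 3), 0.15)
  expect_lt(pig[["lo"]], mean(x)); expect_gt(pig[["hi"]], mean(x))

  # degenerate distribution: zero-width interval
  pic <- prediction_interval(rep(7, 10))
  expect_equal(pic[["lo"]], pic[["hi"]])
})

test_that("the sample-size error criterion reproduces its arithmetic", {
  mk <- function(n, mean, sd) {
    x <- glymphuq:::with_seed(n, stats::rnorm(n))
    mean + sd * (x - mean(x)) / stats::sd(x)   # exact sample moments
  }
  # V = 1, Q = 10, N = 3200: 3 sqrt(1/3200) = 0.053 < 0.1
  expect_true(check_error_criterion(mk(3200L, 10, 1)))
  # V = 1, Q = 10, N = 100: 0.3 > 0.1
  expect_false(check_error_criterion(mk(100L, 10, 1)))
  # zero variance always meets the criterion
  expect_true(check_error_criterion(rep(10, 5)))
  expect_error(check_error_criterion(c(-1, 1)), "zero sample mean")
})

test_that("density and CDF estimates cap at the uncensored fraction", {
  x <- glymphuq:::with_seed(21L, stats::rnorm(100, mean = 14, sd = 2))
  cens <- rep(c(FALSE, TRUE), c(96L, 4L))
  est <- estimate_pdf_cdf(x, cens)
  expect_equal(est$censored_fraction, 0.04)
  expect_equal(max(est$cdf$p), 0.96)

  # the scaled density integrates to the uncensored fraction
  dx <- diff(est$density$x)
  mass <- sum((est$density$y[-1] + est$density$y[-length(est$density$y)]) / 2 * dx)
  expect_equal(mass, 0.96, tolerance = 0.02)

  # KDE mode within 3 bandwidths of the true mean for unimodal samples
  xx <- glymphuq:::with_seed(22L, stats::rnorm(2000, mean = 5, sd = 1))
  est2 <- estimate_pdf_cdf(xx)
  mode <- est2$density$x[which.max(est2$density$y)]
  expect_lt(abs(mode - 5), 3 * stats::bw.nrd(xx))

  expect_error(estimate_pdf_cdf(c(1, 2), c(TRUE, TRUE)), "censored")
})

test_that("a degenerate D1 model yields identical samples and zero-width intervals", {
  mesh <- tiny_brain()
  ds <- diffusion_spec("D1", scale = 1e-40)   # theta -> 0: variance vanishes
  spec <- model_spec("D1", N = 3L, base_seed = 2L, diffusion = ds,
                     t_end = 4 * 3600, output_times = seq(0, 4 * 3600, 3600),
                     checkpoints = c(2, 4) * 3600)
  run <- run_monte_carlo(spec, mesh, default_subregions(mesh))
  expect_equal(nrow(run$table), 3L)
  expect_equal(length(unique(run$table$Q_g_4h)), 1L)
  s <- run$summary
  expect_equal(s$pi_lo[s$qoi == "Q_g_4h"], s$pi_hi[s$qoi == "Q_g_4h"])
  expect_equal(s$se[s$qoi == "Q_g_4h"], 0)
})

test_that("Monte Carlo runs are bit-reproducible and record the model-variant coefficient structure", {
  mesh <- tiny_brain()
  spec <- model_spec("D1", N = 3L, base_seed = 11L, t_end = 3 * 3600,
                     output_times = seq(0, 3 * 3600, 1800),
                     checkpoints = 3 * 3600)
  r1 <- run_monte_carlo(spec, mesh, default_subregions(mesh))
  r2 <- run_monte_carlo(spec, mesh, default_subregions(mesh))
  expect_identical(r1$table, r2$table)

  # D1: stochastic diffusivity, no velocity, no drainage
  co <- glymphuq:::.sample_coefficients(spec, mesh, 1L)
  expect_null(co$velocity)
  expect_equal(co$drainage_r, 0)
  expect_false(co$diffusivity == 1.2e-10)  # a gamma draw, not the constant
  expect_identical(co$seed, derive_seed(11L, 1L))

  # V3: constant diffusivity 1.2e-10, inward velocity, r = 1e-5
  spec3 <- model_spec("V3", N = 1L, base_seed = 11L)
  spec3$velocity <- calibrate_inflow_scale(spec3$velocity, mesh)
  co3 <- glymphuq:::.sample_coefficients(spec3, mesh, 1L)
  expect_equal(co3$diffusivity, 1.2e-10)
  expect_equal(co3$drainage_r, 1e-5)
  expect_false(is.null(co3$velocity))

  # V1 runs on a small resolved box record calibration metadata and r = 0
  lam <- 1020e-6
  boxmesh <- velocity_box_mesh()
  spec1 <- model_spec("V1", N = 2L, base_seed = 4L, dt = 900, t_end = 3600,
                      output_times = c(0, 1800, 3600), checkpoints = 3600)
  run1 <- run_monte_carlo(spec1, boxmesh,
                          subregions = list(
                            S_g = compartment_mask(boxmesh, "gray"),
                            S_w = compartment_mask(boxmesh, "white")),
                          matern = velocity_box_matern())
  expect_equal(run1$metadata$diffusivity, 1.2e-10)
  expect_equal(run1$metadata$drainage_r, 0)
  expect_false(is.null(run1$metadata$calibration))
  expect_equal(nrow(run1$table), 2L)
})

test_that("per-sample seeds are deterministic hashes of (base_seed, omega)", {
  s1 <- derive_seed(1L, 1:100)
  s2 <- derive_seed(1L, 1:100)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 100L)
  expect_true(all(s1 >= 1 & s1 < 2^31 - 1))
  expect_false(any(derive_seed(2L, 1:100) == s1))
})
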