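test_that("directional velocity field evaluates the closed form exactly", {
  # on the brain-stem axis the transverse components vanish
  pts <- rbind(c(0, 0, -0.1), c(0, 0, 0), c(0, 0, 0.1))
  v <- evaluate_directional_velocity(pts)
  expect_equal(v[, 1], rep(0, 3))
  expect_equal(v[, 2], rep(0, 3))

  # x = (0.1, 0, 0): first two components zero, third +8e-8 m/s
  v1 <- evaluate_directional_velocity(c(0.1, 0, 0))
  expect_equal(as.numeric(v1), c(0, 0, 8e-8), tolerance = 1e-15)

  # the axial zero of the vertical component sits at x3 = 0.06 / 0.9
  v2 <- evaluate_directional_velocity(c(0, 0, 0.06 / 0.9))
  expect_lt(abs(v2[3]), 1e-12)

  # linear in v_f
  expect_equal(evaluate_directional_velocity(c(0.02, 0.05, 0.01), v_f = 4e-6),
               2 * evaluate_directional_velocity(c(0.02, 0.05, 0.01), v_f = 2e-6))
})

test_that("the discrete curl is divergence-free on the sampling grid", {
  ms <- velocity_box_matern()
  psi <- sample_matern_scalar(ms, n = 3L, seed = 17L)
  curl <- glymphuq:::.grid_curl(psi, ms$spacing)
  h <- ms$spacing
  dv <- glymphuq:::.grid_diff(curl[[1]], 1L, h) +
        glymphuq:::.grid_diff(curl[[2]], 2L, h) +
        glymphuq:::.grid_diff(curl[[3]], 3L, h)
  n <- dim(dv)
  interior <- dv[3:(n[1] - 2), 3:(n[2] - 2), 3:(n[3] - 2)]
  scale <- max(abs(curl[[1]])) / h
  # centered difference operators commute: interior divergence is exactly zero
  expect_lt(max(abs(interior)) / scale, 1e-12)
})

test_that("eta calibration hits the target RMS and scales linearly with v_avg", {
  ms <- velocity_box_matern()
  vs <- calibrated_v1()
  expect_gt(vs$eta, 0)

  # the closed-form attenuation moment used in the calibration
  expect_equal(glymphuq:::.exp_attenuation_moment(0.2, 2), 5 / (5 + 2 * log(10)))
  expect_equal(5 / (5 + 2 * log(10)), 0.5206, tolerance = 1e-4)

  # RMS magnitude of fresh V1 samples: 0.17 um/s within 3%
  mesh <- velocity_box_mesh()
  rms <- v1_validation_rms()
  expect_lt(abs(rms - 1.7e-7) / 1.7e-7, 0.03)

  # doubling v_avg doubles the sampled field (eta is a pure shape constant)
  vs2 <- vs; vs2$v_avg <- 2 * vs$v_avg
  va <- sample_velocity_V1(vs, ms, mesh, n = 1L, seed = 5L)[[1]]
  vb <- sample_velocity_V1(vs2, ms, mesh, n = 1L, seed = 5L)[[1]]
  expect_equal(unclass(vb), 2 * unclass(va), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("V1 velocity components have zero mean and exponential attenuation", {
  ms <- velocity_box_matern()
  vs <- calibrated_v1()
  mesh <- velocity_box_mesh()
  nsamp <- 200L
  v <- sample_velocity_V1(vs, ms, mesh, n = nsamp, seed = 321L)
  nodes <- c(1L, 50L, 150L, nrow(mesh$vertices))
  for (j in nodes) for (comp in 1:3) {
    x <- vapply(v, function(m) m[j, comp], numeric(1))
    se <- stats::sd(x) / sqrt(nsamp)
    expect_lt(abs(mean(x)), 4 * se)
  }
  # per-sample attenuation draws follow Exponential(mean 0.2):
  # E[10^(-E)] = 5 / (5 + ln 10)
  E <- vapply(v, function(m) attr(m, "E"), numeric(1))
  a <- 10^(-E)
  se <- stats::sd(a) / sqrt(nsamp)
  expect_lt(abs(mean(a) - 5 / (5 + log(10))), 4 * se)
})

test_that("V2 is V1 plus the directional field, exactly", {
  ms <- velocity_box_matern()
  vs1 <- calibrated_v1()
  vs2 <- vs1; vs2$model <- "V2"
  mesh <- velocity_box_mesh()
  v1 <- sample_velocity_V1(vs1, ms, mesh, n = 1L, seed = 99L)[[1]]
  v2 <- sample_velocity_V2(vs2, ms, mesh, n = 1L, seed = 99L)[[1]]
  vdir <- evaluate_directional_velocity(mesh$vertices, vs2$v_f)
  expect_equal(unclass(v2 - v1), unclass(vdir), tolerance = 1e-12,
               ignore_attr = TRUE)

  # with v_f = 0 the same seed reproduces V1 exactly
  vs0 <- vs2; vs0$v_f <- 0
  v20 <- sample_velocity_V2(vs0, ms, mesh, n = 1L, seed = 99L)[[1]]
  expect_equal(unclass(v20), unclass(v1), ignore_attr = TRUE)
})

test_that("V3 inflow vanishes at the center, matches the ansatz and calibrates", {
  mesh <- build_box_mesh(c(-0.048, -0.048, -0.048), c(0.048, 0.048, 0.048),
                         n = 12L)
  vs <- velocity_spec("V3", R = 0.04)
  vs <- calibrate_inflow_scale(vs, mesh)
  expect_gt(vs$inflow_scale, 0)
  s <- sample_velocity_V3(vs, mesh, n = 1L, seed = 4L)[[1]]
  expect_equal(s$drainage_r, 1e-5)

  # the vertex at the center carries zero velocity
  i0 <- which(rowSums(mesh$vertices^2) < 1e-20)
  expect_length(i0, 1L)
  expect_equal(as.numeric(s$velocity[i0, ]), c(0, 0, 0))

  # at ||x - x_c|| = R the exponential factor is 1: magnitude = vbar * R
  iR <- which(abs(mesh$vertices[, 1] - 0.04) < 1e-12 &
              abs(mesh$vertices[, 2]) < 1e-12 & abs(mesh$vertices[, 3]) < 1e-12)
  expect_equal(sqrt(sum(s$velocity[iR, ]^2)), s$vbar * 0.04, tolerance = 1e-12)

  # calibration identity: E[vbar^2] * volume-mean squared profile = v_avg^2
  cent <- cell_centroids(mesh); vol <- cell_volumes(mesh)
  d <- sqrt(rowSums(cent^2))
  mean_prof2 <- sum((glymphuq:::.v3_profile(d, vs$R) * d)^2 * vol) / sum(vol)
  k <- vs$inflow_shape
  expect_equal(sqrt(k * (k + 1) * vs$inflow_scale^2 * mean_prof2), vs$v_avg,
               tolerance = 1e-12)

  # Monte Carlo consistency of the RMS magnitude over realizations and space
  nsamp <- 400L
  ss <- sample_velocity_V3(vs, mesh, n = nsamp, seed = 11L)
  msq <- vapply(ss, function(x) {
    vc <- (x$velocity[mesh$cells[, 1], ] + x$velocity[mesh$cells[, 2], ] +
           x$velocity[mesh$cells[, 3], ] + x$velocity[mesh$cells[, 4], ]) / 4
    sum(rowSums(vc^2) * vol) / sum(vol)
  }, numeric(1))
  se <- stats::sd(msq) / sqrt(nsamp)
  expect_lt(abs(mean(msq) - vs$v_avg^2), 4 * se)
})
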