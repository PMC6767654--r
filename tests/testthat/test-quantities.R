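test_that("regional amounts and means satisfy the quadrature identities", {
  cube <- build_box_mesh(n = 3L)
  all_mask <- region_mask(cube, seq_len(nrow(cube$cells)))

  # uniform concentration: amount = c0 * V, mean = c0
  c0 <- rep(2.5, nrow(cube$vertices))
  expect_equal(amount_in_region(c0, cube, all_mask), 2.5, tolerance = 1e-12)
  expect_equal(mean_concentration_in_region(c0, cube, all_mask), 2.5,
               tolerance = 1e-12)
  expect_equal(amount_in_region(numeric(nrow(cube$vertices)), cube, all_mask), 0)

  # linear field alpha * x3 on the unit cube integrates to alpha / 2 (exact
  # for P1 quadrature of a linear integrand)
  alpha <- 3
  cl <- alpha * cube$vertices[, 3]
  expect_equal(amount_in_region(cl, cube, all_mask), alpha / 2,
               tolerance = 1e-12)

  # amount = mean * volume by definition
  sub <- region_mask(cube, 1:20)
  expect_equal(amount_in_region(cl, cube, sub),
               mean_concentration_in_region(cl, cube, sub) *
                 region_volume(cube, sub), tolerance = 1e-14)
})

test_that("cell quadrature matches an independent Monte Carlo oracle", {
  mesh <- tiny_brain()
  k <- c(10L, 400L)
  mask <- region_mask(mesh, k)
  cvals <- glymphuq:::with_seed(3L, stats::runif(nrow(mesh$vertices)))
  q <- amount_in_region(cvals, mesh, mask)
  # MC integration of the P1 interpolant over each tet
  mc <- 0
  for (kk in k) {
    p <- mesh$vertices[mesh$cells[kk, ], ]
    pts_bary <- glymphuq:::with_seed(kk, {
      w <- matrix(stats::rexp(4L * 20000L), ncol = 4L)
      w / rowSums(w)
    })
    vals <- pts_bary %*% cvals[mesh$cells[kk, ]]
    mc <- mc + mean(vals) * cell_volumes(mesh)[kk]
  }
  expect_equal(q, mc, tolerance = 2e-2)
})

test_that("gray and white amounts reproduce the budget quadrature exactly", {
  mesh <- tiny_brain()
  pr <- transport_problem(mesh, coefficient_sample(1.2e-10), t_end = 4 * 3600,
                          output_times = c(0, 4 * 3600))
  ser <- solve_transport(pr)
  cn <- ser$nodal_c[, 2]
  Qg <- amount_in_region(cn, mesh, compartment_mask(mesh, "gray"))
  Qw <- amount_in_region(cn, mesh, compartment_mask(mesh, "white"))
  expect_equal(Qg + Qw, ser$parenchymal_trace[length(ser$parenchymal_trace)],
               tolerance = 1e-13)
})

test_that("activation times interpolate crossings and censor correctly", {
  # synthetic fixture: a single-tet-region series with a linear ramp in the
  # monitored amount that crosses 10% of n0 exactly at t = 14 h
  cube <- build_box_mesh(n = 2L)
  mask <- region_mask(cube, seq_len(nrow(cube$cells)))  # volume 1
  times <- seq(0, 24, by = 1) * 3600
  n0 <- 5e-4
  # nodal concentration uniform = amount; ramp 0 -> amount(24h)
  ramp_amount <- n0 * 0.1 * (times / 3600) / 14    # exceeds 0.1 n0 after 14 h
  nodal <- matrix(rep(ramp_amount, each = nrow(cube$vertices)),
                  nrow = nrow(cube$vertices))
  ser <- structure(list(times = times, nodal_c = nodal,
                        boundary = boundary_params()),
                   class = "concentration_series")
  at <- activation_time(ser, cube, mask, "fraction_of_n0", 0.1)
  expect_false(at$censored)
  expect_equal(at$time / 3600, 14, tolerance = 1e-9)
  # the interpolated crossing lies between the bracketing stored times
  expect_gte(at$time, 14 * 3600 - 3600); expect_lte(at$time, 15 * 3600)

  # identically sub-threshold trajectory is censored
  low <- activation_time(ser, cube, mask, "fraction_of_n0", 10)
  expect_true(low$censored)
  expect_true(is.na(low$time))

  # degenerate threshold 0 with an everywhere-positive trajectory: the first
  # stored time activates
  serp <- ser; serp$nodal_c <- ser$nodal_c + 1e-9
  z <- activation_time(serp, cube, mask, "fraction_of_n0", 0)
  expect_equal(z$time, times[1])

  # monotonicity: pointwise larger trajectories never activate later
  ser2 <- ser; ser2$nodal_c <- 2 * ser$nodal_c
  at2 <- activation_time(ser2, cube, mask, "fraction_of_n0", 0.1)
  expect_lte(at2$time, at$time)

  # mean-concentration mode: the ramp reaches 3e-5 mol/m^3 at 8.4 h
  atY <- activation_time(ser, cube, mask, "mean_conc", 3e-5)
  expect_false(atY$censored)
  expect_equal(atY$time, 14 * 3600 * (3e-5 / (0.1 * n0)), tolerance = 1e-6)
  # a threshold above the final value is censored
  expect_true(activation_time(ser, cube, mask, "mean_conc", 1e-3)$censored)
})

test_that("plane boundary traces are ordered and bounded by c_CSF", {
  mesh <- tiny_brain()
  pr <- transport_problem(mesh, coefficient_sample(1.2e-10), t_end = 6 * 3600,
                          output_times = c(0, 6 * 3600))
  ser <- solve_transport(pr)
  tr <- plane_boundary_trace(ser)
  expect_named(tr, c("t_hours", "c_csf", "g_fm", "g_sf", "g_ps"))
  # monotone ordering at early times: lower planes see more tracer
  early <- tr$t_hours <= 2
  expect_true(all(tr$g_fm[early] >= tr$g_sf[early]))
  expect_true(all(tr$g_sf[early] >= tr$g_ps[early]))
  # all traces below the SAS mean concentration
  expect_true(all(tr$g_fm <= tr$c_csf & tr$g_sf <= tr$c_csf &
                  tr$g_ps <= tr$c_csf))
  # t = 0 value at z0 equals c_CSF(0)/2 (cf. the boundary model)
  g0 <- boundary_value_g(0, c(0, 0, -0.2), tr$c_csf[1])
  expect_equal(g0, 1.786, tolerance = 1e-3)
})

test_that("the QoI bundle evaluates at all checkpoints", {
  mesh <- tiny_brain()
  pr <- transport_problem(mesh, coefficient_sample(1.2e-10), t_end = 8 * 3600,
                          output_times = seq(0, 8 * 3600, 3600))
  ser <- solve_transport(pr)
  q <- compute_qoi(ser, mesh, default_subregions(mesh),
                   checkpoints = c(3, 5, 8) * 3600)
  expect_named(q$Q_g, c("3h", "5h", "8h"))
  expect_true(all(q$Q_g >= 0 & q$Q_g <= 5e-4))
  expect_true(all(diff(q$Q_g) > 0))   # gray amount grows over the first hours
  expect_true(q$F_w$censored)         # white matter is not reached this early
  tab <- qoi_table(list(q))
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("Q_g_3h", "q_w_8h", "F_w_censored") %in% names(tab)))
})
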