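test_that("assembled operators have the structural properties of the scheme", {
  mesh <- tiny_brain()
  co <- coefficient_sample(1.2e-10)
  ops <- assemble_operators(transport_problem(mesh, co))

  # lumped mass: positive diagonal summing to the mesh volume
  expect_true(all(ops$mass_lumped > 0))
  expect_equal(sum(ops$mass_lumped), sum(cell_volumes(mesh)), tolerance = 1e-12)

  # pure diffusion reduces to the symmetric heat-equation discretization
  asym <- max(abs(ops$stiffness - Matrix::t(ops$stiffness)))
  expect_lt(asym, 1e-20)
  expect_equal(length(ops$convection@x), 0L)

  # a constant (exactly divergence-free) velocity gives vanishing convection
  # row sums at interior nodes; boundary rows report the surface flux
  vel <- matrix(rep(c(1e-7, -2e-7, 5e-8), each = nrow(mesh$vertices)), ncol = 3)
  opsv <- assemble_operators(transport_problem(mesh,
    coefficient_sample(1.2e-10, velocity = vel)))
  rs <- Matrix::rowSums(opsv$convection)
  bnodes <- unique(as.vector(mesh$facets))
  interior <- setdiff(seq_len(nrow(mesh$vertices)), bnodes)
  expect_lt(max(abs(rs[interior])), 1e-18)
  expect_gt(max(abs(rs[bnodes])), 1e-18)

  # degenerate cells are rejected at assembly
  bad <- mesh
  bad$vertices[bad$cells[1, 2], ] <- bad$vertices[bad$cells[1, 1], ]
  expect_error(assemble_operators(transport_problem(bad, co)),
               "degenerate")
})

test_that("a single step reproduces zero dynamics and first-order decay", {
  mesh <- build_box_mesh(c(0, 0, 0), c(0.03, 0.03, 0.03), n = 4L)
  r <- 1e-4
  co <- coefficient_sample(1e-10, drainage_r = r)
  pr <- transport_problem(mesh, co, dt = 300, t_end = 900,
                          output_times = c(0, 900))
  ops <- assemble_operators(pr)
  dir <- ops$dirichlet_nodes

  # zero boundary data and zero state stay exactly zero
  c0 <- numeric(ops$n)
  expect_equal(transport_step(ops, c0, rep(0, length(dir)), 300),
               numeric(ops$n))

  # uniform state held at the boundary: interior decays like exp(-r dt)
  dt <- 300
  cstart <- rep(2, ops$n)
  cnext <- transport_step(ops, cstart, rep(2, length(dir)), dt)
  interior <- setdiff(seq_len(ops$n), dir)
  ode <- 2 * (1 - r * dt / 2) / (1 + r * dt / 2)  # midpoint rule on dc/dt=-rc
  # nodes away from the held boundary follow the nodal ODE; the scheme error
  # against the exact exponential is first order in dt
  deep <- interior[rowSums((mesh$vertices[interior, , drop = FALSE] - 0.015)^2) < 1e-5]
  expect_equal(mean(cnext[deep]), ode, tolerance = 1e-6)
  expect_lt(abs(mean(cnext[deep]) - 2 * exp(-r * dt)), 2 * (r * dt)^2)
})

test_that("transient diffusion matches the 1D series solution at second order in space", {
  # box with one Dirichlet face (x = L) and insulated remaining faces; the
  # exact solution is the classical cosine series
  L <- 0.05; D <- 2e-6; cb <- 1; t_end <- 600; dt <- 5
  series_sol <- function(x, t) {
    k <- 0:40
    lam <- (2 * k + 1) * pi / (2 * L)
    a <- 2 * cb * (-1)^k / (lam * L)
    cb - as.vector(cos(outer(x, lam)) %*% (a * exp(-D * lam^2 * t)))
  }
  mesh <- build_box_mesh(c(0, 0, 0), c(L, L, L), n = 8L, sas_faces = "xmax")
  pr <- transport_problem(mesh, coefficient_sample(D), boundary = NULL,
                          dt = dt, t_end = t_end, output_times = c(0, t_end),
                          dirichlet = function(t, x) rep(cb, nrow(x)))
  ser <- solve_transport(pr)
  exact <- series_sol(mesh$vertices[, 1], t_end)
  M <- assemble_operators(pr)$mass_lumped
  err <- sqrt(sum(M * (ser$nodal_c[, 2] - exact)^2) / sum(M * exact^2))
  expect_lt(err, 0.05)   # within discretization error of the analytic series
})

test_that("a compatible diffusion mode converges at second order in space", {
  # exact separable solution cos(lambda0 x) exp(-D lambda0^2 t): zero
  # Dirichlet data at x = L, natural (zero-flux) on all remaining faces
  L <- 0.05; D <- 2e-6; t_end <- 200; dt <- 1
  lam0 <- pi / (2 * L)
  err <- vapply(c(4L, 8L), function(n) {
    mesh <- build_box_mesh(c(0, 0, 0), c(L, L, L), n = n, sas_faces = "xmax")
    pr <- transport_problem(mesh, coefficient_sample(D), boundary = NULL,
                            dt = dt, t_end = t_end, output_times = c(0, t_end),
                            dirichlet = function(t, x) rep(0, nrow(x)),
                            initial = function(x) cos(lam0 * x[, 1]))
    ser <- solve_transport(pr)
    M <- assemble_operators(pr)$mass_lumped
    exact <- cos(lam0 * mesh$vertices[, 1]) * exp(-D * lam0^2 * t_end)
    sqrt(sum(M * (ser$nodal_c[, 2] - exact)^2))
  }, numeric(1))
  rate <- log2(err[1] / err[2])
  expect_gt(rate, 1.5)   # second-order spatial convergence
  expect_lt(rate, 3.0)
})

test_that("the coupled trajectory converges under time-step refinement", {
  mesh <- tiny_brain()
  co <- coefficient_sample(1.2e-10)
  sol_at <- function(dt) {
    pr <- transport_problem(mesh, co, dt = dt, t_end = 6 * 3600,
                            output_times = c(0, 6 * 3600))
    solve_transport(pr)
  }
  ref <- sol_at(225)
  e <- vapply(c(1800, 900), function(dt)
    max(abs(sol_at(dt)$nodal_c[, 2] - ref$nodal_c[, 2])), numeric(1))
  ratio <- e[1] / e[2]
  expect_gt(ratio, 1.5)  # at least first-order accuracy in time overall
  expect_lt(ratio, 5.0)

  # the explicit-coupling lag indicator decays at first order in dt
  lag <- vapply(c(1800, 900, 450), function(dt) {
    s <- sol_at(dt)
    max(s$coupling_lag[s$step_times >= 3600], na.rm = TRUE)
  }, numeric(1))
  expect_gt(lag[1] / lag[2], 1.5); expect_lt(lag[1] / lag[2], 3)
  expect_gt(lag[2] / lag[3], 1.5); expect_lt(lag[2] / lag[3], 3)
})

test_that("with pure diffusion the solution respects the boundary-data bounds", {
  mesh <- build_box_mesh(c(0, 0, 0), c(0.03, 0.03, 0.03), n = 4L)
  co <- coefficient_sample(5e-9)
  pr <- transport_problem(mesh, co, boundary = NULL, dt = 30, t_end = 3000,
                          output_times = seq(0, 3000, 300),
                          dirichlet = function(t, x) rep(1.5, nrow(x)))
  ser <- solve_transport(pr)
  eps <- 1e-3 * 1.5
  expect_gt(min(ser$nodal_c), -eps)
  expect_lt(max(ser$nodal_c), 1.5 + eps)
})

test_that("identical problems give bitwise identical trajectories", {
  mesh <- tiny_brain()
  co <- coefficient_sample(1.2e-10)
  pr <- transport_problem(mesh, co, t_end = 4 * 3600,
                          output_times = c(0, 4 * 3600))
  s1 <- solve_transport(pr)
  s2 <- solve_transport(pr)
  expect_identical(s1$nodal_c, s2$nodal_c)
  expect_identical(s1$c_csf_trace, s2$c_csf_trace)
})

test_that("an inflow-with-drainage run conserves the injected amount", {
  mesh <- medium_brain()
  vs <- calibrate_inflow_scale(velocity_spec("V3"), mesh)
  v <- sample_velocity_V3(vs, mesh, n = 1L, seed = derive_seed(5L, 1L))[[1]]
  co <- coefficient_sample(1.2e-10, v$velocity, v$drainage_r)
  ser <- solve_transport(transport_problem(mesh, co))
  # parenchymal + SAS + drained + ventricular efflux totals 0.5 mmol within 2%
  expect_lt(max(ser$budget_residuals), 0.02)
  # drainage is substantial: tens of percent of the injection over 24 h
  expect_gt(ser$drained_trace[length(ser$drained_trace)], 0.1 * 5e-4)
})

test_that("the Peclet estimate reproduces the printed convection-dominance bound", {
  pe <- estimate_peclet(0.084, 1.7e-7, 1.2e-10)
  expect_equal(pe, 9 * 0.084 * 1.7e-7 / 1.2e-10)
  expect_equal(pe, 1071, tolerance = 1e-3)
  expect_gte(pe, 1e3)
  expect_equal(estimate_peclet(0.084, 0, 1.2e-10), 0)
  expect_equal(estimate_peclet(2 * 0.084, 1.7e-7, 1.2e-10), 2 * pe)
  expect_error(estimate_peclet(0.084, 1.7e-7, 0), "positive")
})
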