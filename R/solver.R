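# Deterministic transport solver: P1 (continuous piecewise linear) finite
# elements with mass lumping on a labeled tetrahedral mesh, implicit midpoint
# time stepping, Dirichlet data on the SAS boundary and zero diffusive flux
# on the ventricular boundary.  Convection is discretized in the divergence
# form of the governing equation; the convective boundary term arising from
# integration by parts is retained on the ventricle facets (configurable) and
# tracked as an explicit budget component.

#' Bundle one realization of the stochastic coefficients
#'
#' @param diffusivity scalar (m^2/s) or per-vertex numeric vector.
#' @param velocity `NULL` (no convection) or an n_vertices x 3 matrix (m/s).
#' @param drainage_r homogeneous drainage rate in 1/s.
#' @param seed,index bookkeeping: the per-sample seed and realization index.
#' @return an object of class `coefficient_sample`.
#' @export
coefficient_sample <- function(diffusivity, velocity = NULL, drainage_r = 0,
                               seed = NA_integer_, index = NA_integer_) {
  stopifnot(all(diffusivity > 0), drainage_r >= 0)
  if (!is.null(velocity)) {
    velocity <- as.matrix(velocity)
    stopifnot(ncol(velocity) == 3L, all(is.finite(velocity)))
  }
  structure(list(diffusivity = diffusivity, velocity = velocity,
                 drainage_r = drainage_r, seed = seed, index = index),
            class = "coefficient_sample")
}

#' Define a transport problem
#'
#' @param mesh a [labeled_mesh()].
#' @param coeffs a [coefficient_sample()].
#' @param boundary a [boundary_params()] (coupled SAS model), or `NULL` when
#'   `dirichlet` supplies fixed boundary data directly.
#' @param dt time step in s (default 900 s = 15 min).
#' @param t_end final time in s (default 24 h).
#' @param output_times times at which the full nodal field is stored; must be
#'   multiples of `dt` within `[0, t_end]`. Default hourly.
#' @param dirichlet optional `function(t, x)` returning the SAS boundary
#'   concentration at coordinates `x` (n x 3); overrides the coupled SAS
#'   model (used for verification problems).
#' @param initial initial nodal concentration: a scalar, a vector (one value
#'   per vertex) or a `function(x)`; default 0 (tracer-free parenchyma).
#' @param retain_ventricle_convection keep the convective `v.n c` boundary
#'   term on the ventricle facets (the natural weak-form reading of the
#'   zero-diffusive-flux condition there).
#' @param budget_tol relative budget breach that aborts the run.
#' @return an object of class `transport_problem`.
#' @export
transport_problem <- function(mesh, coeffs, boundary = boundary_params(),
                              dt = 900, t_end = 86400,
                              output_times = seq(0, t_end, by = 3600),
                              dirichlet = NULL, initial = 0,
                              retain_ventricle_convection = TRUE,
                              budget_tol = 0.05) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(coeffs, "coefficient_sample"),
            dt > 0, t_end > 0)
  if (is.null(boundary) && is.null(dirichlet))
    stop("either a boundary model or explicit dirichlet data is required")
  output_times <- sort(unique(output_times))
  if (any(output_times < 0 | output_times > t_end + 1e-9))
    stop("output_times must lie in [0, t_end]")
  k <- output_times / dt
  if (any(abs(k - round(k)) > 1e-8))
    stop("dt must divide the spacing of output_times")
  nsteps <- round(t_end / dt)
  if (abs(nsteps * dt - t_end) > 1e-6 * t_end)
    stop("dt must divide t_end")
  if (!is.null(coeffs$velocity) && nrow(coeffs$velocity) != nrow(mesh$vertices))
    stop("velocity must be given per mesh vertex")
  if (length(coeffs$diffusivity) != 1L &&
      length(coeffs$diffusivity) != nrow(mesh$vertices))
    stop("diffusivity must be a scalar or one value per mesh vertex")
  structure(list(mesh = mesh, coeffs = coeffs, boundary = boundary,
                 dt = dt, t_end = t_end, output_times = output_times,
                 dirichlet = dirichlet, initial = initial,
                 retain_ventricle_convection = retain_ventricle_convection,
                 budget_tol = budget_tol),
            class = "transport_problem")
}

#' Assemble the discrete transport operators
#'
#' Builds the lumped mass vector, the diffusion (stiffness) matrix, the
#' divergence-form convection matrix, the reaction diagonal, the ventricle
#' facet flux matrix and the Dirichlet node set for a transport problem.
#'
#' @param problem a [transport_problem()].
#' @return a list of operators (class `transport_operators`): `mass_lumped`
#'   (vector), `stiffness`, `convection`, `ventricle_flux` (sparse matrices),
#'   `reaction` (diagonal vector), `A` (their sum as used by the scheme),
#'   `dirichlet_nodes`, and mesh/problem references.
#' @export
assemble_operators <- function(problem) {
  mesh <- problem$mesh
  v <- mesh$vertices
  cl <- mesh$cells
  n <- nrow(v); m <- nrow(cl)
  p1 <- v[cl[, 1L], , drop = FALSE]
  a <- v[cl[, 2L], , drop = FALSE] - p1
  b <- v[cl[, 3L], , drop = FALSE] - p1
  c3 <- v[cl[, 4L], , drop = FALSE] - p1
  cross <- function(u, w) cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
                                u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
                                u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  bxc <- cross(b, c3)
  det <- rowSums(a * bxc)            # 6 V (positive: cells are oriented)
  if (any(det <= 0)) stop("non-positive lumped mass entry: degenerate cell")
  vol <- det / 6
  g2 <- bxc / det
  g3 <- cross(c3, a) / det
  g4 <- cross(a, b) / det
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  # lumped mass
  M <- as.vector(Matrix::sparseMatrix(i = as.vector(cl),
                                      j = rep.int(1L, 4L * m),
                                      x = rep(vol / 4, 4L),
                                      dims = c(n, 1L)))

  D <- problem$coeffs$diffusivity
  Dk <- if (length(D) == 1L) rep.int(D, m) else
    (D[cl[, 1L]] + D[cl[, 2L]] + D[cl[, 3L]] + D[cl[, 4L]]) / 4

  ii <- integer(0); jj <- integer(0); xs <- numeric(0)
  for (i in 1:4) for (j in 1:4) {
    ii <- c(ii, cl[, i]); jj <- c(jj, cl[, j])
    xs <- c(xs, Dk * vol * rowSums(grads[[i]] * grads[[j]]))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xs, dims = c(n, n))

  vel <- problem$coeffs$velocity
  if (!is.null(vel)) {
    vk <- (vel[cl[, 1L], , drop = FALSE] + vel[cl[, 2L], , drop = FALSE] +
           vel[cl[, 3L], , drop = FALSE] + vel[cl[, 4L], , drop = FALSE]) / 4
    ii <- integer(0); jj <- integer(0); xs <- numeric(0)
    for (i in 1:4) {
      ci <- -rowSums(vk * grads[[i]]) * vol / 4
      for (j in 1:4) {
        ii <- c(ii, cl[, i]); jj <- c(jj, cl[, j]); xs <- c(xs, ci)
      }
    }
    C <- Matrix::sparseMatrix(i = ii, j = jj, x = xs, dims = c(n, n))
  } else {
    C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }

  # convective flux matrix on ventricle facets (v.n c phi_i phi_j surface term)
  vent <- which(mesh$facet_label == .VENT)
  if (!is.null(vel) && length(vent)) {
    fac <- mesh$facets[vent, , drop = FALSE]
    areas <- facet_areas(mesh)[vent]
    normals <- .facet_normals(mesh)[vent, , drop = FALSE]
    vf <- (vel[fac[, 1L], , drop = FALSE] + vel[fac[, 2L], , drop = FALSE] +
           vel[fac[, 3L], , drop = FALSE]) / 3
    wn <- rowSums(vf * normals)       # facet-average v.n (outward)
    ii <- integer(0); jj <- integer(0); xs <- numeric(0)
    for (i in 1:3) for (j in 1:3) {
      ii <- c(ii, fac[, i]); jj <- c(jj, fac[, j])
      xs <- c(xs, wn * areas / 12 * (1 + (i == j)))
    }
    B <- Matrix::sparseMatrix(i = ii, j = jj, x = xs, dims = c(n, n))
  } else {
    B <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }

  r <- problem$coeffs$drainage_r
  A <- K + C + Matrix::Diagonal(n, r * M)
  if (problem$retain_ventricle_convection) A <- A + B

  dir_nodes <- sort(unique(as.vector(mesh$facets[mesh$facet_label == .SAS, ])))

  structure(list(mass_lumped = M, stiffness = K, convection = C,
                 ventricle_flux = B, reaction = r * M, A = A,
                 dirichlet_nodes = dir_nodes, drainage_r = r,
                 n = n, mesh = mesh),
            class = "transport_operators")
}

#' One implicit midpoint step
#'
#' Advances the concentration by one step of the implicit midpoint scheme
#' with Dirichlet row replacement on the SAS nodes. Intended for verification
#' and unit tests; [solve_transport()] reuses a single factorization over the
#' whole trajectory.
#'
#' @param ops operators from [assemble_operators()].
#' @param c_now current nodal concentration.
#' @param g_dir Dirichlet values (one per `ops$dirichlet_nodes`) to impose
#'   over the step.
#' @param dt time step in s.
#' @return nodal concentration after the step.
#' @export
transport_step <- function(ops, c_now, g_dir, dt) {
  n <- ops$n
  dir <- ops$dirichlet_nodes
  Mdt <- Matrix::Diagonal(n, ops$mass_lumped / dt)
  lhs <- Mdt + ops$A / 2
  rhs <- as.vector(Mdt %*% c_now - ops$A %*% c_now / 2)
  keep <- rep.int(1, n); keep[dir] <- 0
  lhs <- Matrix::Diagonal(n, keep) %*% lhs +
    Matrix::sparseMatrix(i = dir, j = dir, x = 1, dims = c(n, n))
  rhs[dir] <- g_dir
  as.vector(Matrix::solve(lhs, rhs))
}

#' Solve a transport problem
#'
#' Runs the full implicit-midpoint trajectory. With the coupled SAS model the
#' Dirichlet value over each step is `c_CSF(t_n) * (h(t_n) + h(t_{n+1})) / 2`
#' (explicit trapezoidal boundary coupling); `c_CSF` is recovered after every
#' step by rearranging the tracer conservation identity. The drained amount
#' and the ventricular convective efflux are accumulated by trapezoidal
#' quadrature in time and enter the budget as explicit components.
#'
#' The returned series carries, per step: the SAS concentration trace, the
#' parenchymal amount, the cumulative drained and ventricular amounts, the
#' budget closure residual, and the explicit-coupling lag
#' `|c_CSF(t_{n+1}) - c_CSF(t_n)| V_CSF / n0` (the first-order-in-dt error
#' indicator of the explicit boundary coupling).
#'
#' @param problem a [transport_problem()].
#' @param ops optional pre-assembled operators (from [assemble_operators()]).
#' @return an object of class `concentration_series`.
#' @export
solve_transport <- function(problem, ops = NULL) {
  if (is.null(ops)) ops <- assemble_operators(problem)
  mesh <- problem$mesh
  n <- ops$n
  dt <- problem$dt
  nsteps <- round(problem$t_end / dt)
  dir <- ops$dirichlet_nodes
  xdir <- mesh$vertices[dir, , drop = FALSE]
  bp <- problem$boundary
  coupled <- is.null(problem$dirichlet)

  Mdt <- Matrix::Diagonal(n, ops$mass_lumped / dt)
  keep <- rep.int(1, n); keep[dir] <- 0
  lhs <- Matrix::Diagonal(n, keep) %*% (Mdt + ops$A / 2) +
    Matrix::sparseMatrix(i = dir, j = dir, x = 1, dims = c(n, n))
  fac <- Matrix::lu(methods::as(lhs, "CsparseMatrix"))
  rhs_op <- Mdt - ops$A / 2
  Bvent <- ops$ventricle_flux
  track_vent <- problem$retain_ventricle_convection &&
    length(Bvent@x) > 0

  cc <- if (is.function(problem$initial)) problem$initial(mesh$vertices)
        else rep_len(problem$initial, n)
  cc <- as.numeric(cc)
  paren <- sum(ops$mass_lumped * cc); drained <- 0; vented <- 0
  ccsf <- if (coupled)
    update_csf_concentration(paren, 0, bp, tol = problem$budget_tol)
  else NA_real_
  step_times <- seq(0, by = dt, length.out = nsteps + 1L)
  ccsf_trace <- numeric(nsteps + 1L); ccsf_trace[1L] <- ccsf
  paren_trace <- numeric(nsteps + 1L); paren_trace[1L] <- paren
  drained_trace <- numeric(nsteps + 1L)
  vent_trace <- numeric(nsteps + 1L)
  budget_resid <- numeric(nsteps + 1L)
  coupling_lag <- rep(NA_real_, nsteps + 1L)
  min_c <- 0

  out_idx <- match(round(problem$output_times / dt), 0:nsteps)
  nodal_out <- matrix(NA_real_, n, length(problem$output_times))
  if (!is.na(k0 <- match(1L, out_idx))) nodal_out[, k0] <- cc

  for (s in seq_len(nsteps)) {
    t0 <- step_times[s]; t1 <- step_times[s + 1L]
    if (coupled) {
      gbar <- ccsf * (spatial_profile_h(t0, xdir[, 3L], bp) +
                      spatial_profile_h(t1, xdir[, 3L], bp)) / 2
    } else {
      gbar <- (problem$dirichlet(t0, xdir) + problem$dirichlet(t1, xdir)) / 2
    }
    b <- as.vector(rhs_op %*% cc)
    b[dir] <- gbar
    c_new <- as.vector(Matrix::solve(fac, b))
    if (anyNA(c_new) || any(!is.finite(c_new)))
      stop("transport solve produced non-finite values at t = ", t1, " s")
    c_mid <- (cc + c_new) / 2
    paren_mid <- sum(ops$mass_lumped * c_mid)
    drained <- drained + dt * ops$drainage_r * paren_mid
    if (track_vent) vented <- vented + dt * sum(Bvent %*% c_mid)
    cc <- c_new
    paren <- sum(ops$mass_lumped * cc)
    min_c <- min(min_c, min(cc))
    paren_trace[s + 1L] <- paren
    drained_trace[s + 1L] <- drained
    vent_trace[s + 1L] <- vented
    if (coupled) {
      ccsf_new <- update_csf_concentration(paren, drained, bp, vented,
                                           tol = problem$budget_tol)
      budget_resid[s + 1L] <- abs(paren + ccsf_new * bp$V_CSF + drained +
                                  vented - bp$n0) / bp$n0
      coupling_lag[s + 1L] <- abs(ccsf_new - ccsf) * bp$V_CSF / bp$n0
      ccsf <- ccsf_new
      ccsf_trace[s + 1L] <- ccsf
    }
    if (!is.na(k <- match(s + 1L, out_idx))) nodal_out[, k] <- cc
  }

  structure(list(times = problem$output_times,
                 nodal_c = nodal_out,
                 step_times = step_times,
                 c_csf_trace = if (coupled) ccsf_trace else NULL,
                 parenchymal_trace = paren_trace,
                 drained_trace = drained_trace,
                 ventricular_trace = vent_trace,
                 budget_residuals = if (coupled) budget_resid else NULL,
                 coupling_lag = if (coupled) coupling_lag else NULL,
                 min_concentration = min_c,
                 dt = dt, t_end = problem$t_end,
                 boundary = bp, coeffs_meta = list(
                   diffusivity = problem$coeffs$diffusivity,
                   drainage_r = problem$coeffs$drainage_r,
                   seed = problem$coeffs$seed,
                   index = problem$coeffs$index)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("concentration_series: %d stored fields over %.1f h (dt = %.0f s)\n",
              length(x$times), x$t_end / 3600, x$dt))
  if (!is.null(x$c_csf_trace))
    cat(sprintf("  c_CSF: %.3f -> %.3f mol/m^3; parenchymal %.3g mol; max budget residual %.2g\n",
                x$c_csf_trace[1L], x$c_csf_trace[length(x$c_csf_trace)],
                x$parenchymal_trace[length(x$parenchymal_trace)],
                max(x$budget_residuals)))
  invisible(x)
}

#' Upper estimate of the Peclet number
#'
#' `Pe = 9 L v / D`: the ratio of convective to diffusive transport rates
#' over the half-diameter L of the domain, with the factor 9 accounting for
#' the low-probability upper range of the stochastic velocity magnitude.
#'
#' @param L length scale in m (half the domain diameter, about 0.084 m).
#' @param v_mag velocity magnitude in m/s.
#' @param D diffusivity in m^2/s (must be positive).
#' @return dimensionless Peclet estimate.
#' @export
estimate_peclet <- function(L = 0.084, v_mag = 1.7e-7, D = 1.2e-10) {
  if (D <= 0) stop("D must be positive")
  9 * L * v_mag / D
}
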