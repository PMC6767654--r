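# Stochastic convective velocity fields.
#
# V1 (glymphatic circulation): the curl of a vector potential of three i.i.d.
#    standard Matern fields (divergence-free by construction), scaled by
#    v_avg * eta * 10^(-E) with E ~ Exponential(mean 0.2) drawn once per
#    realization.  eta is calibrated so E[||v||^2]^(1/2) = v_avg.
# V2: V1 plus a deterministic large-scale directional field v_dir following
#    the cardiac-pulse path up the brain stem.
# V3 (paraarterial inflow with drainage): a radial inward field vanishing at
#    the ventricular center, scaled by a gamma random variable per
#    realization, together with a homogeneous drainage rate r.

#' Specify a stochastic velocity model
#'
#' @param model `"V1"`, `"V2"` or `"V3"`.
#' @param v_avg target RMS velocity magnitude in m/s.
#' @param lambda_v correlation length of the Matern vector potential in m
#'   (V1/V2), the typical arteriole-venule spacing.
#' @param exp_mean mean of the exponential attenuation exponent E (V1/V2).
#' @param eta calibrated scaling constant (set by [calibrate_eta()]).
#' @param v_f directional field speed scale in m/s (V2).
#' @param R radius of the inflow target region in m (V3).
#' @param x_c center of the inflow target region, the ventricular center (V3).
#' @param inflow_shape gamma shape of the V3 inflow magnitude.
#' @param inflow_scale gamma scale of the V3 inflow magnitude, calibrated by
#'   [calibrate_inflow_scale()].
#' @param drainage_r homogeneous drainage rate in 1/s (non-zero only for V3).
#' @return an object of class `velocity_spec`.
#' @export
velocity_spec <- function(model = c("V1", "V2", "V3"),
                          v_avg = 1.7e-7,
                          lambda_v = 1020e-6,
                          exp_mean = 0.2,
                          eta = NULL,
                          v_f = 2e-6,
                          R = 0.08,
                          x_c = c(0, 0, 0),
                          inflow_shape = 2,
                          inflow_scale = NULL,
                          drainage_r = if (match.arg(model) == "V3") 1e-5 else 0) {
  model <- match.arg(model)
  stopifnot(v_avg > 0, lambda_v > 0, exp_mean > 0, v_f >= 0, R > 0,
            drainage_r >= 0, inflow_shape > 0)
  if (!is.null(eta) && eta <= 0) stop("eta must be positive once calibrated")
  structure(list(model = model, v_avg = v_avg, lambda_v = lambda_v,
                 exp_mean = exp_mean, eta = eta, v_f = v_f, R = R,
                 x_c = as.numeric(x_c), inflow_shape = inflow_shape,
                 inflow_scale = inflow_scale, drainage_r = drainage_r),
            class = "velocity_spec")
}

# E[10^(-p*E)] for E ~ Exponential(mean mu): Laplace transform at p*ln(10)
.exp_attenuation_moment <- function(mu, p = 1) {
  rate <- 1 / mu
  rate / (rate + p * log(10))
}

# centered-difference curl of a vector potential sampled on the regular grid;
# one-sided differences at the box faces.  Centered difference operators
# commute, so the discrete (centered) divergence of the result vanishes
# identically on the grid interior.
.grid_diff <- function(a, axis, h) {
  n <- dim(a)
  d <- array(0, n)
  idx <- function(k) switch(axis,
    a[k, , , drop = FALSE], a[, k, , drop = FALSE], a[, , k, drop = FALSE])
  assign_slice <- function(arr, k, val) {
    switch(axis,
           arr[k, , ] <- val, arr[, k, ] <- val, arr[, , k] <- val)
    arr
  }
  nk <- n[axis]
  mid <- 2:(nk - 1L)
  d <- assign_slice(d, mid, (idx(mid + 1L) - idx(mid - 1L)) / (2 * h))
  d <- assign_slice(d, 1L, (idx(2L) - idx(1L)) / h)
  d <- assign_slice(d, nk, (idx(nk) - idx(nk - 1L)) / h)
  d
}

.grid_curl <- function(psi, h) {
  list(.grid_diff(psi[[3L]], 2L, h) - .grid_diff(psi[[2L]], 3L, h),
       .grid_diff(psi[[1L]], 3L, h) - .grid_diff(psi[[3L]], 1L, h),
       .grid_diff(psi[[2L]], 1L, h) - .grid_diff(psi[[1L]], 2L, h))
}

# raw (unscaled) curl realization interpolated to points; one per sample
.sample_raw_curl <- function(matern, points, seed) {
  psi <- sample_matern_scalar(matern, n = 3L, seed = seed)
  grid <- attr(psi, "grid")
  curl <- .grid_curl(psi, matern$spacing)
  cbind(.interp_grid(curl[[1L]], grid, points),
        .interp_grid(curl[[2L]], grid, points),
        .interp_grid(curl[[3L]], grid, points))
}

#' Calibrate the glymphatic velocity scaling constant eta
#'
#' Chooses eta so that the RMS magnitude of the full V1 field,
#' `E[||v||^2]^(1/2)` (expectation over realizations and space), equals
#' `v_avg`. The attenuation moment `E[10^(-2E)]` is evaluated in closed form
#' (Laplace transform of the exponential); the curl second moment is
#' estimated by Monte Carlo over `n_samples` potential realizations,
#' evaluated through the full operational pipeline (grid sampling, centered
#' finite-difference curl, trilinear interpolation) at uniform random points
#' in the sampling box, so the calibration applies to the field as evaluated
#' at mesh vertices.
#'
#' @param spec a [velocity_spec()] for V1 or V2.
#' @param matern a [matern_spec()] for the vector potential components.
#' @param n_samples Monte Carlo calibration sample count.
#' @param seed integer seed (calibration is reproducible).
#' @param points optional fixed evaluation points (n x 3): supply the mesh
#'   vertices the field will actually be evaluated at, so the calibrated RMS
#'   applies exactly to that population of points. Default: fresh uniform
#'   points in the sampling box interior per realization.
#' @param n_points evaluation points per realization (when `points` is NULL).
#' @return `spec` with `eta` set; calibration details in
#'   `attr(spec, "calibration")`.
#' @export
calibrate_eta <- function(spec, matern, n_samples = 200L, seed = 1L,
                          points = NULL, n_points = 2000L) {
  stopifnot(inherits(spec, "velocity_spec"), spec$model %in% c("V1", "V2"),
            inherits(matern, "matern_spec"))
  pad <- matern$spacing
  lo <- matern$box_min + pad
  hi <- matern$box_max - pad
  ms <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    s <- derive_seed(seed, i)
    pts <- if (is.null(points))
      with_seed(derive_seed(s, 99L),
        cbind(stats::runif(n_points, lo[1L], hi[1L]),
              stats::runif(n_points, lo[2L], hi[2L]),
              stats::runif(n_points, lo[3L], hi[3L])))
    else points
    cr <- .sample_raw_curl(matern, pts, s)
    ms[i] <- mean(rowSums(cr^2))
  }
  m_curl2 <- mean(ms)
  if (m_curl2 <= 0) stop("degenerate curl field: zero variance on this grid")
  e10 <- .exp_attenuation_moment(spec$exp_mean, p = 2)
  spec$eta <- 1 / sqrt(e10 * m_curl2)
  attr(spec, "calibration") <- list(mean_curl_sq = m_curl2,
                                    attenuation_moment = e10,
                                    n_samples = n_samples, seed = seed)
  spec
}

#' Sample the glymphatic circulation velocity field (Model V1)
#'
#' Each realization draws three i.i.d. standard Matern potential components
#' on the auxiliary grid, takes their centered-difference curl (exactly
#' divergence-free in the discrete sense), interpolates to the mesh vertices
#' and scales by `v_avg * eta * 10^(-E)` with a fresh exponential E per
#' realization.
#'
#' @param spec a calibrated [velocity_spec()] (`eta` set).
#' @param matern the [matern_spec()] used for calibration.
#' @param mesh a [labeled_mesh()] contained in the sampling box.
#' @param n number of realizations.
#' @param seed integer seed.
#' @return list of `n` vertex-velocity matrices (n_vertices x 3, m/s), each
#'   with the drawn attenuation exponent attached as attribute `E`.
#' @export
sample_velocity_V1 <- function(spec, matern, mesh, n = 1L, seed) {
  stopifnot(inherits(spec, "velocity_spec"), spec$model %in% c("V1", "V2"))
  if (is.null(spec$eta)) stop("eta is not calibrated; run calibrate_eta() first")
  .check_box_contains(matern, mesh$vertices)
  lapply(seq_len(n), function(i) {
    s <- derive_seed(seed, i)
    cr <- .sample_raw_curl(matern, mesh$vertices, derive_seed(s, 1L))
    E <- with_seed(derive_seed(s, 2L), stats::rexp(1L, rate = 1 / spec$exp_mean))
    v <- spec$v_avg * spec$eta * 10^(-E) * cr
    attr(v, "E") <- E
    v
  })
}

#' Deterministic directional velocity field
#'
#' Large-scale directional flow following the cardiac-pulse propagation path:
#' upward along the brain-stem axis, spreading out and slowing with distance
#' from the axis, evaluated componentwise as
#' `-v_f * (atan(15 x1) (|x1| - 0.1), atan(15 x2) (|x2| - 0.1),
#' -0.9 x3 + 0.06 - sqrt(x1^2 + x2^2))`.
#'
#' @param points n x 3 matrix of coordinates (m).
#' @param v_f speed scale in m/s.
#' @return n x 3 matrix of velocities (m/s).
#' @export
evaluate_directional_velocity <- function(points, v_f = 2e-6) {
  points <- matrix(as.numeric(points), ncol = 3L)
  x1 <- points[, 1L]; x2 <- points[, 2L]; x3 <- points[, 3L]
  -v_f * cbind(atan(15 * x1) * (abs(x1) - 0.1),
               atan(15 * x2) * (abs(x2) - 0.1),
               -0.9 * x3 + 0.06 - sqrt(x1^2 + x2^2))
}

#' Sample the glymphatic velocity field with directionality (Model V2)
#'
#' Superposition of a fresh V1 realization and the deterministic directional
#' field: the same seed yields the V1 sample plus
#' [evaluate_directional_velocity()] exactly.
#'
#' @inheritParams sample_velocity_V1
#' @return list of `n` vertex-velocity matrices (m/s).
#' @export
sample_velocity_V2 <- function(spec, matern, mesh, n = 1L, seed) {
  v1 <- sample_velocity_V1(spec, matern, mesh, n = n, seed = seed)
  vdir <- evaluate_directional_velocity(mesh$vertices, spec$v_f)
  lapply(v1, function(v) {
    out <- v + vdir
    attr(out, "E") <- attr(v, "E")
    out
  })
}

# spatial profile of the V3 inflow ansatz: s(x) such that
# v = vbar * s(||x - x_c||) * (x_c - x); s -> 0 at the center and beyond 2R
.v3_profile <- function(dist, R) {
  q <- (R - dist)^2
  den <- R^2 - q
  ifelse(den > 0, exp(-3 * q / den), 0)
}

#' Calibrate the V3 inflow gamma scale
#'
#' Sets the gamma scale theta of the per-realization inflow magnitude so that
#' `E[||v||^2]^(1/2) = v_avg` over the mesh, using mesh quadrature of the
#' squared spatial profile and `E[vbar^2] = k (k + 1) theta^2`.
#'
#' @param spec a [velocity_spec()] with `model = "V3"`.
#' @param mesh a [labeled_mesh()].
#' @return `spec` with `inflow_scale` set.
#' @export
calibrate_inflow_scale <- function(spec, mesh) {
  stopifnot(inherits(spec, "velocity_spec"), spec$model == "V3")
  cent <- cell_centroids(mesh)
  vol <- cell_volumes(mesh)
  d <- sqrt(rowSums(sweep(cent, 2L, spec$x_c, `-`)^2))
  prof2 <- (.v3_profile(d, spec$R) * d)^2
  mean_prof2 <- sum(prof2 * vol) / sum(vol)
  k <- spec$inflow_shape
  spec$inflow_scale <- spec$v_avg / sqrt(k * (k + 1) * mean_prof2)
  spec
}

#' Sample the paraarterial inflow velocity field (Model V3)
#'
#' Radially inward field `vbar(omega) * s(||x - x_c||) * (x_c - x)` vanishing
#' at the ventricular center, with one gamma draw `vbar` per realization, plus
#' the homogeneous drainage rate r.
#'
#' @param spec a [velocity_spec()] with `model = "V3"` and calibrated
#'   `inflow_scale` (see [calibrate_inflow_scale()]).
#' @param mesh a [labeled_mesh()].
#' @param n number of realizations.
#' @param seed integer seed.
#' @return list of `n` elements, each a list with `velocity`
#'   (n_vertices x 3, m/s), `vbar` (the gamma draw, 1/(m s)) and `drainage_r`
#'   (1/s).
#' @export
sample_velocity_V3 <- function(spec, mesh, n = 1L, seed) {
  stopifnot(inherits(spec, "velocity_spec"), spec$model == "V3")
  if (is.null(spec$inflow_scale))
    stop("inflow_scale is not calibrated; run calibrate_inflow_scale() first")
  lo <- apply(mesh$vertices, 2L, min); hi <- apply(mesh$vertices, 2L, max)
  if (any(spec$x_c < lo) || any(spec$x_c > hi))
    stop("inflow center x_c lies outside the mesh bounding box")
  d <- sqrt(rowSums(sweep(mesh$vertices, 2L, spec$x_c, `-`)^2))
  s <- .v3_profile(d, spec$R)
  dirmat <- sweep(-mesh$vertices, 2L, spec$x_c, `+`)  # x_c - x
  vbars <- with_seed(seed,
    stats::rgamma(n, shape = spec$inflow_shape, scale = spec$inflow_scale))
  lapply(seq_len(n), function(i)
    list(velocity = vbars[i] * s * dirmat,
         vbar = vbars[i],
         drainage_r = spec$drainage_r))
}
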