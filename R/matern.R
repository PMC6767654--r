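# Stationary Matern Gaussian random fields sampled on a regular auxiliary box
# grid by circulant embedding (FFT), then evaluated at arbitrary points by
# trilinear interpolation.  The correlation length lambda is defined as the
# distance at which the correlation decays to exp(-1); with the default
# smoothness nu = 1/2 the covariance is exponential, exp(-d/lambda).

#' Specify a Matern field and its sampling grid
#'
#' @param correlation_length correlation length lambda in m (e-folding
#'   distance of the correlation function).
#' @param box_min,box_max corners of the auxiliary sampling box (m). The box
#'   must strictly contain any mesh the field will be evaluated on.
#' @param spacing grid spacing in m. Resolving the field requires
#'   `spacing <= lambda/3`; coarser grids are allowed (with a warning) because
#'   brain-scale velocity sampling is routinely run on grids coarser than the
#'   1020 um correlation length.
#' @param nu Matern smoothness; `0.5` gives the exponential covariance.
#' @param variance marginal variance of the field (1 for standard fields).
#' @return an object of class `matern_spec`.
#' @export
matern_spec <- function(correlation_length, box_min, box_max, spacing,
                        nu = 0.5, variance = 1) {
  if (correlation_length <= 0) stop("correlation length must be positive")
  if (spacing <= 0) stop("grid spacing must be positive")
  box_min <- as.numeric(box_min); box_max <- as.numeric(box_max)
  if (length(box_min) != 3L || length(box_max) != 3L || any(box_max <= box_min))
    stop("box_min/box_max must define a non-empty 3D box")
  if (spacing > correlation_length / 3)
    warning("grid spacing exceeds lambda/3: the field will be under-resolved on this grid")
  dims <- pmax(2L, as.integer(ceiling((box_max - box_min) / spacing)) + 1L)
  structure(
    list(lambda = correlation_length, nu = nu, variance = variance,
         box_min = box_min, box_max = box_max, spacing = spacing,
         dims = dims, cache = new.env(parent = emptyenv())),
    class = "matern_spec")
}

#' Matern correlation function
#'
#' Correlation at lag `d` for smoothness `nu`, scaled so that the correlation
#' at `d = lambda` equals `exp(-1)` (the package's definition of correlation
#' length). For `nu = 0.5` this is exactly `exp(-d/lambda)`.
#'
#' @param d lag distance(s) in m.
#' @param lambda correlation length in m.
#' @param nu smoothness.
#' @return correlation value(s) in (0, 1].
#' @export
matern_correlation <- function(d, lambda, nu = 0.5) {
  if (abs(nu - 0.5) < 1e-12) return(exp(-abs(d) / lambda))
  base <- function(t) {
    out <- rep(1, length(t))
    pos <- t > 0
    tp <- t[pos]
    out[pos] <- 2^(1 - nu) / gamma(nu) * tp^nu * besselK(tp, nu)
    out
  }
  # choose the internal scale so base(scale * lambda) = exp(-1)
  f <- function(s) base(s) - exp(-1)
  s_star <- stats::uniroot(f, c(1e-8, 50), tol = 1e-12)$root
  base(abs(d) * s_star / lambda)
}

# circulant-embedding eigenvalues (cached per spec)
.matern_eigen <- function(spec) {
  if (!is.null(spec$cache$sqrt_eig)) return(spec$cache$sqrt_eig)
  n <- spec$dims
  # pad so points are separated by >= 6 lambda around the torus (keeps the
  # embedding positive definite for the exponential family), FFT-friendly sizes
  pad <- ceiling(6 * spec$lambda / spec$spacing)
  N <- vapply(pmax(2L * (n - 1L), n - 1L + pad), stats::nextn,
              integer(1L), factors = c(2L, 3L, 5L))
  dist1 <- function(Nk) {
    k <- 0:(Nk - 1L)
    pmin(k, Nk - k) * spec$spacing
  }
  dx <- dist1(N[1L]); dy <- dist1(N[2L]); dz <- dist1(N[3L])
  d2 <- outer(dx^2, dy^2, `+`)
  dist <- sqrt(outer(d2, dz^2, `+`))
  cov <- array(matern_correlation(dist, spec$lambda, spec$nu), dim = N)
  eig <- Re(stats::fft(cov))
  neg <- eig < 0
  if (any(neg)) {
    worst <- min(eig)
    if (worst < -1e-3 * max(eig))
      warning(sprintf(
        "circulant embedding not positive definite (min eigenvalue %.3g relative); clipping",
        worst / max(eig)))
    eig[neg] <- 0
  }
  spec$cache$sqrt_eig <- sqrt(eig / prod(N))
  spec$cache$sqrt_eig
}

#' Sample standard Matern scalar fields on the auxiliary grid
#'
#' Draws `n` independent realizations of the zero-mean Gaussian field with
#' the spec's Matern covariance on the regular box grid, via circulant
#' embedding: each FFT of complex white noise yields two independent
#' realizations (real and imaginary parts).
#'
#' @param spec a [matern_spec()].
#' @param n number of realizations.
#' @param seed integer seed (local; the global RNG state is untouched).
#' @return list of `n` 3D arrays of dimension `spec$dims`, with the grid
#'   description attached as attribute `grid`.
#' @export
sample_matern_scalar <- function(spec, n = 1L, seed) {
  stopifnot(inherits(spec, "matern_spec"))
  sqrt_eig <- .matern_eigen(spec)
  N <- dim(sqrt_eig)
  ntot <- prod(N)
  sdv <- sqrt(spec$variance)
  fields <- vector("list", n)
  with_seed(seed, {
    k <- 1L
    while (k <= n) {
      xi <- array(complex(real = stats::rnorm(ntot),
                          imaginary = stats::rnorm(ntot)), dim = N)
      w <- stats::fft(sqrt_eig * xi)
      fields[[k]] <- sdv * Re(w)[seq_len(spec$dims[1L]),
                                 seq_len(spec$dims[2L]),
                                 seq_len(spec$dims[3L]), drop = FALSE]
      if (k + 1L <= n)
        fields[[k + 1L]] <- sdv * Im(w)[seq_len(spec$dims[1L]),
                                        seq_len(spec$dims[2L]),
                                        seq_len(spec$dims[3L]), drop = FALSE]
      k <- k + 2L
    }
  })
  attr(fields, "grid") <- list(origin = spec$box_min, spacing = spec$spacing,
                               dims = spec$dims)
  fields
}

#' Grid coordinates of a Matern spec
#' @param spec a [matern_spec()].
#' @return list of coordinate vectors `x`, `y`, `z`.
#' @export
matern_grid_coords <- function(spec) {
  list(x = spec$box_min[1L] + (seq_len(spec$dims[1L]) - 1L) * spec$spacing,
       y = spec$box_min[2L] + (seq_len(spec$dims[2L]) - 1L) * spec$spacing,
       z = spec$box_min[3L] + (seq_len(spec$dims[3L]) - 1L) * spec$spacing)
}

# trilinear interpolation of a gridded field to arbitrary points.
# normalize = TRUE rescales each interpolated value to unit marginal variance
# using the Matern correlation between the 8 cell corners (needed for the
# copula transform: plain interpolation of a unit-variance Gaussian field has
# marginal variance < 1 between grid nodes).
.interp_grid <- function(field, grid, points, normalize = FALSE,
                         lambda = NULL, nu = 0.5) {
  n <- grid$dims
  h <- grid$spacing
  rel <- sweep(points, 2L, grid$origin, `-`) / h
  i0 <- pmin(pmax(floor(rel[, 1L]), 0), n[1L] - 2L)
  j0 <- pmin(pmax(floor(rel[, 2L]), 0), n[2L] - 2L)
  k0 <- pmin(pmax(floor(rel[, 3L]), 0), n[3L] - 2L)
  tx <- pmin(pmax(rel[, 1L] - i0, 0), 1)
  ty <- pmin(pmax(rel[, 2L] - j0, 0), 1)
  tz <- pmin(pmax(rel[, 3L] - k0, 0), 1)
  n1 <- n[1L]; n12 <- n[1L] * n[2L]
  base <- (i0 + 1L) + j0 * n1 + k0 * n12
  off <- c(0L, 1L, n1, n1 + 1L, n12, n12 + 1L, n12 + n1, n12 + n1 + 1L)
  W <- cbind((1 - tx) * (1 - ty) * (1 - tz),
             tx * (1 - ty) * (1 - tz),
             (1 - tx) * ty * (1 - tz),
             tx * ty * (1 - tz),
             (1 - tx) * (1 - ty) * tz,
             tx * (1 - ty) * tz,
             (1 - tx) * ty * tz,
             tx * ty * tz)
  f <- as.vector(field)
  val <- numeric(nrow(points))
  for (a in 1:8) val <- val + W[, a] * f[base + off[a]]
  if (normalize) {
    # corner order matches the columns of W
    corners <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                     c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
    dmat <- as.matrix(stats::dist(corners)) * h
    Rho <- matern_correlation(dmat, lambda, nu)
    diag(Rho) <- 1
    sd_int <- sqrt(pmax(rowSums((W %*% Rho) * W), 1e-12))
    val <- val / sd_int
  }
  val
}
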