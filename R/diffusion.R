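# Stochastic effective diffusivity of gadobutrol in brain parenchyma.
# Model D1: a single gamma-distributed random variable per realization.
# Model D2: a random field with the same pointwise gamma marginal and a
# 0.01 m correlation length (Gaussian-copula transform of a Matern field).
# Both are bounded below by 0.25 * D_Gad, so realizations are always positive.

#' Specify a stochastic diffusivity model
#'
#' The sampled diffusivity is `offset_factor * D_Gad + Gamma(shape, scale)`,
#' giving expectation `D_Gad` with the default shape 3 and scale
#' `0.75 * D_Gad / 3`, and an infimum of `0.25 * D_Gad`.
#'
#' @param model `"D1"` (random variable) or `"D2"` (random field).
#' @param D_Gad effective gadobutrol diffusivity in m^2/s.
#' @param offset_factor lower bound as a fraction of `D_Gad`.
#' @param shape gamma shape parameter k.
#' @param scale gamma scale parameter theta in m^2/s.
#' @param correlation_length spatial correlation length of the D2 field in m.
#' @return an object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(model = c("D1", "D2"),
                           D_Gad = 1.2e-10,
                           offset_factor = 0.25,
                           shape = 3,
                           scale = (1 - offset_factor) * D_Gad / shape,
                           correlation_length = 0.01) {
  model <- match.arg(model)
  stopifnot(D_Gad > 0, offset_factor > 0, shape > 0, scale > 0,
            correlation_length > 0)
  structure(list(model = model, D_Gad = D_Gad, offset_factor = offset_factor,
                 shape = shape, scale = scale,
                 correlation_length = correlation_length),
            class = "diffusion_spec")
}

#' Sample the homogeneous diffusivity (Model D1)
#'
#' @param spec a [diffusion_spec()] with `model = "D1"`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of diffusivities in m^2/s, each strictly greater
#'   than `offset_factor * D_Gad`.
#' @export
sample_diffusion_D1 <- function(spec, n = 1L, seed) {
  stopifnot(inherits(spec, "diffusion_spec"), spec$model == "D1")
  with_seed(seed,
    spec$offset_factor * spec$D_Gad +
      stats::rgamma(n, shape = spec$shape, scale = spec$scale))
}

#' Sample the heterogeneous diffusivity field (Model D2)
#'
#' Draws a standard Matern field on an auxiliary box grid enclosing the mesh,
#' interpolates it to the mesh vertices (with exact variance renormalization),
#' and maps it through the standard normal CDF and the gamma quantile
#' function. The pointwise marginal is therefore exactly the shifted gamma of
#' Model D1; the spatial correlation is approximately Matern with the spec's
#' correlation length.
#'
#' @param spec a [diffusion_spec()] with `model = "D2"`.
#' @param mesh a [labeled_mesh()].
#' @param n number of field realizations.
#' @param seed integer seed.
#' @param matern optional pre-built [matern_spec()] (reused across calls to
#'   amortize the embedding setup); must enclose the mesh.
#' @return list of `n` nodal vectors (one value per mesh vertex, m^2/s).
#' @export
sample_diffusion_D2 <- function(spec, mesh, n = 1L, seed, matern = NULL) {
  stopifnot(inherits(spec, "diffusion_spec"), spec$model == "D2")
  if (is.null(matern)) matern <- .mesh_matern_spec(mesh, spec$correlation_length)
  .check_box_contains(matern, mesh$vertices)
  fields <- sample_matern_scalar(matern, n = n, seed = seed)
  grid <- attr(fields, "grid")
  lapply(fields, function(f) {
    z <- .interp_grid(f, grid, mesh$vertices, normalize = TRUE,
                      lambda = matern$lambda, nu = matern$nu)
    spec$offset_factor * spec$D_Gad +
      stats::qgamma(stats::pnorm(z), shape = spec$shape, scale = spec$scale)
  })
}

# default auxiliary sampling box for a mesh: bounding box padded by one
# correlation length, spacing lambda/4
.mesh_matern_spec <- function(mesh, lambda, spacing = lambda / 4) {
  lo <- apply(mesh$vertices, 2L, min) - max(lambda / 2, 2 * spacing)
  hi <- apply(mesh$vertices, 2L, max) + max(lambda / 2, 2 * spacing)
  matern_spec(lambda, lo, hi, spacing)
}

.check_box_contains <- function(matern, points) {
  lo <- apply(points, 2L, min); hi <- apply(points, 2L, max)
  if (any(lo < matern$box_min - 1e-12) || any(hi > matern$box_max + 1e-12))
    stop("mesh extends outside the Matern sampling box")
  invisible(TRUE)
}
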