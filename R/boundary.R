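# Subarachnoid-space (SAS) tracer boundary model.
#
# The Dirichlet value on the SAS interface is g(t,x) = c_CSF(t) * h(t,x):
# a smooth step profile h travelling upward (the tracer front rising from the
# spinal to the cranial SAS) times the average SAS concentration c_CSF, which
# is coupled to the parenchymal content through conservation of the injected
# tracer amount n0.

#' SAS boundary model parameters
#'
#' @param a concentration-gradient steepness of the SAS front in 1/m.
#' @param z0 front position at t = 0 in m (z-coordinate; z = 0 is the
#'   lateral-ventricle level).
#' @param u_x3 upward front speed in m/s.
#' @param n0 injected tracer amount in mol.
#' @param V_CSF CSF volume of the SAS and ventricles in m^3.
#' @return an object of class `boundary_params`.
#' @export
boundary_params <- function(a = 20, z0 = -0.2, u_x3 = 1.5e-5,
                            n0 = 5e-4, V_CSF = 1.4e-4) {
  stopifnot(a > 0, u_x3 >= 0, n0 > 0, V_CSF > 0)
  structure(list(a = a, z0 = z0, u_x3 = u_x3, n0 = n0, V_CSF = V_CSF),
            class = "boundary_params")
}

#' Spatial step profile of the SAS tracer front
#'
#' `h(t, x3) = 0.5 + arctan(-a (x3 - z0 - u_x3 t)) / pi`: strictly in (0, 1),
#' monotonically decreasing in `x3`, equal to 0.5 on the front
#' `x3 = z0 + u_x3 t`, which rises at speed `u_x3`.
#'
#' @param t time in s.
#' @param x3 z-coordinate(s) in m.
#' @param params a [boundary_params()].
#' @return profile value(s) in (0, 1).
#' @export
spatial_profile_h <- function(t, x3, params = boundary_params()) {
  0.5 + atan(-params$a * (x3 - params$z0 - params$u_x3 * t)) / pi
}

#' SAS concentration from the tracer budget
#'
#' Rearranges the conservation identity: everything injected that is neither
#' in the parenchyma, nor drained, nor lost through the ventricular wall,
#' resides in the CSF:
#' `c_CSF = (n0 - parenchymal - drained - ventricular) / V_CSF`.
#' The value is floored at 0; a negative budget numerator beyond `tol * n0`
#' signals a conservation breach upstream and raises an error.
#'
#' @param parenchymal_amount tracer amount in the parenchyma, mol.
#' @param drained_amount cumulative drained amount, mol.
#' @param params a [boundary_params()].
#' @param ventricular_amount cumulative amount advected out through the
#'   ventricular wall (zero unless a model with nonzero velocity retains the
#'   convective ventricle term), mol.
#' @param tol relative tolerance on budget breach.
#' @return SAS concentration in mol/m^3.
#' @export
update_csf_concentration <- function(parenchymal_amount, drained_amount = 0,
                                     params = boundary_params(),
                                     ventricular_amount = 0, tol = 0.02) {
  num <- params$n0 - parenchymal_amount - drained_amount - ventricular_amount
  if (num < -tol * params$n0)
    stop(sprintf(
      "tracer budget breached: parenchymal + drained exceeds n0 by %.2f%%",
      -100 * num / params$n0))
  max(num, 0) / params$V_CSF
}

#' Dirichlet boundary value on the SAS interface
#'
#' `g(t, x) = c_CSF(t) * h(t, x)`, applied on the SAS part of the boundary
#' only; always in `[0, c_CSF]`.
#'
#' @param t time in s.
#' @param x n x 3 coordinate matrix (or 3-vector).
#' @param c_CSF SAS concentration in mol/m^3 (non-negative).
#' @param params a [boundary_params()].
#' @return boundary concentration(s) in mol/m^3.
#' @export
boundary_value_g <- function(t, x, c_CSF, params = boundary_params()) {
  stopifnot(c_CSF >= 0)
  x <- matrix(as.numeric(x), ncol = 3L)
  c_CSF * spatial_profile_h(t, x[, 3L], params)
}
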