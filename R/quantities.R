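# Per-realization quantities of interest: regional tracer amounts, regional
# mean concentrations, activation times (with censoring at the simulation
# horizon) and boundary-plane concentration traces.

# exact P1 integral of a nodal field over a set of cells
.integrate_cells <- function(c_nodal, mesh, cells_idx, vol = NULL) {
  cl <- mesh$cells[cells_idx, , drop = FALSE]
  if (is.null(vol)) vol <- cell_volumes(mesh)[cells_idx]
  sum(vol / 4 * (c_nodal[cl[, 1L]] + c_nodal[cl[, 2L]] +
                 c_nodal[cl[, 3L]] + c_nodal[cl[, 4L]]))
}

#' Amount of tracer in a region
#'
#' Exact quadrature of the P1 concentration field over the masked cells,
#' `Q = integral_S c dx`. Summing the gray and white compartment masks
#' reproduces the total parenchymal amount used in the budget identity (same
#' quadrature).
#'
#' @param c_nodal nodal concentration (mol/m^3).
#' @param mesh a [labeled_mesh()].
#' @param mask a `region_mask`.
#' @return amount in mol.
#' @export
amount_in_region <- function(c_nodal, mesh, mask) {
  if (!length(mask$members)) stop("empty region mask")
  .integrate_cells(c_nodal, mesh, mask$members)
}

#' Mean tracer concentration in a region
#'
#' `q = (1/V) integral_S c dx` with V the mask volume.
#'
#' @inheritParams amount_in_region
#' @return mean concentration in mol/m^3.
#' @export
mean_concentration_in_region <- function(c_nodal, mesh, mask) {
  vol <- region_volume(mesh, mask)
  if (vol <= 0) stop("region has zero volume")
  amount_in_region(c_nodal, mesh, mask) / vol
}

#' Activation time of a region
#'
#' First time the monitored functional exceeds its threshold (strictly:
#' values exactly at the threshold do not activate), linearly interpolated
#' between stored output times. `mode = "fraction_of_n0"` monitors
#' `integral_S c dx / n0` (threshold X, e.g. 0.1); `mode = "mean_conc"`
#' monitors the regional mean concentration in mol/m^3 (threshold Y, e.g.
#' 1e-3). If the threshold is never exceeded within the stored horizon the
#' result is censored.
#'
#' @param series a `concentration_series` from [solve_transport()].
#' @param mesh the mesh the series was computed on.
#' @param mask a `region_mask`.
#' @param mode `"fraction_of_n0"` or `"mean_conc"`.
#' @param threshold activation threshold (dimensionless fraction or mol/m^3).
#' @param n0 injected amount in mol (for `fraction_of_n0`); defaults to the
#'   boundary model's n0 carried by the series.
#' @return list with `time` (s, `NA` if censored) and `censored` (logical).
#' @export
activation_time <- function(series, mesh, mask,
                            mode = c("fraction_of_n0", "mean_conc"),
                            threshold,
                            n0 = if (!is.null(series$boundary)) series$boundary$n0 else NULL) {
  mode <- match.arg(mode)
  vals <- apply(series$nodal_c, 2L, function(cn)
    amount_in_region(cn, mesh, mask))
  vals <- switch(mode,
                 fraction_of_n0 = {
                   if (is.null(n0)) stop("n0 required for fraction_of_n0 mode")
                   vals / n0
                 },
                 mean_conc = vals / region_volume(mesh, mask))
  .first_crossing(series$times, vals, threshold)
}

# first strict crossing of a sampled trajectory, linearly interpolated
.first_crossing <- function(times, vals, threshold) {
  above <- vals > threshold
  if (!any(above)) return(list(time = NA_real_, censored = TRUE))
  k <- which(above)[1L]
  if (k == 1L) return(list(time = times[1L], censored = FALSE))
  t0 <- times[k - 1L]; t1 <- times[k]
  v0 <- vals[k - 1L]; v1 <- vals[k]
  list(time = t0 + (threshold - v0) / (v1 - v0) * (t1 - t0), censored = FALSE)
}

#' Boundary concentration traces at reference planes
#'
#' The SAS boundary concentration `g(t, z) = c_CSF(t) h(t, z)` evaluated at
#' axial planes, by default z = -0.1, 0 and 0.1 m: the levels of the foramen
#' magnum, Sylvian fissure and precentral sulcus.
#'
#' @param series a `concentration_series` from a coupled run.
#' @param z_levels z-coordinates of the planes (m).
#' @param params a [boundary_params()]; defaults to the one carried by the
#'   series.
#' @return data.frame with columns `t_hours`, `c_csf` and one `g_` column per
#'   level (mol/m^3).
#' @export
plane_boundary_trace <- function(series, z_levels = c(-0.1, 0, 0.1),
                                 params = series$boundary) {
  if (is.null(series$c_csf_trace))
    stop("series was run with fixed Dirichlet data; no SAS trace available")
  t <- series$step_times
  out <- data.frame(t_hours = t / 3600, c_csf = series$c_csf_trace)
  nm <- c("g_fm", "g_sf", "g_ps")
  for (i in seq_along(z_levels)) {
    cn <- if (i <= 3L && length(z_levels) == 3L) nm[i] else paste0("g_z", i)
    out[[cn]] <- series$c_csf_trace * spatial_profile_h(t, z_levels[i], params)
  }
  out
}

#' Quantities of interest for one realization
#'
#' Evaluates the full QoI set of a solved realization: gray/white tracer
#' amounts `Q_g`, `Q_w` (mol) and subregion mean concentrations `q_g`, `q_w`
#' (mol/m^3) at the checkpoint times (default 3, 5, 8, 24 h), the white
#' matter activation time `F_w` (first time the white-matter amount exceeds
#' `X n0`, default X = 10%) and the white subregion activation time `f_w`
#' (first time the subregion mean concentration exceeds `Y`, default
#' 1e-3 mol/m^3), both censored at the horizon if never exceeded.
#'
#' @param series a `concentration_series`.
#' @param mesh the mesh.
#' @param subregions list with region masks `S_g` and `S_w` (see
#'   [default_subregions()]).
#' @param checkpoints times in s at which amounts/concentrations are reported.
#' @param X white-matter activation fraction threshold.
#' @param Y subregion activation concentration threshold (mol/m^3).
#' @return object of class `qoi_sample`: a list with `Q_g`, `Q_w`, `q_g`,
#'   `q_w` (named vectors over checkpoints), `F_w`, `f_w` (crossing lists)
#'   and `index`.
#' @export
compute_qoi <- function(series, mesh, subregions,
                        checkpoints = c(3, 5, 8, 24) * 3600,
                        X = 0.1, Y = 1e-3) {
  stopifnot(all(checkpoints %in% series$times))
  gray <- compartment_mask(mesh, "gray")
  white <- compartment_mask(mesh, "white")
  ks <- match(checkpoints, series$times)
  nm <- paste0(checkpoints / 3600, "h")
  Qg <- Qw <- qg <- qw <- stats::setNames(numeric(length(ks)), nm)
  for (i in seq_along(ks)) {
    cn <- series$nodal_c[, ks[i]]
    Qg[i] <- amount_in_region(cn, mesh, gray)
    Qw[i] <- amount_in_region(cn, mesh, white)
    qg[i] <- mean_concentration_in_region(cn, mesh, subregions$S_g)
    qw[i] <- mean_concentration_in_region(cn, mesh, subregions$S_w)
  }
  Fw <- activation_time(series, mesh, white, "fraction_of_n0", X)
  fw <- activation_time(series, mesh, subregions$S_w, "mean_conc", Y)
  structure(list(Q_g = Qg, Q_w = Qw, q_g = qg, q_w = qw,
                 F_w = Fw, f_w = fw,
                 index = series$coeffs_meta$index),
            class = "qoi_sample")
}

#' Flatten QoI samples to a table
#'
#' One row per realization: amounts and concentrations at every checkpoint,
#' activation times in hours and their censoring flags.
#'
#' @param qois list of `qoi_sample` objects.
#' @return data.frame.
#' @export
qoi_table <- function(qois) {
  rows <- lapply(qois, function(q) {
    v <- c(stats::setNames(q$Q_g, paste0("Q_g_", names(q$Q_g))),
           stats::setNames(q$Q_w, paste0("Q_w_", names(q$Q_w))),
           stats::setNames(q$q_g, paste0("q_g_", names(q$q_g))),
           stats::setNames(q$q_w, paste0("q_w_", names(q$q_w))))
    data.frame(omega = q$index, t(v),
               F_w_hours = q$F_w$time / 3600, F_w_censored = q$F_w$censored,
               f_w_hours = q$f_w$time / 3600, f_w_censored = q$f_w$censored)
  })
  do.call(rbind, rows)
}
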