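# Monte Carlo orchestration over the five stochastic model variants and the
# statistical summaries: sample means with standard errors, 99.73% empirical
# prediction intervals, histogram/KDE density estimates, CDFs with censored
# mass, and the sample-size error criterion 3 (V/N)^(1/2) < 0.01 Q.

#' Specify a stochastic model variant
#'
#' Encodes the coefficient structure of the five model variants:
#' D1 (random-variable diffusivity, v = 0, r = 0), D2 (random-field
#' diffusivity, v = 0, r = 0), V1 (constant diffusivity, glymphatic
#' circulation velocity, r = 0), V2 (V1 plus directional field, r = 0) and
#' V3 (constant diffusivity, radial inflow, r > 0).
#'
#' @param model one of `"D1"`, `"D2"`, `"V1"`, `"V2"`, `"V3"`.
#' @param N number of Monte Carlo samples.
#' @param base_seed integer base seed; per-sample seeds are derived with
#'   [derive_seed()].
#' @param diffusion a [diffusion_spec()] (for D1/D2; for velocity models the
#'   diffusivity is the constant `diffusion$D_Gad`).
#' @param velocity a [velocity_spec()] (velocity models only).
#' @param boundary a [boundary_params()].
#' @param dt,t_end,output_times solver controls, see [transport_problem()].
#' @param checkpoints QoI checkpoint times in s.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = c("D1", "D2", "V1", "V2", "V3"),
                       N = 64L, base_seed = 1L,
                       diffusion = diffusion_spec(if (model %in% c("D1", "D2")) model else "D1"),
                       velocity = if (model %in% c("V1", "V2", "V3")) velocity_spec(model) else NULL,
                       boundary = boundary_params(),
                       dt = 900, t_end = 86400,
                       output_times = seq(0, t_end, by = 3600),
                       checkpoints = c(3, 5, 8, 24) * 3600) {
  model <- match.arg(model)
  stopifnot(N >= 1L)
  if (model %in% c("V1", "V2", "V3") &&
      (is.null(velocity) || velocity$model != model))
    stop("velocity spec must match the model variant")
  structure(list(model = model, N = as.integer(N),
                 base_seed = as.integer(base_seed),
                 diffusion = diffusion, velocity = velocity,
                 boundary = boundary, dt = dt, t_end = t_end,
                 output_times = output_times, checkpoints = checkpoints),
            class = "model_spec")
}

# one coefficient realization with the variant-specific coefficient structure
.sample_coefficients <- function(spec, mesh, omega, matern = NULL) {
  s <- derive_seed(spec$base_seed, omega)
  switch(spec$model,
    D1 = coefficient_sample(sample_diffusion_D1(spec$diffusion, 1L, s),
                            velocity = NULL, drainage_r = 0,
                            seed = s, index = omega),
    D2 = coefficient_sample(sample_diffusion_D2(spec$diffusion, mesh, 1L, s,
                                                matern = matern)[[1L]],
                            velocity = NULL, drainage_r = 0,
                            seed = s, index = omega),
    V1 = coefficient_sample(spec$diffusion$D_Gad,
                            velocity = sample_velocity_V1(spec$velocity, matern,
                                                          mesh, 1L, s)[[1L]],
                            drainage_r = 0, seed = s, index = omega),
    V2 = coefficient_sample(spec$diffusion$D_Gad,
                            velocity = sample_velocity_V2(spec$velocity, matern,
                                                          mesh, 1L, s)[[1L]],
                            drainage_r = 0, seed = s, index = omega),
    V3 = {
      vs <- sample_velocity_V3(spec$velocity, mesh, 1L, s)[[1L]]
      coefficient_sample(spec$diffusion$D_Gad, velocity = vs$velocity,
                         drainage_r = vs$drainage_r, seed = s, index = omega)
    })
}

#' Run the Monte Carlo pipeline for one model variant
#'
#' For each of the N realizations: draw the stochastic coefficients with a
#' deterministically derived per-sample seed, solve the transport problem,
#' and evaluate the quantities of interest; then summarize. Identical
#' `base_seed` gives bit-identical QoI tables, independent of execution
#' order.
#'
#' @param spec a [model_spec()].
#' @param mesh a [labeled_mesh()] (default: the synthetic brain geometry).
#' @param subregions gray/white subregion masks (default
#'   [default_subregions()]).
#' @param matern optional [matern_spec()] for field-based models (built
#'   automatically when needed; for V1/V2 an uncalibrated velocity spec is
#'   calibrated once with seed `derive_seed(base_seed, 0)` and recorded).
#' @param on_error `"abort"` (default) or `"skip"`: failed samples abort the
#'   run or are recorded and skipped.
#' @param progress print per-sample progress.
#' @return list of class `mc_run` with `qois` (list of `qoi_sample`),
#'   `table` (data.frame, one row per realization), `summary` (see
#'   [summarize_mc()]), and `metadata`.
#' @export
run_monte_carlo <- function(spec, mesh = build_synthetic_brain(),
                            subregions = default_subregions(mesh),
                            matern = NULL, on_error = c("abort", "skip"),
                            progress = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  on_error <- match.arg(on_error)
  calibration <- NULL
  if (spec$model == "D2" && is.null(matern))
    matern <- .mesh_matern_spec(mesh, spec$diffusion$correlation_length)
  if (spec$model %in% c("V1", "V2")) {
    if (is.null(matern))
      matern <- .mesh_matern_spec(mesh, spec$velocity$lambda_v,
                                  spacing = spec$velocity$lambda_v / 3)
    if (is.null(spec$velocity$eta)) {
      spec$velocity <- calibrate_eta(spec$velocity, matern,
                                     seed = derive_seed(spec$base_seed, 0L),
                                     points = mesh$vertices)
      calibration <- attr(spec$velocity, "calibration")
    }
  }
  if (spec$model == "V3" && is.null(spec$velocity$inflow_scale))
    spec$velocity <- calibrate_inflow_scale(spec$velocity, mesh)

  qois <- vector("list", spec$N)
  failures <- list()
  for (omega in seq_len(spec$N)) {
    res <- tryCatch({
      co <- .sample_coefficients(spec, mesh, omega, matern)
      pr <- transport_problem(mesh, co, boundary = spec$boundary,
                              dt = spec$dt, t_end = spec$t_end,
                              output_times = spec$output_times)
      ser <- solve_transport(pr)
      compute_qoi(ser, mesh, subregions, checkpoints = spec$checkpoints)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort")
        stop("sample ", omega, " failed: ", conditionMessage(res))
      failures[[length(failures) + 1L]] <- list(omega = omega,
                                                message = conditionMessage(res))
    } else qois[[omega]] <- res
    if (progress) message(sprintf("sample %d/%d done", omega, spec$N))
  }
  qois <- Filter(Negate(is.null), qois)
  tab <- qoi_table(qois)
  structure(list(qois = qois, table = tab,
                 summary = summarize_mc(tab, N = length(qois)),
                 metadata = list(model = spec$model, N = spec$N,
                                 base_seed = spec$base_seed,
                                 dt = spec$dt, t_end = spec$t_end,
                                 diffusivity = if (spec$model %in% c("D1", "D2"))
                                   "stochastic" else spec$diffusion$D_Gad,
                                 drainage_r = if (spec$model == "V3")
                                   spec$velocity$drainage_r else 0,
                                 calibration = calibration,
                                 failures = failures)),
            class = "mc_run")
}

#' Monte Carlo mean and standard error
#'
#' @param samples numeric vector of QoI samples.
#' @return list with `mean` and `se` (`(V/N)^(1/2)`).
#' @export
estimate_expectation <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("at least 2 samples are required")
  list(mean = mean(samples), se = sqrt(stats::var(samples) / n))
}

#' Empirical prediction interval
#'
#' Central empirical quantile interval: with the default 99.73% coverage,
#' 0.135% of the samples lie above and 0.135% below (the +-3 sigma analogue
#' for Gaussian samples).
#'
#' @param samples numeric vector.
#' @param coverage interval coverage in (0, 1).
#' @return numeric `c(lo, hi)`.
#' @export
prediction_interval <- function(samples, coverage = 0.9973) {
  if (length(samples) < 2L) stop("at least 2 samples are required")
  alpha <- (1 - coverage) / 2
  stats::setNames(as.numeric(stats::quantile(samples, c(alpha, 1 - alpha),
                                             names = FALSE, type = 7)),
                  c("lo", "hi"))
}

#' Monte Carlo sample-size error criterion
#'
#' TRUE iff `3 (V/N)^(1/2) < 0.01 |Q|` for the sample variance V, sample
#' size N and sample mean Q, i.e. the 3-sigma statistical error of the mean
#' is below 1% of the estimate.
#'
#' @param samples numeric vector (N >= 2, nonzero mean).
#' @return logical.
#' @export
check_error_criterion <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("at least 2 samples are required")
  Q <- mean(samples)
  if (Q == 0) stop("error criterion undefined for zero sample mean")
  V <- stats::var(samples)
  3 * sqrt(V / n) < 0.01 * abs(Q)
}

#' Density and CDF estimates with censored mass
#'
#' Histogram (Freedman-Diaconis bins) and kernel density (Scott-type
#' bandwidth) over the uncensored samples, scaled so the density integrates
#' to the uncensored fraction; empirical CDF scaled so its supremum equals
#' the uncensored fraction (censored realizations never cross the threshold,
#' so the CDF caps below 1).
#'
#' @param values numeric samples (crossing times or any QoI).
#' @param censored logical vector (default none censored).
#' @return list with `density` (data.frame x, y), `cdf` (data.frame x, p),
#'   `breaks` (histogram breaks), `counts`, and `censored_fraction`.
#' @export
estimate_pdf_cdf <- function(values, censored = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(censored))
  unc <- values[!censored]
  if (!length(unc)) stop("all samples are censored")
  frac <- length(unc) / length(values)
  h <- if (length(unc) > 1L && stats::sd(unc) > 0)
    graphics::hist(unc, breaks = "FD", plot = FALSE)
  else list(breaks = range(unc) + c(-0.5, 0.5), counts = length(unc))
  dens <- if (length(unc) > 1L && stats::sd(unc) > 0) {
    d <- stats::density(unc, bw = stats::bw.nrd(unc))
    data.frame(x = d$x, y = d$y * frac)
  } else data.frame(x = unc[1L], y = Inf)
  xs <- sort(unc)
  cdf <- data.frame(x = xs, p = seq_along(xs) / length(values))
  list(density = dens, cdf = cdf, breaks = h$breaks, counts = h$counts,
       censored_fraction = 1 - frac)
}

#' Summarize a Monte Carlo QoI table
#'
#' Per numeric QoI column: sample mean, standard error, 99.73% prediction
#' interval and the sample-size error criterion. Activation-time columns are
#' summarized over uncensored samples only, with the censored fraction
#' reported.
#'
#' @param table data.frame from [qoi_table()].
#' @param N total sample count (for censored fractions).
#' @return data.frame, one row per QoI.
#' @export
summarize_mc <- function(table, N = nrow(table)) {
  cols <- setdiff(names(table),
                  c("omega", "F_w_censored", "f_w_censored"))
  rows <- lapply(cols, function(cn) {
    x <- table[[cn]]
    cens_frac <- 0
    if (cn == "F_w_hours") {
      keep <- !table$F_w_censored
      cens_frac <- 1 - mean(keep); x <- x[keep]
    } else if (cn == "f_w_hours") {
      keep <- !table$f_w_censored
      cens_frac <- 1 - mean(keep); x <- x[keep]
    }
    if (length(x) < 2L)
      return(data.frame(qoi = cn, mean = if (length(x)) mean(x) else NA_real_,
                        se = NA_real_, pi_lo = NA_real_, pi_hi = NA_real_,
                        criterion_met = NA, censored_fraction = cens_frac))
    est <- estimate_expectation(x)
    pi <- prediction_interval(x)
    crit <- if (est$mean != 0) check_error_criterion(x) else NA
    data.frame(qoi = cn, mean = est$mean, se = est$se,
               pi_lo = pi[["lo"]], pi_hi = pi[["hi"]],
               criterion_met = crit, censored_fraction = cens_frac)
  })
  do.call(rbind, rows)
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("mc_run: model %s, N = %d (base seed %d)\n",
              x$metadata$model, nrow(x$table), x$metadata$base_seed))
  print(x$summary, digits = 4)
  invisible(x)
}
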