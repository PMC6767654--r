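# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# coarse synthetic brain (fast: ~1.5k vertices)
tiny_brain <- function() fixture("tiny_brain", function()
  build_synthetic_brain(target_edge_length = 0.03, surface_refinement = 0.006))

# default-resolution synthetic brain (the study geometry)
study_brain <- function() fixture("study_brain", function()
  build_synthetic_brain())

# medium resolution with the default surface refinement (velocity runs)
medium_brain <- function() fixture("medium_brain", function()
  build_synthetic_brain(target_edge_length = 0.015, surface_refinement = 0.002))

# small resolved Matern box for velocity-field tests: 10 correlation lengths
velocity_box_matern <- function() fixture("velocity_box_matern", function() {
  lam <- 1020e-6
  matern_spec(lam, c(0, 0, 0), rep(10 * lam, 3), lam / 3)
})

# box mesh inside the velocity box, head-scale coordinates
velocity_box_mesh <- function() fixture("velocity_box_mesh", function() {
  lam <- 1020e-6
  build_box_mesh(rep(0.5 * lam, 3), rep(9.5 * lam, 3), n = 6)
})

# calibrated V1 spec on that box (shared between velocity and acceptance
# tests); calibration evaluates the field at the mesh vertices it will be
# validated on
calibrated_v1 <- function() fixture("calibrated_v1", function()
  calibrate_eta(velocity_spec("V1"), velocity_box_matern(),
                n_samples = 400L, seed = 101L,
                points = velocity_box_mesh()$vertices))

# RMS magnitude of fresh V1 samples after calibration (expensive; shared)
v1_validation_rms <- function() fixture("v1_validation_rms", function() {
  v <- sample_velocity_V1(calibrated_v1(), velocity_box_matern(),
                          velocity_box_mesh(), n = 600L, seed = 2024L)
  msq <- vapply(v, function(m) mean(rowSums(m^2)), numeric(1))
  sqrt(mean(msq))
})

# uniform-in-tet sample points (independent quadrature oracle)
sample_points_in_tet <- function(p, n, seed) {
  glymphuq:::with_seed(seed, {
    w <- matrix(stats::rexp(4L * n), n, 4L)
    w <- w / rowSums(w)
    w %*% p
  })
}
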