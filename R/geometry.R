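# Labeled tetrahedral meshes: synthetic brain-like geometry, box meshes,
# subregion masks and the low-level mesh predicates used by the solver.
#
# Conventions (SI units, metres):
#   cell labels:  "gray" = 1, "white" = 2   (integer codes in cell data "subdomain")
#   facet labels: "SAS" = 1, "ventricle" = 2 (integer codes in facet data "boundary")
#   z = 0 passes through the ventricular cavity center (lateral-ventricle level).

.GRAY <- 1L
.WHITE <- 2L
.SAS <- 1L
.VENT <- 2L

.cell_label_names <- c("gray", "white")
.facet_label_names <- c("SAS", "ventricle")

#' Construct a labeled tetrahedral mesh
#'
#' Builds the central mesh container used throughout the package: vertices,
#' tetrahedra, a gray/white label per cell, and a SAS/ventricle label per
#' boundary facet. Tetrahedra are re-oriented to positive volume. Boundary
#' facets are derived from the cell connectivity; the supplied `facets` and
#' `facet_label` are matched against them, and every boundary facet must
#' receive exactly one label.
#'
#' @param vertices numeric matrix (n x 3), coordinates in metres.
#' @param cells integer matrix (m x 4), 1-based vertex indices.
#' @param cell_label integer (1 = gray, 2 = white) or character vector
#'   (`"gray"`/`"white"`) of length m.
#' @param facets integer matrix (f x 3) of boundary triangles.
#' @param facet_label integer (1 = SAS, 2 = ventricle) or character vector
#'   (`"SAS"`/`"ventricle"`) of length f.
#' @param validate run [validate_labeled_mesh()] before returning.
#' @param check_extent passed on to the validator.
#' @return an object of class `labeled_mesh` with elements `vertices`, `cells`,
#'   `cell_label`, `facets`, `facet_label`, `facet_cell` (owner cell of each
#'   boundary facet).
#' @export
labeled_mesh <- function(vertices, cells, cell_label, facets, facet_label,
                         validate = TRUE, check_extent = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  dimnames(cells) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(cells) != 4L) stop("cells must be an m x 4 matrix")
  cell_label <- .coerce_labels(cell_label, .cell_label_names, nrow(cells))
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  dimnames(facets) <- NULL
  facet_label <- .coerce_labels(facet_label, .facet_label_names, nrow(facets))

  # orient cells to positive volume
  vol <- .signed_cell_volumes(vertices, cells)
  flip <- which(vol < 0)
  if (length(flip)) {
    tmp <- cells[flip, 3L]
    cells[flip, 3L] <- cells[flip, 4L]
    cells[flip, 4L] <- tmp
  }

  bnd <- .boundary_faces(cells)
  key_b <- .face_key(bnd$faces, nrow(vertices))
  key_f <- .face_key(facets, nrow(vertices))
  pos <- match(key_b, key_f)
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    stop(sprintf("boundary facet (%d, %d, %d) carries no label",
                 bnd$faces[i, 1L], bnd$faces[i, 2L], bnd$faces[i, 3L]))
  }
  if (anyDuplicated(key_f)) stop("duplicate facet definitions supplied")
  extra <- !(key_f %in% key_b)
  if (any(extra)) {
    i <- which(extra)[1L]
    stop(sprintf("facet (%d, %d, %d) is labeled but is not a boundary facet",
                 facets[i, 1L], facets[i, 2L], facets[i, 3L]))
  }

  mesh <- structure(
    list(vertices = vertices,
         cells = cells,
         cell_label = cell_label,
         facets = bnd$faces,
         facet_label = facet_label[pos],
         facet_cell = bnd$owner),
    class = "labeled_mesh")
  if (validate) validate_labeled_mesh(mesh, check_extent = check_extent)
  mesh
}

.coerce_labels <- function(x, names, n) {
  if (is.character(x)) x <- match(x, names)
  x <- as.integer(x)
  if (length(x) != n || anyNA(x) || any(x < 1L | x > length(names)))
    stop("invalid labels: expected one of ", paste(names, collapse = "/"),
         " for each of ", n, " entities")
  x
}

.signed_cell_volumes <- function(vertices, cells) {
  p1 <- vertices[cells[, 1L], , drop = FALSE]
  a <- vertices[cells[, 2L], , drop = FALSE] - p1
  b <- vertices[cells[, 3L], , drop = FALSE] - p1
  c3 <- vertices[cells[, 4L], , drop = FALSE] - p1
  det <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
         a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
         a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  det / 6
}

# all boundary faces of a tet mesh, with owning cell; errors on non-conforming
# faces (shared by > 2 cells)
.boundary_faces <- function(cells) {
  m <- nrow(cells)
  faces <- rbind(cells[, c(2L, 3L, 4L), drop = FALSE],
                 cells[, c(1L, 3L, 4L), drop = FALSE],
                 cells[, c(1L, 2L, 4L), drop = FALSE],
                 cells[, c(1L, 2L, 3L), drop = FALSE])
  owner <- rep.int(seq_len(m), 4L)
  a <- faces[, 1L]; b <- faces[, 2L]; c3 <- faces[, 3L]
  lo <- pmin(a, b, c3); hi <- pmax(a, b, c3); mid <- a + b + c3 - lo - hi
  ord <- order(lo, mid, hi)
  lo <- lo[ord]; mid <- mid[ord]; hi <- hi[ord]
  same_next <- c(lo[-1L] == lo[-length(lo)] &
                 mid[-1L] == mid[-length(mid)] &
                 hi[-1L] == hi[-length(hi)], FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  if (any(same_next & same_prev))
    stop("non-conforming mesh: a facet is shared by more than 2 cells")
  is_bnd <- !(same_next | same_prev)
  idx <- ord[is_bnd]
  list(faces = cbind(lo[is_bnd], mid[is_bnd], hi[is_bnd]), owner = owner[idx])
}

.face_key <- function(faces, nv) {
  a <- faces[, 1L]; b <- faces[, 2L]; c3 <- faces[, 3L]
  lo <- pmin(a, b, c3); hi <- pmax(a, b, c3); mid <- a + b + c3 - lo - hi
  paste(lo, mid, hi, sep = ".")
}

#' Validate labeled-mesh invariants
#'
#' Checks that the mesh is conforming (every interior facet shared by exactly
#' two cells), that all cell volumes are positive, that gray and white cells
#' both exist, that every boundary facet carries exactly one label, and
#' (optionally) that the domain fits inside a 0.16 x 0.21 x 0.17 m bounding
#' box, the extent of a human head.
#'
#' @param mesh a [labeled_mesh()].
#' @param check_extent enforce the head-scale bounding-box limit.
#' @return `mesh`, invisibly; errors on any violation.
#' @export
validate_labeled_mesh <- function(mesh, check_extent = TRUE) {
  v <- mesh$vertices; cl <- mesh$cells
  if (max(cl) > nrow(v) || min(cl) < 1L) stop("cell vertex index out of range")
  vol <- .signed_cell_volumes(v, cl)
  if (any(vol <= 0)) stop("degenerate cell: non-positive volume")
  if (!all(c(.GRAY, .WHITE) %in% mesh$cell_label))
    stop("gray and white compartments must both be non-empty")
  bnd <- .boundary_faces(cl)  # errors if non-conforming
  if (nrow(bnd$faces) != nrow(mesh$facets))
    stop("boundary facet set does not match labeled facets")
  if (!all(mesh$facet_label %in% c(.SAS, .VENT)))
    stop("facet labels must be SAS or ventricle")
  if (check_extent) {
    ext <- apply(v, 2L, function(x) diff(range(x)))
    lim <- c(0.16, 0.21, 0.17)
    if (any(ext > lim + 1e-9))
      stop(sprintf(
        "domain extent %.3f x %.3f x %.3f m exceeds the 0.16 x 0.21 x 0.17 m head-scale bounding box",
        ext[1L], ext[2L], ext[3L]))
  }
  invisible(mesh)
}

#' Cell volumes of a tetrahedral mesh
#' @param mesh a [labeled_mesh()].
#' @return numeric vector of cell volumes in m^3.
#' @export
cell_volumes <- function(mesh) {
  abs(.signed_cell_volumes(mesh$vertices, mesh$cells))
}

#' Cell centroids
#' @param mesh a [labeled_mesh()].
#' @return m x 3 matrix of centroid coordinates.
#' @export
cell_centroids <- function(mesh) {
  (mesh$vertices[mesh$cells[, 1L], , drop = FALSE] +
   mesh$vertices[mesh$cells[, 2L], , drop = FALSE] +
   mesh$vertices[mesh$cells[, 3L], , drop = FALSE] +
   mesh$vertices[mesh$cells[, 4L], , drop = FALSE]) / 4
}

#' Areas of the boundary facets
#' @param mesh a [labeled_mesh()].
#' @return numeric vector of facet areas in m^2.
#' @export
facet_areas <- function(mesh) {
  p1 <- mesh$vertices[mesh$facets[, 1L], , drop = FALSE]
  e1 <- mesh$vertices[mesh$facets[, 2L], , drop = FALSE] - p1
  e2 <- mesh$vertices[mesh$facets[, 3L], , drop = FALSE] - p1
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# outward unit normals of boundary facets (oriented away from the owner cell)
.facet_normals <- function(mesh) {
  p1 <- mesh$vertices[mesh$facets[, 1L], , drop = FALSE]
  e1 <- mesh$vertices[mesh$facets[, 2L], , drop = FALSE] - p1
  e2 <- mesh$vertices[mesh$facets[, 3L], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / len
  fc <- (p1 + mesh$vertices[mesh$facets[, 2L], , drop = FALSE] +
         mesh$vertices[mesh$facets[, 3L], , drop = FALSE]) / 3
  cc <- cell_centroids(mesh)[mesh$facet_cell, , drop = FALSE]
  inward <- rowSums(nrm * (fc - cc)) < 0
  nrm[inward, ] <- -nrm[inward, ]
  nrm
}

#' @export
print.labeled_mesh <- function(x, ...) {
  vol <- cell_volumes(x)
  cat(sprintf("labeled_mesh: %d vertices, %d cells (%d gray, %d white), %d boundary facets (%d SAS, %d ventricle)\n",
              nrow(x$vertices), nrow(x$cells),
              sum(x$cell_label == .GRAY), sum(x$cell_label == .WHITE),
              nrow(x$facets), sum(x$facet_label == .SAS),
              sum(x$facet_label == .VENT)))
  cat(sprintf("  total volume %.4g m^3; bounding box %.3f x %.3f x %.3f m\n",
              sum(vol),
              diff(range(x$vertices[, 1L])), diff(range(x$vertices[, 2L])),
              diff(range(x$vertices[, 3L]))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Synthetic brain-like geometry: concentric-ellipsoid gray shell around a
# white core, with a central spherical ventricular cavity.  The triangulated
# directions come from a subdivided octahedron; radial layers interpolate
# between the cavity sphere, the gray/white interface ellipsoid and the
# outer (SAS) ellipsoid, and each triangular prism between layers is split
# into three tetrahedra with globally consistent diagonals.
# ---------------------------------------------------------------------------

.octasphere <- function(level) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1L, 3L, 5L), c(3L, 2L, 5L), c(2L, 4L, 5L), c(4L, 1L, 5L),
             c(3L, 1L, 6L), c(2L, 3L, 6L), c(4L, 2L, 6L), c(1L, 4L, 6L))
  for (l in seq_len(level)) {
    env <- new.env(hash = TRUE, size = 4L * nrow(f))
    nv <- nrow(v)
    extra <- list()
    midpoint <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      id <- env[[key]]
      if (is.null(id)) {
        p <- v[i, ] + v[j, ]
        p <- p / sqrt(sum(p^2))
        extra[[length(extra) + 1L]] <<- p
        id <- nv + length(extra)
        env[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c3 <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4L * k - 3L, ] <- c(a, ab, ca)
      nf[4L * k - 2L, ] <- c(b, bc, ab)
      nf[4L * k - 1L, ] <- c(c3, ca, bc)
      nf[4L * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- nf
  }
  list(vertices = v, faces = f)
}

# split the prism stack over a sorted surface triangle into tets; diagonals
# are chosen by global vertex order so adjacent prisms share quad diagonals
.prism_tets <- function(faces_sorted, lower_offset, upper_offset) {
  b0 <- faces_sorted[, 1L] + lower_offset
  b1 <- faces_sorted[, 2L] + lower_offset
  b2 <- faces_sorted[, 3L] + lower_offset
  t0 <- faces_sorted[, 1L] + upper_offset
  t1 <- faces_sorted[, 2L] + upper_offset
  t2 <- faces_sorted[, 3L] + upper_offset
  rbind(cbind(b0, b1, b2, t0),
        cbind(b1, b2, t0, t1),
        cbind(b2, t0, t1, t2))
}

#' Generate the synthetic brain-like labeled mesh
#'
#' Stand-in for a labeled brain atlas mesh: a gray-matter ellipsoidal shell of
#' thickness `gray_thickness` around a white-matter core, with a central
#' spherical ventricular cavity of radius `ventricle_radius`. The outer
#' surface is labeled SAS, the cavity surface ventricle. The cavity center is
#' at the origin, so z = 0 is the lateral-ventricle level (z of about -0.1
#' corresponds to the foramen magnum and +0.1 to the precentral sulcus for
#' head-sized axes). The generator is deterministic given its arguments.
#'
#' @param outer_semi_axes semi-axes (a, b, c) of the outer ellipsoid in m.
#' @param gray_thickness thickness of the gray shell in m (measured along each
#'   semi-axis).
#' @param ventricle_radius radius of the central spherical cavity in m; must
#'   lie strictly inside the white core.
#' @param target_edge_length requested mesh edge length in m.
#' @param surface_refinement radial thickness of the outermost gray layer in
#'   m. Radial layers in the gray shell are graded geometrically (ratio
#'   `grading_ratio`) toward the SAS surface, mirroring the near-surface
#'   refinement of atlas FEM meshes; adequate surface resolution is also what
#'   keeps the explicit SAS concentration coupling stable, since the
#'   tracer-holding capacity of the first cell layer must stay well below the
#'   CSF volume.
#' @param grading_ratio geometric growth factor of the radial gray layers
#'   (from the SAS surface inward).
#' @return a [labeled_mesh()]; generator parameters are stored in
#'   `attr(mesh, "provenance")`.
#' @examples
#' mesh <- build_synthetic_brain(target_edge_length = 0.02)
#' mesh
#' @export
build_synthetic_brain <- function(outer_semi_axes = c(0.07, 0.09, 0.08),
                                  gray_thickness = 0.02,
                                  ventricle_radius = 0.02,
                                  target_edge_length = 0.01,
                                  surface_refinement = 0.002,
                                  grading_ratio = 1.5) {
  ax <- as.numeric(outer_semi_axes)
  if (length(ax) != 3L || any(ax <= 0)) stop("outer_semi_axes must be 3 positive lengths")
  if (gray_thickness <= 0 || gray_thickness >= min(ax))
    stop("infeasible geometry: gray_thickness must be positive and smaller than the smallest semi-axis")
  inner <- ax - gray_thickness
  if (ventricle_radius <= 0 || ventricle_radius >= min(inner))
    stop("infeasible geometry: ventricular cavity must lie strictly inside the white compartment")
  h <- target_edge_length
  if (h <= 0) stop("target_edge_length must be positive")

  level <- max(1L, min(6L, ceiling(log2((pi / 2) * mean(ax) / h))))
  sph <- .octasphere(level)
  dirs <- sph$vertices
  faces <- sph$faces
  # sort face vertices ascending for the consistent prism split
  fs <- t(apply(faces, 1L, sort))
  ns <- nrow(dirs)

  n_w <- max(2L, round((mean(inner) - ventricle_radius) / h))

  # graded radial spacings in the gray shell, thinnest at the SAS surface
  d <- min(surface_refinement, h)
  sp <- numeric(0)
  while (sum(sp) < gray_thickness) {
    sp <- c(sp, d)
    d <- min(h, d * grading_ratio)
  }
  sp <- sp * gray_thickness / sum(sp)
  s_gray <- cumsum(rev(sp)) / gray_thickness  # inner interface -> outer surface
  n_g <- length(s_gray)

  p_vent <- ventricle_radius * dirs
  p_inner <- sweep(dirs, 2L, inner, `*`)
  p_outer <- sweep(dirs, 2L, ax, `*`)

  layers <- vector("list", n_w + n_g + 1L)
  for (l in 0:n_w) {
    s <- l / n_w
    layers[[l + 1L]] <- (1 - s) * p_vent + s * p_inner
  }
  for (l in seq_len(n_g)) {
    s <- s_gray[l]
    layers[[n_w + 1L + l]] <- (1 - s) * p_inner + s * p_outer
  }
  vertices <- do.call(rbind, layers)

  n_band <- n_w + n_g
  cells <- vector("list", n_band)
  labels <- vector("list", n_band)
  for (l in seq_len(n_band)) {
    tet <- .prism_tets(fs, (l - 1L) * ns, l * ns)
    cells[[l]] <- tet
    labels[[l]] <- rep.int(if (l <= n_w) .WHITE else .GRAY, nrow(tet))
  }
  cells <- do.call(rbind, cells)
  cell_label <- unlist(labels)

  facets <- rbind(fs, fs + n_band * ns)
  facet_label <- rep.int(c(.VENT, .SAS), c(nrow(fs), nrow(fs)))

  mesh <- labeled_mesh(vertices, cells, cell_label, facets, facet_label,
                       validate = FALSE)
  attr(mesh, "provenance") <- list(generator = "build_synthetic_brain",
                                   outer_semi_axes = ax,
                                   gray_thickness = gray_thickness,
                                   ventricle_radius = ventricle_radius,
                                   target_edge_length = h,
                                   subdivision_level = level,
                                   n_white_layers = n_w, n_gray_layers = n_g)
  mesh
}

#' Structured box mesh (verification geometry)
#'
#' Regular tetrahedral mesh of an axis-aligned box, used for solver
#' verification (manufactured/analytic solutions) and quadrature tests. Each
#' grid hexahedron is split into six tetrahedra. Cells are labeled gray above
#' the box midplane of `split_axis` and white below, so both compartments are
#' non-empty; facet labels are assigned per box face.
#'
#' @param lower,upper box corners (length-3 numeric).
#' @param n number of cells per axis (length 1 or 3).
#' @param sas_faces character vector of box faces carrying the SAS label, from
#'   `c("xmin","xmax","ymin","ymax","zmin","zmax")`; remaining faces are
#'   labeled ventricle (zero diffusive flux).
#' @param split_axis axis (1, 2 or 3) used for the gray/white split.
#' @param check_extent enforce the head-scale bounding box (disable for
#'   unit-scale verification boxes).
#' @return a [labeled_mesh()].
#' @export
build_box_mesh <- function(lower = c(0, 0, 0), upper = c(1, 1, 1), n = 4L,
                           sas_faces = c("xmin", "xmax", "ymin", "ymax",
                                         "zmin", "zmax"),
                           split_axis = 3L, check_extent = FALSE) {
  n <- rep_len(as.integer(n), 3L)
  if (any(n < 1L)) stop("n must be >= 1")
  xs <- seq(lower[1L], upper[1L], length.out = n[1L] + 1L)
  ys <- seq(lower[2L], upper[2L], length.out = n[2L] + 1L)
  zs <- seq(lower[3L], upper[3L], length.out = n[3L] + 1L)
  nx <- n[1L] + 1L; ny <- n[2L] + 1L; nz <- n[3L] + 1L
  vertices <- cbind(rep(xs, times = ny * nz),
                    rep(rep(ys, each = nx), times = nz),
                    rep(zs, each = nx * ny))
  vid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ii <- rep(seq_len(n[1L]), times = n[2L] * n[3L])
  jj <- rep(rep(seq_len(n[2L]), each = n[1L]), times = n[3L])
  kk <- rep(seq_len(n[3L]), each = n[1L] * n[2L])
  v000 <- vid(ii, jj, kk);         v100 <- vid(ii + 1L, jj, kk)
  v010 <- vid(ii, jj + 1L, kk);    v110 <- vid(ii + 1L, jj + 1L, kk)
  v001 <- vid(ii, jj, kk + 1L);    v101 <- vid(ii + 1L, jj, kk + 1L)
  v011 <- vid(ii, jj + 1L, kk + 1L); v111 <- vid(ii + 1L, jj + 1L, kk + 1L)
  # six-tet Kuhn split of each hexahedron (consistent across shared faces)
  cells <- rbind(cbind(v000, v100, v110, v111),
                 cbind(v000, v110, v010, v111),
                 cbind(v000, v010, v011, v111),
                 cbind(v000, v011, v001, v111),
                 cbind(v000, v001, v101, v111),
                 cbind(v000, v101, v100, v111))
  storage.mode(cells) <- "integer"

  mid <- (lower[split_axis] + upper[split_axis]) / 2
  cents <- (vertices[cells[, 1L], split_axis] + vertices[cells[, 2L], split_axis] +
            vertices[cells[, 3L], split_axis] + vertices[cells[, 4L], split_axis]) / 4
  cell_label <- ifelse(cents >= mid, .GRAY, .WHITE)

  bnd <- .boundary_faces(cells)
  fc <- (vertices[bnd$faces[, 1L], , drop = FALSE] +
         vertices[bnd$faces[, 2L], , drop = FALSE] +
         vertices[bnd$faces[, 3L], , drop = FALSE]) / 3
  tol <- 1e-9 * max(abs(upper - lower))
  face_of <- character(nrow(bnd$faces))
  face_of[abs(fc[, 1L] - lower[1L]) < tol] <- "xmin"
  face_of[abs(fc[, 1L] - upper[1L]) < tol] <- "xmax"
  face_of[abs(fc[, 2L] - lower[2L]) < tol] <- "ymin"
  face_of[abs(fc[, 2L] - upper[2L]) < tol] <- "ymax"
  face_of[abs(fc[, 3L] - lower[3L]) < tol] <- "zmin"
  face_of[abs(fc[, 3L] - upper[3L]) < tol] <- "zmax"
  facet_label <- ifelse(face_of %in% sas_faces, .SAS, .VENT)

  labeled_mesh(vertices, cells, cell_label, bnd$faces, facet_label,
               validate = TRUE, check_extent = check_extent)
}

# ---------------------------------------------------------------------------
# Region masks
# ---------------------------------------------------------------------------

#' Define a spherical subregion of the mesh
#'
#' Cell-set mask of all cells whose centroid lies inside the given sphere and
#' (optionally) carries the requested compartment label. Used for the small
#' gray- and white-matter regions of interest over which average tracer
#' concentrations are reported.
#'
#' @param mesh a [labeled_mesh()].
#' @param center sphere center (3-vector, m).
#' @param radius sphere radius (m).
#' @param restrict_to `"gray"`, `"white"` or `"any"`.
#' @return an object of class `region_mask` with `kind`, `members` (cell
#'   indices) and `volume` (m^3).
#' @export
define_spherical_subregion <- function(mesh, center, radius,
                                       restrict_to = c("any", "gray", "white")) {
  restrict_to <- match.arg(restrict_to)
  cent <- cell_centroids(mesh)
  d2 <- (cent[, 1L] - center[1L])^2 + (cent[, 2L] - center[2L])^2 +
        (cent[, 3L] - center[3L])^2
  inside <- d2 <= radius^2
  if (restrict_to == "gray") inside <- inside & mesh$cell_label == .GRAY
  if (restrict_to == "white") inside <- inside & mesh$cell_label == .WHITE
  members <- which(inside)
  if (!length(members))
    stop("empty subregion: the sphere does not intersect the requested compartment")
  region_mask(mesh, members)
}

#' Build a cell-set region mask
#' @param mesh a [labeled_mesh()].
#' @param members integer vector of cell indices.
#' @return a `region_mask` with precomputed volume.
#' @export
region_mask <- function(mesh, members) {
  members <- as.integer(members)
  if (!length(members) || anyNA(members) ||
      min(members) < 1L || max(members) > nrow(mesh$cells))
    stop("invalid cell members for region mask")
  vol <- sum(cell_volumes(mesh)[members])
  structure(list(kind = "cell-set", members = members, volume = vol),
            class = "region_mask")
}

#' Mask of a whole compartment
#' @param mesh a [labeled_mesh()].
#' @param label `"gray"` or `"white"`.
#' @return a `region_mask` of all cells with that label.
#' @export
compartment_mask <- function(mesh, label = c("gray", "white")) {
  label <- match.arg(label)
  region_mask(mesh, which(mesh$cell_label == if (label == "gray") .GRAY else .WHITE))
}

#' Volume of a masked region
#' @param mesh a [labeled_mesh()].
#' @param mask a `region_mask`.
#' @return region volume in m^3.
#' @export
region_volume <- function(mesh, mask) {
  if (!length(mask$members)) stop("empty region mask")
  sum(cell_volumes(mesh)[mask$members])
}

#' Default gray/white subregions for the synthetic geometry
#'
#' The gray region of interest sits 3 mm beneath the SAS surface on the
#' positive x-axis at z = 0; the white region sits mid-way through the white
#' core on the same axis. Both are spheres of radius 4 mm (configurable).
#' Requires a mesh produced by [build_synthetic_brain()] (the generator
#' parameters travel with the mesh).
#'
#' @param mesh a mesh from [build_synthetic_brain()].
#' @param radius subregion radius in m.
#' @return list with elements `S_g` and `S_w` (region masks).
#' @export
default_subregions <- function(mesh, radius = 0.004) {
  prov <- attr(mesh, "provenance")
  if (is.null(prov) || !identical(prov$generator, "build_synthetic_brain"))
    stop("default subregions are defined for synthetic meshes; supply centers explicitly otherwise")
  a <- prov$outer_semi_axes[1L]
  inner <- a - prov$gray_thickness
  sg_center <- c(a - 0.003 - radius / 2, 0, 0)
  sw_center <- c((prov$ventricle_radius + inner) / 2, 0, 0)
  grow <- function(center, restrict) {
    # on coarse meshes the nominal radius may contain no cell centroid; grow
    # it geometrically until the region resolves
    r <- radius
    for (k in 1:8) {
      m <- tryCatch(define_spherical_subregion(mesh, center, r, restrict),
                    error = function(e) NULL)
      if (!is.null(m)) return(m)
      r <- 1.4 * r
    }
    stop("could not resolve a subregion near (",
         paste(signif(center, 3), collapse = ", "), ")")
  }
  list(S_g = grow(sg_center, "gray"), S_w = grow(sw_center, "white"))
}
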