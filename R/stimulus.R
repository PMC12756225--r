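#' Viewing geometry of the stereoscopic display
#'
#' World coordinates (cm): the screen plane is `z = 0` with the aperture
#' centre at the origin, `x` points screen-right, `y` up, and `z` toward the
#' viewer. The cyclopic eye sits at `(0, 0, viewing_distance)`; the left and
#' right eyes are offset horizontally by half the interpupillary distance.
#' Stimulus planes pass through the aperture centre.
#'
#' @param viewing_distance Eye-to-screen distance in cm (default 50; the
#'   alternative 55 cm figure can be set here).
#' @param ipd Interpupillary distance in cm (default 6.4).
#' @param aperture_diameter Circular aperture diameter in degrees of visual
#'   angle (default 35.5).
#' @return A list of class `viewing_geometry`.
#' @examples
#' vg <- viewing_geometry()
#' aperture_radius_cm(vg)
#' @export
viewing_geometry <- function(viewing_distance = 50, ipd = 6.4,
                             aperture_diameter = 35.5) {
  stopifnot_scalar_number(viewing_distance, "viewing_distance")
  stopifnot_scalar_number(ipd, "ipd")
  stopifnot_scalar_number(aperture_diameter, "aperture_diameter")
  abort_if(viewing_distance <= 0 || ipd <= 0 || aperture_diameter <= 0,
           "viewing geometry parameters must be positive.",
           class = "cueweights_config_error")
  structure(list(viewing_distance = viewing_distance, ipd = ipd,
                 aperture_diameter = aperture_diameter),
            class = "viewing_geometry")
}

#' @rdname viewing_geometry
#' @export
aperture_radius_cm <- function(vg) {
  vg$viewing_distance * tan(deg2rad(vg$aperture_diameter / 2))
}

#' Jittered-grid Voronoi texture sites
#'
#' Site points for a Voronoi tessellation texture: a `grid_size` x
#' `grid_size` regular grid of cell centres on the unit square, each centre
#' perturbed by an independent uniform jitter of up to `jitter/2` cell widths
#' per axis. The texture breaks up perspective regularity while keeping cell
#' sizes statistically uniform. Deterministic for a fixed `seed`.
#'
#' @param grid_size Cells per side (>= 2).
#' @param jitter Jitter amplitude as a fraction of the cell size, in `[0, 1]`
#'   (0 = exact regular grid, 1 = sites anywhere within their cell).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A tibble with columns `row`, `col`, `x`, `y` (one site per cell),
#'   carrying `grid_size`, `jitter` and `seed` as attributes.
#' @examples
#' generate_voronoi_sites(4, jitter = 0.5, seed = 1)
#' @export
generate_voronoi_sites <- function(grid_size, jitter = 0.8, seed = NULL) {
  if (!is.numeric(grid_size) || grid_size < 2 || grid_size != round(grid_size)) {
    rlang::abort("`grid_size` must be an integer >= 2.",
                 class = "cueweights_config_error")
  }
  if (!is.numeric(jitter) || length(jitter) != 1L || jitter < 0 || jitter > 1) {
    rlang::abort("`jitter` must be a single number in [0, 1].",
                 class = "cueweights_config_error")
  }
  gs <- as.integer(grid_size)
  cell <- 1 / gs
  idx <- expand.grid(col = seq_len(gs), row = seq_len(gs))
  cx <- (idx$col - 0.5) * cell
  cy <- (idx$row - 0.5) * cell
  off <- with_seed_opt(seed, matrix(runif(2L * gs^2, -jitter / 2, jitter / 2),
                                    ncol = 2L)) * cell
  out <- tibble(row = idx$row, col = idx$col,
                x = cx + off[, 1], y = cy + off[, 2])
  attr(out, "grid_size") <- gs
  attr(out, "jitter") <- jitter
  attr(out, "seed") <- seed
  out
}

as_pose <- function(pose, arg = "pose") {
  if (is.data.frame(pose)) pose <- c(pose$slant[1], pose$tilt[1])
  if (!is.numeric(pose) || length(pose) != 2L) {
    rlang::abort(sprintf("`%s` must be c(slant, tilt) or a data frame with those columns.", arg),
                 class = "cueweights_validation_error")
  }
  c(slant = pose[[1]], tilt = pose[[2]])
}

# orthonormal in-plane basis (e1, e2) for a plane with pose (slant, tilt);
# e1 is the horizontal-screen direction of the tilt axis
plane_basis <- function(pose) {
  n <- drop(normal_from_orientation(pose[1], pose[2]))
  if (pose[1] < 1e-9) {
    e1 <- c(1, 0, 0)
  } else {
    e1 <- c(-n[2], n[1], 0)
    e1 <- e1 / sqrt(sum(e1^2))
  }
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

#' Back-project texture-plane points onto the disparity plane
#'
#' The metastimulus is built by texturing a plane at the texture pose,
#' imaging it from the cyclopic eye, and projecting that image onto a second
#' plane at the disparity pose (a virtual projector co-located with the
#' cyclopic eye). Geometrically each texture-plane point is carried along its
#' cyclopic ray to its intersection with the disparity plane, so the
#' monocular (cyclopic) image is invariant to the disparity pose while the
#' binocular disparity of the result is governed by the disparity pose alone.
#'
#' @param texture_points An n x 2 matrix (or length-2 vector) of coordinates
#'   (cm) in the texture plane's own orthonormal basis, origin at the
#'   aperture centre.
#' @param texture_pose,disparity_pose Poses as `c(slant, tilt)` in degrees
#'   (or one-row data frames with `slant`, `tilt` columns).
#' @param vg A [viewing_geometry()].
#' @return An n x 3 matrix of world points (cm) on the disparity plane.
#' @examples
#' vg <- viewing_geometry()
#' backproject(c(1, 2), c(10, 0), c(40, 0), vg)
#' @export
backproject <- function(texture_points, texture_pose, disparity_pose, vg) {
  if (is.null(dim(texture_points))) texture_points <- matrix(texture_points, ncol = 2L)
  texture_points <- as.matrix(texture_points)
  tp <- as_pose(texture_pose, "texture_pose")
  dp <- as_pose(disparity_pose, "disparity_pose")
  bt <- plane_basis(tp)
  bd <- plane_basis(dp)
  eye <- c(0, 0, vg$viewing_distance)
  # world point on the texture plane
  p <- outer(texture_points[, 1], bt$e1) + outer(texture_points[, 2], bt$e2)
  # ray x(t) = eye + t (p - eye); disparity plane: n_d . x = 0
  num <- sum(bd$n * eye)
  den <- num - drop(p %*% bd$n)   # n_d . (eye - p)
  abort_if(abs(den) < 1e-12, "cyclopic ray is parallel to the disparity plane.",
           class = "cueweights_geometry_error")
  t_hit <- num / den
  abort_if(t_hit <= 0, "disparity plane intersection lies behind the eye.",
           class = "cueweights_geometry_error")
  out <- matrix(eye, nrow = nrow(p), ncol = 3L, byrow = TRUE) +
    t_hit * sweep(p, 2L, eye)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Stereo (off-axis) projection of world points
#'
#' Projects world points through the left and right eyes onto the screen
#' plane with screen-converged (off-axis) frusta: points on the screen plane
#' have zero disparity, and points nearer than the screen have crossed
#' disparity, taken as positive. Disparity is the signed horizontal
#' difference `left_x - right_x` in cm.
#'
#' @param p An n x 3 matrix (or length-3 vector) of world points (cm), in
#'   front of the eyes (`z < viewing_distance`).
#' @param vg A [viewing_geometry()].
#' @return A tibble with columns `left_x`, `left_y`, `right_x`, `right_y`,
#'   `disparity` (all cm).
#' @examples
#' stereo_project(c(0, 0, 25), viewing_geometry(viewing_distance = 50))
#' @export
stereo_project <- function(p, vg) {
  p <- as_normal_matrix(p, "p")   # n x 3 of doubles; not necessarily unit
  vd <- vg$viewing_distance
  px <- unname(p[, 1]); py <- unname(p[, 2]); pz <- unname(p[, 3])
  abort_if(pz >= vd, "points must lie in front of the eyes (z < viewing_distance).",
           class = "cueweights_geometry_error")
  half <- vg$ipd / 2
  t <- vd / (vd - pz)
  lx <- -half + t * (px + half)
  rx <- half + t * (px - half)
  y <- t * py
  tibble(left_x = lx, left_y = y, right_x = rx, right_y = y,
         disparity = lx - rx)
}

#' Disparity field of a cue-conflict stimulus
#'
#' Composes [backproject()] and [stereo_project()] over a grid of cyclopic
#' sample directions: each grid point is a screen position (cm at the
#' screen plane), the corresponding cyclopic ray is intersected with the
#' disparity plane, and the intersection's signed horizontal disparity is
#' returned. Sampling by cyclopic ray makes the projector-consistency
#' property explicit: the field depends only on the disparity pose, because
#' the texture pose only moves surface points *within* their cyclopic rays.
#'
#' @param config One cue-conflict configuration: a one-row data frame with
#'   `sigma_c`, `tau_c`, `delta_sigma`, `delta_tau` (degrees).
#' @param vg A [viewing_geometry()].
#' @param sample_grid Optional n x 2 matrix of screen coordinates (cm); by
#'   default a `n_grid` x `n_grid` square grid spanning the aperture,
#'   clipped to the circular aperture.
#' @param n_grid Grid resolution for the default sample grid.
#' @return A tibble with screen coordinates `u`, `v`, world coordinates
#'   `x`, `y`, `z` of the surface point, and `disparity` (cm).
#' @examples
#' cfg <- data.frame(sigma_c = 25, tau_c = 0, delta_sigma = 30, delta_tau = 0)
#' field <- disparity_field(cfg, viewing_geometry(), n_grid = 5)
#' @export
disparity_field <- function(config, vg, sample_grid = NULL, n_grid = 15L) {
  config <- expand_conflict(config)[1, ]
  if (is.null(sample_grid)) {
    r <- aperture_radius_cm(vg)
    ax <- seq(-r, r, length.out = n_grid)
    sample_grid <- as.matrix(expand.grid(u = ax, v = ax))
    sample_grid <- sample_grid[rowSums(sample_grid^2) <= r^2, , drop = FALSE]
  }
  # the screen plane is the frontoparallel plane through the aperture
  # centre, so screen coordinates are texture coordinates at pose (0, 0)
  pts <- backproject(sample_grid, c(0, 0),
                     c(config$sigma_d, config$tau_d), vg)
  proj <- stereo_project(pts, vg)
  tibble(u = sample_grid[, 1], v = sample_grid[, 2],
         x = pts[, 1], y = pts[, 2], z = pts[, 3],
         disparity = proj$disparity)
}
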