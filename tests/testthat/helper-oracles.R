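# Fixture generators and independent oracles shared across test files.

# random surface orientations away from the degenerate frontoparallel pole
rand_orientations <- function(n, slant_range = c(5, 60)) {
  tibble::tibble(slant = runif(n, slant_range[1], slant_range[2]),
                 tilt = runif(n, 0, 360))
}

# random cue pairs with separation comfortably above the parallel tolerance
# (rows failing the separation check are redrawn individually)
rand_cue_pairs <- function(n, min_sep = 5) {
  a <- rand_orientations(n)
  b <- rand_orientations(n)
  n_t <- normal_from_orientation(a$slant, a$tilt)
  n_d <- normal_from_orientation(b$slant, b$tilt)
  repeat {
    bad <- which(angle_between(n_t, n_d) <= min_sep)
    if (!length(bad)) return(list(n_t = n_t, n_d = n_d))
    a2 <- rand_orientations(length(bad))
    b2 <- rand_orientations(length(bad))
    n_t[bad, ] <- normal_from_orientation(a2$slant, a2$tilt)
    n_d[bad, ] <- normal_from_orientation(b2$slant, b2$tilt)
  }
}

# weight pairs drawn uniformly in angle on the conflict ellipse, and the
# exactly-unit percepts they generate (in the cue plane by construction)
rand_on_ellipse <- function(n_t, n_d, theta = NULL) {
  g <- rowSums(n_t * n_d)
  n <- length(g)
  if (is.null(theta)) theta <- runif(n, 0, 2 * pi)
  A <- 1 / sqrt(1 - g)   # semi-axis along (1,-1)/sqrt(2)
  B <- 1 / sqrt(1 + g)   # semi-axis along (1, 1)/sqrt(2)
  w_t <- (cos(theta) * A + sin(theta) * B) / sqrt(2)
  w_d <- (-cos(theta) * A + sin(theta) * B) / sqrt(2)
  list(w_t = w_t, w_d = w_d, n_p = w_t * n_t + w_d * n_d)
}

# brute-force oracle: minimise the two constraint residuals on a dense grid,
# refined twice around the incumbent; independent of the package solvers
grid_search_weights <- function(n_p, n_t, n_d, span = 3, n_grid = 201) {
  g <- sum(n_t * n_d); pt <- sum(n_p * n_t); pd <- sum(n_p * n_d)
  cost <- function(wt, wd) {
    (wt^2 + wd^2 + 2 * g * wt * wd - 1)^2 + (wt * pt + wd * pd - 1)^2
  }
  ctr <- c(0, 0); half <- span
  for (pass in 1:3) {
    wt <- seq(ctr[1] - half, ctr[1] + half, length.out = n_grid)
    wd <- seq(ctr[2] - half, ctr[2] + half, length.out = n_grid)
    cc <- outer(wt, wd, cost)
    k <- arrayInd(which.min(cc), dim(cc))
    ctr <- c(wt[k[1]], wd[k[2]])
    half <- half * 2 / (n_grid - 1) * 4
  }
  list(w_t = ctr[1], w_d = ctr[2], cost = cost(ctr[1], ctr[2]))
}

# brute-force oracle for in-plane percepts: enumerate points along the
# percept line (which contains the tangency point) and minimise the ellipse
# residual |f1|; the residual is quadratic along the line so a fine grid
# localises the solution sharply
line_search_weights <- function(n_p, n_t, n_d, step = 1e-5, span = 3) {
  g <- sum(n_t * n_d); pt <- sum(n_p * n_t); pd <- sum(n_p * n_d)
  nrm2 <- pt^2 + pd^2
  base <- c(pt, pd) / nrm2                 # least-norm point on the line
  dirv <- c(-pd, pt) / sqrt(nrm2)          # direction along the line
  t <- seq(-span, span, by = step)
  wt <- base[1] + t * dirv[1]
  wd <- base[2] + t * dirv[2]
  f1 <- wt^2 + wd^2 + 2 * g * wt * wd - 1
  k <- which.min(abs(f1))
  list(w_t = wt[k], w_d = wd[k], f1 = f1[k])
}

# discriminant of the line-ellipse intersection quadratic: substitute the
# percept line into the ellipse and expand in the weight with the larger
# line coefficient (avoids division blow-ups)
line_ellipse_discriminant <- function(n_p, n_t, n_d) {
  g <- sum(n_t * n_d); pt <- sum(n_p * n_t); pd <- sum(n_p * n_d)
  if (abs(pt) >= abs(pd)) {
    # w_t = (1 - w_d pd) / pt
    a <- pd^2 / pt^2 - 2 * g * pd / pt + 1
    b <- -2 * pd / pt^2 + 2 * g / pt
    c0 <- 1 / pt^2 - 1
  } else {
    a <- pt^2 / pd^2 - 2 * g * pt / pd + 1
    b <- -2 * pt / pd^2 + 2 * g / pd
    c0 <- 1 / pd^2 - 1
  }
  b^2 - 4 * a * c0
}

# independent parametric ray-plane intersection (oracle for backproject)
ray_plane_oracle <- function(eye, through, plane_normal) {
  dirv <- through - eye
  t <- -sum(plane_normal * eye) / sum(plane_normal * dirv)
  eye + t * dirv
}

# analytic screen-converged disparity of a world point (similar triangles)
analytic_disparity <- function(z, vg) {
  vg$ipd * z / (vg$viewing_distance - z)
}

# cyclopic image (projection through the cyclopic eye onto the screen z = 0)
cyclopic_image <- function(p, vg) {
  vd <- vg$viewing_distance
  t <- vd / (vd - p[, 3])
  cbind(t * p[, 1], t * p[, 2])
}

# unit screen-plane direction of a tilt angle (degrees)
deg2rad_dir <- function(tau) c(cos(tau * pi / 180), sin(tau * pi / 180))
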