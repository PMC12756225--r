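#' Slant/tilt surface orientations and unit normals
#'
#' A planar surface's 3D pose is described by two angles: *slant* (sigma), the
#' rotation away from the frontoparallel plane, and *tilt* (tau), the direction
#' of the projection of the surface normal onto the frontoparallel plane,
#' measured counter-clockwise from screen-right. `normal_from_orientation()`
#' maps (slant, tilt) to the unit surface normal
#' \deqn{n(\sigma, \tau) = (\sin\sigma\cos\tau,\; \sin\sigma\sin\tau,\; \cos\sigma),}
#' so the normal of a frontoparallel surface points along +z (toward the
#' viewer) and the angle between the normal and +z equals the slant.
#' `orientation_from_normal()` inverts the map; tilt is undefined (flagged,
#' reported `NA`) below `slant_epsilon` because a frontoparallel plane has no
#' tilt direction.
#'
#' All interface angles are degrees; slants must lie in `[0, 90)` so normals
#' always have z > 0.
#'
#' @param slant,tilt Numeric vectors of angles in degrees (recycled to a
#'   common length). Slant must be in `[0, 90)`.
#' @param n A length-3 numeric vector or an n x 3 matrix of unit normals with
#'   positive z components.
#' @param slant_epsilon Slant (degrees) below which tilt is reported as
#'   undefined. Default 0.1.
#' @param tol Unit-norm validation tolerance for `orientation_from_normal()`.
#'
#' @return `normal_from_orientation()`: an n x 3 numeric matrix with columns
#'   `x`, `y`, `z`. `orientation_from_normal()`: a tibble with columns
#'   `slant`, `tilt` (degrees, tilt in `[0, 360)` or `NA` when undefined) and
#'   `tilt_undefined` (logical).
#'
#' @examples
#' normal_from_orientation(30, 90)
#' orientation_from_normal(c(0.5, 0.5, sqrt(0.5)))
#' @export
normal_from_orientation <- function(slant, tilt) {
  k <- vctrs_recycle2(slant, tilt)
  slant <- k[[1]]; tilt <- k[[2]]
  abort_if(!is.finite(slant) | slant < 0 | slant >= 90,
           "`slant` must lie in [0, 90).", class = "cueweights_domain_error")
  s <- deg2rad(slant); t <- deg2rad(tilt)
  m <- cbind(x = sin(s) * cos(t), y = sin(s) * sin(t), z = cos(s))
  m
}

# minimal common-length recycling for two numeric vectors
vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  list(rep_len(as.numeric(a), n), rep_len(as.numeric(b), n))
}

#' @rdname normal_from_orientation
#' @export
orientation_from_normal <- function(n, slant_epsilon = 0.1, tol = 1e-6) {
  n <- as_normal_matrix(n)
  check_unit_rows(n, "n", tol = tol)
  abort_if(n[, "z"] <= 0, "normals must have z > 0 (slant in [0, 90)).",
           class = "cueweights_domain_error")
  slant <- rad2deg(acos(clamp(n[, "z"], -1, 1)))
  tilt <- wrap360(rad2deg(atan2(n[, "y"], n[, "x"])))
  undef <- slant < slant_epsilon
  tilt[undef] <- NA_real_
  tibble(slant = unname(slant), tilt = unname(tilt),
         tilt_undefined = unname(undef))
}

#' Angle between unit normals
#'
#' Angular separation of paired rows of two unit-vector matrices, in degrees.
#'
#' @param a,b Length-3 vectors or n x 3 matrices of unit vectors.
#' @return Numeric vector of angles in `[0, 180]` degrees.
#' @examples
#' angle_between(c(0, 0, 1), c(1, 0, 0))
#' @export
angle_between <- function(a, b) {
  a <- as_normal_matrix(a, "a"); b <- as_normal_matrix(b, "b")
  check_unit_rows(a, "a"); check_unit_rows(b, "b")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  unname(rad2deg(acos(clamp(rowSums(a * b), -1, 1))))
}

#' Expand cue-conflict configurations into per-cue orientations
#'
#' A cue-conflict configuration is a central orientation (`sigma_c`, `tau_c`)
#' plus discrepancies (`delta_sigma`, `delta_tau`) split symmetrically between
#' the two cues: the disparity cue takes the half-discrepancy *toward*
#' frontoparallel (minus half), the texture cue the half *away* from it
#' (plus half), so the disparity-specified orientation is always the one
#' closer to frontoparallel:
#' \deqn{\sigma_d = \sigma_c - \Delta\sigma/2,\quad \tau_d = \tau_c - \Delta\tau/2,}
#' \deqn{\sigma_t = \sigma_c + \Delta\sigma/2,\quad \tau_t = \tau_c + \Delta\tau/2.}
#'
#' @param configs A data frame with numeric columns `sigma_c`, `tau_c`,
#'   `delta_sigma`, `delta_tau` (degrees). Extra columns are carried through.
#' @return The input as a tibble with columns `sigma_d`, `tau_d`, `sigma_t`,
#'   `tau_t` appended (tilts wrapped into `[0, 360)`).
#' @examples
#' expand_conflict(data.frame(sigma_c = 25, tau_c = 45,
#'                            delta_sigma = 30, delta_tau = 45))
#' @export
expand_conflict <- function(configs) {
  configs <- as_tibble(configs)
  need <- c("sigma_c", "tau_c", "delta_sigma", "delta_tau")
  missing_cols <- setdiff(need, names(configs))
  if (length(missing_cols)) {
    rlang::abort(paste0("`configs` is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "cueweights_config_error")
  }
  sigma_d <- configs$sigma_c - configs$delta_sigma / 2
  sigma_t <- configs$sigma_c + configs$delta_sigma / 2
  abort_if(sigma_d < 0 | sigma_t >= 90,
           "expanded slants must lie in [0, 90); reduce `delta_sigma` or recentre.",
           class = "cueweights_config_error")
  configs %>%
    mutate(
      sigma_d = sigma_d,
      tau_d   = wrap360(.data$tau_c - .data$delta_tau / 2),
      sigma_t = sigma_t,
      tau_t   = wrap360(.data$tau_c + .data$delta_tau / 2)
    )
}

# cue normals for expanded configs: list(n_t = , n_d = ) of n x 3 matrices
conflict_normals <- function(configs) {
  if (!all(c("sigma_d", "sigma_t") %in% names(configs))) {
    configs <- expand_conflict(configs)
  }
  list(
    n_t = normal_from_orientation(configs$sigma_t, configs$tau_t),
    n_d = normal_from_orientation(configs$sigma_d, configs$tau_d)
  )
}
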