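#' Estimate texture and disparity cue weights from a perceived normal
#'
#' The vector-sum model represents the perceived surface normal as a weighted
#' sum of the unit normals specified by the texture and disparity cues,
#' \deqn{n_p = w_t n_t + w_d n_d,}
#' and asks that the combined vector itself be a unit normal. This yields a
#' pair of constraints on the weight pair \eqn{(w_d, w_t)}:
#' \deqn{\|w_t n_t + w_d n_d\|^2 - 1 = 0 \quad\textrm{(ellipse)},}
#' \deqn{n_p \cdot (w_t n_t + w_d n_d) - 1 = 0 \quad\textrm{(line)}.}
#' Three solvers are provided:
#'
#' * `weights_pseudoinverse()` solves the overdetermined 3x2 linear system
#'   by least squares (Moore-Penrose pseudo-inverse). It minimises the
#'   residual \eqn{\|n_p - (w_t n_t + w_d n_d)\|} but does **not** constrain
#'   the combined vector to unit norm.
#' * `weights_closed_form()` applies when the perceived normal lies in the
#'   span of the two cue normals: by Cauchy-Schwarz the line is then tangent
#'   to the ellipse and the unique tangency point is the coordinate pair of
#'   `n_p` in the (generally non-orthogonal) cue basis, obtained from the
#'   2x2 Gram system. Off-plane percepts raise an error directing the caller
#'   to `weights_constrained()`.
#' * `weights_constrained()` minimises the two constraint residuals jointly
#'   (equal weighting) with a damped Gauss-Newton (Levenberg-Marquardt)
#'   iteration, vectorised across trials. For in-plane percepts it agrees
#'   with the closed form; for off-plane percepts (the generic case for
#'   noisy settings) it returns the best-fitting weight pair with a nonzero
#'   `residual_norm`.
#'
#' Weights may legitimately be negative (the percept lies outside the wedge
#' spanned by the cues) and, on the ellipse, non-negative weight pairs
#' satisfy \eqn{w_t + w_d \ge 1} — the weights do not sum to one.
#'
#' Near-parallel cues (separation below `tol_angle`) make the weights
#' unidentifiable: every pair with \eqn{w_t + w_d = 1} solves the
#' zero-conflict system. All solvers then report the symmetric pair
#' `(0.5, 0.5)` with `degenerate = TRUE` instead of failing, so batch
#' pipelines keep running.
#'
#' @param n_p,n_t,n_d Perceived, texture-cue and disparity-cue unit normals:
#'   length-3 vectors or row-paired n x 3 matrices.
#' @param init Optional starting weight pair `c(w_t, w_d)` (or n x 2 matrix)
#'   for the Levenberg-Marquardt iteration; defaults to the pseudo-inverse
#'   solution radially projected onto the constraint ellipse.
#' @param tol_angle Cue separation (degrees) below which the problem is
#'   flagged degenerate. Default 0.5.
#' @param tol_plane Tolerance on the scalar triple product for the in-plane
#'   test in `weights_closed_form()`. Default 1e-9.
#' @param tol_solve Residual tolerance for the `converged` flag (the
#'   iteration itself runs to the numerical floor so that the tangency
#'   point — a double root of the system — is located to full precision).
#'   Default 1e-10.
#' @param max_iter Maximum Levenberg-Marquardt iterations. Default 200.
#'
#' @return A tibble with one row per trial and columns `w_t`, `w_d`,
#'   `residual_norm`, `method`, `degenerate`, `converged`. For the
#'   pseudo-inverse, `residual_norm` is the Euclidean misfit
#'   \eqn{\|n_p - (w_t n_t + w_d n_d)\|}; for the closed-form and
#'   Levenberg-Marquardt solvers it is the norm of the two constraint
#'   residuals.
#'
#' @examples
#' n_t <- normal_from_orientation(40, 0)
#' n_d <- normal_from_orientation(10, 0)
#' n_p <- normal_from_orientation(25, 0)   # in the cue plane
#' weights_closed_form(n_p, n_t, n_d)
#' weights_constrained(n_p, n_t, n_d)
#' @export
weights_pseudoinverse <- function(n_p, n_t, n_d, tol_angle = 0.5) {
  x <- prep_weight_inputs(n_p, n_t, n_d, tol_angle)
  det <- 1 - x$g^2
  w_t <- (x$pt - x$g * x$pd) / det
  w_d <- (x$pd - x$g * x$pt) / det
  w_t[x$degen] <- 0.5
  w_d[x$degen] <- 0.5
  v <- w_t * x$n_t + w_d * x$n_d
  res <- sqrt(rowSums((x$n_p - v)^2))
  tibble(w_t = w_t, w_d = w_d, residual_norm = res,
         method = "pseudoinverse", degenerate = x$degen, converged = TRUE)
}

#' @rdname weights_pseudoinverse
#' @export
weights_closed_form <- function(n_p, n_t, n_d, tol_angle = 0.5,
                                tol_plane = 1e-9, tol_solve = 1e-10) {
  x <- prep_weight_inputs(n_p, n_t, n_d, tol_angle)
  # scalar triple product: 0 iff n_p lies in span(n_t, n_d)
  triple <- rowSums(x$n_p * cross3(x$n_t, x$n_d))
  off <- abs(triple) > tol_plane & !x$degen
  if (any(off)) {
    rlang::abort(
      "perceived normal lies off the cue plane: the line does not meet the ellipse; use `weights_constrained()`.",
      class = "cueweights_no_intersection_error")
  }
  det <- 1 - x$g^2
  w_t <- (x$pt - x$g * x$pd) / det
  w_d <- (x$pd - x$g * x$pt) / det
  w_t[x$degen] <- 0.5
  w_d[x$degen] <- 0.5
  res <- constraint_residual_norm(w_t, w_d, x)
  tibble(w_t = w_t, w_d = w_d, residual_norm = res,
         method = "closed_form", degenerate = x$degen, converged = TRUE)
}

#' @rdname weights_pseudoinverse
#' @export
weights_constrained <- function(n_p, n_t, n_d, init = NULL, tol_angle = 0.5,
                                tol_solve = 1e-10, max_iter = 200L) {
  x <- prep_weight_inputs(n_p, n_t, n_d, tol_angle)
  n <- length(x$g)
  if (is.null(init)) {
    det <- 1 - x$g^2
    w_t <- (x$pt - x$g * x$pd) / det
    w_d <- (x$pd - x$g * x$pt) / det
    # radial projection onto the ellipse (unit combined norm)
    q <- w_t^2 + w_d^2 + 2 * x$g * w_t * w_d
    ok <- is.finite(q) & q > 1e-12
    scl <- ifelse(ok, 1 / sqrt(pmax(q, 1e-12)), NA_real_)
    w_t <- ifelse(ok, w_t * scl, 0.5)
    w_d <- ifelse(ok, w_d * scl, 0.5)
  } else {
    if (is.null(dim(init))) init <- matrix(init, nrow = n, ncol = 2, byrow = TRUE)
    w_t <- init[, 1]; w_d <- init[, 2]
  }

  fit <- lm_solve_batch(w_t, w_d, x$g, x$pt, x$pd,
                        tol = tol_solve, max_iter = max_iter)
  w_t <- fit$w_t; w_d <- fit$w_d
  w_t[x$degen] <- 0.5
  w_d[x$degen] <- 0.5
  res <- constraint_residual_norm(w_t, w_d, x)
  conv <- fit$converged | x$degen
  if (any(!conv)) {
    rlang::warn(sprintf(
      "Levenberg-Marquardt did not reach a stationary point for %d trial(s); best iterate returned.",
      sum(!conv)))
  }
  tibble(w_t = w_t, w_d = w_d, residual_norm = res,
         method = "levenberg_marquardt", degenerate = x$degen, converged = conv)
}

#' Conflict ellipse of admissible weight pairs
#'
#' The unit-norm constraint on the combined vector restricts \eqn{(w_d, w_t)}
#' to an origin-centred ellipse
#' \eqn{w_t^2 + w_d^2 + 2 w_t w_d\,(n_d\cdot n_t) = 1}
#' whose shape depends only on the angle between the cue normals. Its
#' principal axes lie along the diagonals of the weight plane: the axis along
#' the \eqn{-\pi/4} direction has semi-length \eqn{1/\sqrt{1 - n_d\cdot n_t}}
#' and the perpendicular one \eqn{1/\sqrt{1 + n_d\cdot n_t}}. For positively
#' correlated cues (`cue_dot > 0`, the experimental regime) the \eqn{-\pi/4}
#' axis is the major one.
#'
#' @inheritParams weights_pseudoinverse
#' @return A tibble with columns `cue_dot`, `rotation` (radians, always
#'   `-pi/4`), `semi_axis_major` (semi-axis along the rotation direction) and
#'   `semi_axis_minor`.
#' @examples
#' conflict_ellipse(normal_from_orientation(40, 0), normal_from_orientation(10, 0))
#' @export
conflict_ellipse <- function(n_t, n_d) {
  n_t <- check_unit_rows(as_normal_matrix(n_t, "n_t"), "n_t")
  n_d <- check_unit_rows(as_normal_matrix(n_d, "n_d"), "n_d")
  g <- rowSums(n_t * n_d)
  abort_if(abs(g) >= 1 - 1e-12,
           "cue normals are (anti-)parallel: the weight locus degenerates.",
           class = "cueweights_degenerate_error")
  tibble(cue_dot = g, rotation = -pi / 4,
         semi_axis_major = 1 / sqrt(1 - g),
         semi_axis_minor = 1 / sqrt(1 + g))
}

# ---- internal ----------------------------------------------------------

# common validation + scalar products for the solvers
prep_weight_inputs <- function(n_p, n_t, n_d, tol_angle) {
  n_p <- check_unit_rows(as_normal_matrix(n_p, "n_p"), "n_p")
  n_t <- check_unit_rows(as_normal_matrix(n_t, "n_t"), "n_t")
  n_d <- check_unit_rows(as_normal_matrix(n_d, "n_d"), "n_d")
  n <- max(nrow(n_p), nrow(n_t), nrow(n_d))
  expand1 <- function(m) if (nrow(m) == 1L && n > 1L) m[rep(1L, n), , drop = FALSE] else m
  n_p <- expand1(n_p); n_t <- expand1(n_t); n_d <- expand1(n_d)
  if (nrow(n_p) != n || nrow(n_t) != n || nrow(n_d) != n) {
    rlang::abort("`n_p`, `n_t`, `n_d` must have matching (or single) rows.",
                 class = "cueweights_validation_error")
  }
  g <- rowSums(n_t * n_d)
  degen <- angle_between(n_t, n_d) < tol_angle
  list(n_p = n_p, n_t = n_t, n_d = n_d,
       g = g, pt = rowSums(n_p * n_t), pd = rowSums(n_p * n_d),
       degen = degen)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

constraint_residual_norm <- function(w_t, w_d, x) {
  f1 <- w_t^2 + w_d^2 + 2 * x$g * w_t * w_d - 1
  f2 <- w_t * x$pt + w_d * x$pd - 1
  sqrt(f1^2 + f2^2)
}

# Damped Gauss-Newton (Levenberg-Marquardt) on the two constraint residuals,
# vectorised across trials; per-trial damping with accept/reject steps.
lm_solve_batch <- function(w_t, w_d, g, pt, pd, tol = 1e-10, max_iter = 100L) {
  n <- length(w_t)
  lambda <- rep(1e-3, n)
  resid2 <- function(wt, wd) {
    f1 <- wt^2 + wd^2 + 2 * g * wt * wd - 1
    f2 <- wt * pt + wd * pd - 1
    list(f1 = f1, f2 = f2, cost = f1^2 + f2^2)
  }
  cur <- resid2(w_t, w_d)
  active <- rep(TRUE, n)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    f1 <- cur$f1; f2 <- cur$f2
    # Jacobian of (f1, f2) wrt (w_t, w_d)
    j11 <- 2 * (w_t + g * w_d); j12 <- 2 * (w_d + g * w_t)
    j21 <- pt;                  j22 <- pd
    grad1 <- j11 * f1 + j21 * f2
    grad2 <- j12 * f1 + j22 * f2
    small_grad <- sqrt(grad1^2 + grad2^2) < 1e-14
    # iterate to the numerical floor: the tangency point is a double root,
    # so a loose residual stop would leave O(sqrt(tol)) positional slack
    done <- (cur$cost < 1e-28) | small_grad | (lambda > 1e7)
    active <- active & !done
    if (!any(active)) break
    a11 <- j11^2 + j21^2; a12 <- j11 * j12 + j21 * j22; a22 <- j12^2 + j22^2
    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    step_t <- (-grad1 * d22 + grad2 * a12) / det
    step_d <- (-grad2 * d11 + grad1 * a12) / det
    wt_new <- w_t + ifelse(active, step_t, 0)
    wd_new <- w_d + ifelse(active, step_d, 0)
    new <- resid2(wt_new, wd_new)
    better <- active & (new$cost < cur$cost)
    w_t[better] <- wt_new[better]
    w_d[better] <- wd_new[better]
    cur$f1[better] <- new$f1[better]
    cur$f2[better] <- new$f2[better]
    cur$cost[better] <- new$cost[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-12)
    rej <- active & !better
    lambda[rej] <- pmin(lambda[rej] * 4, 1e8)
  }
  # Newton polish on the square system for near-solvable (in-plane) cases:
  # the normal-equations step squares the condition number and loses the
  # tangent-valley direction to cancellation at ~1e-5; solving J step = -f
  # directly is conditioned by det(J) and reaches the floor of the double
  # root. Off-plane percepts (large residual) are left to the LM minimiser.
  polish <- sqrt(cur$cost) < 1e-6
  if (any(polish)) {
    for (k in seq_len(40L)) {
      f1 <- cur$f1; f2 <- cur$f2
      j11 <- 2 * (w_t + g * w_d); j12 <- 2 * (w_d + g * w_t)
      detj <- j11 * pd - j12 * pt
      act <- polish & abs(detj) > 1e-12 & cur$cost > 0
      if (!any(act)) break
      st <- -(f1 * pd - f2 * j12) / detj
      sd_ <- -(j11 * f2 - pt * f1) / detj
      wt_new <- w_t + ifelse(act, st, 0)
      wd_new <- w_d + ifelse(act, sd_, 0)
      new <- resid2(wt_new, wd_new)
      ok <- act & (new$cost < cur$cost)
      w_t[ok] <- wt_new[ok]; w_d[ok] <- wd_new[ok]
      cur$f1[ok] <- new$f1[ok]; cur$f2[ok] <- new$f2[ok]
      cur$cost[ok] <- new$cost[ok]
      polish <- polish & ok
    }
  }
  # converged: residuals at tolerance, or at a stationary point of the
  # sum-of-squares (generic for off-plane percepts)
  f1 <- cur$f1; f2 <- cur$f2
  j11 <- 2 * (w_t + g * w_d); j12 <- 2 * (w_d + g * w_t)
  gn <- sqrt((j11 * f1 + pt * f2)^2 + (j12 * f1 + pd * f2)^2)
  list(w_t = w_t, w_d = w_d,
       converged = (sqrt(cur$cost) < tol) | (gn < 1e-8))
}
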