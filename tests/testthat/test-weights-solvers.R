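test_that("pseudo-inverse recovers pure-cue percepts and reports misfit", {
  n_t <- normal_from_orientation(40, 10)
  n_d <- normal_from_orientation(12, 350)
  est <- weights_pseudoinverse(n_t, n_t, n_d)
  expect_equal(est$w_t, 1, tolerance = 1e-12)
  expect_equal(est$w_d, 0, tolerance = 1e-12)
  expect_lt(est$residual_norm, 1e-12)

  # in-plane percept: least squares attains the exact solution, unit combined norm
  withr::local_seed(11)
  cues <- rand_cue_pairs(100)
  on <- rand_on_ellipse(cues$n_t, cues$n_d)
  est <- weights_pseudoinverse(on$n_p, cues$n_t, cues$n_d)
  expect_lt(max(est$residual_norm), 1e-10)
  v <- est$w_t * cues$n_t + est$w_d * cues$n_d
  expect_equal(sqrt(rowSums(v^2)), rep(1, 100), tolerance = 1e-10)

  # off-plane percept: positive residual, combined norm at most 1 (projection)
  n_p <- normal_from_orientation(25, 60)
  n_t <- normal_from_orientation(40, 0); n_d <- normal_from_orientation(10, 0)
  est <- weights_pseudoinverse(n_p, n_t, n_d)
  expect_gt(est$residual_norm, 1e-3)
  v <- est$w_t * drop(n_t) + est$w_d * drop(n_d)
  expect_lte(sqrt(sum(v^2)), 1)
})

test_that("conflict ellipse parameters match the eigendecomposition of the quadratic form", {
  n_t <- normal_from_orientation(40, 0); n_d <- normal_from_orientation(10, 0)
  ell <- conflict_ellipse(n_t, n_d)
  expect_equal(ell$rotation, -pi / 4)
  expect_equal(ell$cue_dot, cos(pi / 6), tolerance = 1e-12)
  g <- ell$cue_dot
  ev <- eigen(matrix(c(1, g, g, 1), 2))$values   # independent oracle
  expect_equal(sort(c(ell$semi_axis_major, ell$semi_axis_minor)),
               sort(1 / sqrt(ev)), tolerance = 1e-12)
  expect_equal(ell$semi_axis_major, 1 / sqrt(1 - g), tolerance = 1e-12)
  expect_equal(ell$semi_axis_minor, 1 / sqrt(1 + g), tolerance = 1e-12)

  # orthogonal cues: unit circle
  circ <- conflict_ellipse(c(0, 0, 1), c(1, 0, 0))
  expect_equal(circ$semi_axis_major, 1)
  expect_equal(circ$semi_axis_minor, 1)

  expect_error(conflict_ellipse(n_t, n_t), class = "cueweights_degenerate_error")
})

test_that("closed form solves the tangency problem and matches brute-force search", {
  n_t <- normal_from_orientation(40, 0); n_d <- normal_from_orientation(10, 0)
  est <- weights_closed_form(n_d, n_t, n_d)
  expect_equal(est$w_t, 0, tolerance = 1e-12)
  expect_equal(est$w_d, 1, tolerance = 1e-12)

  # angular bisector of cues 30 deg apart: w = 1 / (2 cos 15 deg)
  n_p <- normal_from_orientation(25, 0)
  est <- weights_closed_form(n_p, n_t, n_d)
  expect_equal(est$w_t, 1 / (2 * cos(pi / 12)), tolerance = 1e-10)
  expect_equal(est$w_d, est$w_t, tolerance = 1e-10)
  oracle <- line_search_weights(drop(n_p), drop(n_t), drop(n_d))
  expect_equal(est$w_t, oracle$w_t, tolerance = 1e-4)
  expect_equal(est$w_d, oracle$w_d, tolerance = 1e-4)

  # no-conflict degenerate case: symmetric pair reported, flagged
  deg <- weights_closed_form(n_d, n_d, n_d)
  expect_true(deg$degenerate)
  expect_equal(c(deg$w_t, deg$w_d), c(0.5, 0.5))

  # off-plane percept: no line-ellipse intersection
  expect_error(weights_closed_form(normal_from_orientation(25, 40), n_t, n_d),
               class = "cueweights_no_intersection_error")
})

test_that("constrained LM agrees with the closed form in-plane and with minpack off-plane", {
  n_t <- normal_from_orientation(40, 0); n_d <- normal_from_orientation(10, 0)
  n_p <- normal_from_orientation(25, 0)
  lm_est <- weights_constrained(n_p, n_t, n_d)
  cf_est <- weights_closed_form(n_p, n_t, n_d)
  expect_equal(lm_est$w_t, cf_est$w_t, tolerance = 1e-8)
  expect_equal(lm_est$w_d, cf_est$w_d, tolerance = 1e-8)
  expect_true(lm_est$converged)

  # 2 degrees out of plane: positive residual, near the in-plane solution,
  # and matching both a dense grid search and minpack.lm's LM implementation
  n_off <- normal_from_orientation(25, 2)
  off <- weights_constrained(n_off, n_t, n_d)
  expect_gt(off$residual_norm, 0)
  expect_lt(abs(off$w_t - lm_est$w_t), 0.05)
  oracle <- grid_search_weights(drop(n_off), drop(n_t), drop(n_d))
  expect_lt(off$residual_norm^2, oracle$cost + 1e-10)

  g <- sum(n_t * n_d); pt <- sum(n_off * n_t); pd <- sum(n_off * n_d)
  fn <- function(w) c(w[1]^2 + w[2]^2 + 2 * g * w[1] * w[2] - 1,
                      w[1] * pt + w[2] * pd - 1)
  mp <- minpack.lm::nls.lm(par = c(0.5, 0.5), fn = fn,
                           control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15))
  expect_equal(unname(c(off$w_t, off$w_d)), unname(coef(mp)), tolerance = 1e-6)
})

test_that("LM solution is insensitive to the starting point for in-plane percepts", {
  withr::local_seed(3)
  cues <- rand_cue_pairs(50)
  on <- rand_on_ellipse(cues$n_t, cues$n_d)
  a <- weights_constrained(on$n_p, cues$n_t, cues$n_d)
  b <- weights_constrained(on$n_p, cues$n_t, cues$n_d, init = c(0.5, 0.5))
  expect_equal(a$w_t, b$w_t, tolerance = 1e-6)
  expect_equal(a$w_d, b$w_d, tolerance = 1e-6)
})

test_that("all solvers recover weight pairs planted on the conflict ellipse", {
  withr::local_seed(19)
  cues <- rand_cue_pairs(300)
  on <- rand_on_ellipse(cues$n_t, cues$n_d)
  for (f in list(weights_pseudoinverse, weights_closed_form, weights_constrained)) {
    est <- f(on$n_p, cues$n_t, cues$n_d)
    expect_lt(max(abs(est$w_t - on$w_t)), 1e-6)
    expect_lt(max(abs(est$w_d - on$w_d)), 1e-6)
  }
})

test_that("unit-norm conservation holds for constrained in-plane estimates", {
  withr::local_seed(23)
  cues <- rand_cue_pairs(300)
  on <- rand_on_ellipse(cues$n_t, cues$n_d)
  est <- weights_constrained(on$n_p, cues$n_t, cues$n_d)
  v <- est$w_t * cues$n_t + est$w_d * cues$n_d
  expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-6)
})

test_that("near-parallel cues are flagged degenerate instead of erroring", {
  n_a <- normal_from_orientation(20, 0)
  n_b <- normal_from_orientation(20.2, 0)   # 0.2 deg apart, below tol_angle
  for (f in list(weights_pseudoinverse, weights_constrained)) {
    est <- f(n_a, n_a, n_b)
    expect_true(est$degenerate)
    expect_equal(c(est$w_t, est$w_d), c(0.5, 0.5))
  }
})
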