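test_that("per-trial estimation recovers pure-cue percepts and flags degenerate trials", {
  cfg <- expand_conflict(data.frame(sigma_c = 25, tau_c = 0,
                                    delta_sigma = 30, delta_tau = 0))
  rec <- tibble::tibble(cfg,
                        perceived_slant = cfg$sigma_t,
                        perceived_tilt = cfg$tau_t)
  est <- estimate_trial_weights(rec)
  expect_equal(est$w_t, 1, tolerance = 1e-8)
  expect_equal(est$w_d, 0, tolerance = 1e-8)

  # zero-conflict record: unidentifiable, flagged, batch keeps running
  rec2 <- tibble::tibble(sigma_c = c(25, 25), tau_c = 0,
                         delta_sigma = c(0, 30), delta_tau = 0,
                         perceived_slant = 25, perceived_tilt = 0)
  est2 <- estimate_trial_weights(rec2)
  expect_true(est2$degenerate[1])
  expect_false(est2$degenerate[2])

  # undefined perceived tilt: flagged, weights NA
  rec3 <- tibble::tibble(sigma_c = 25, tau_c = 0, delta_sigma = 30,
                         delta_tau = 0, perceived_slant = 0.05,
                         perceived_tilt = NA_real_)
  est3 <- estimate_trial_weights(rec3)
  expect_true(est3$degenerate)
  expect_true(is.na(est3$w_d))
})

test_that("aggregation takes cell means, excludes and counts degenerate trials", {
  rec <- tibble::tibble(
    subject = 1, phase = "pre", sigma_c = 25, tau_c = 0,
    delta_sigma = c(30, 30, 30, 0), delta_tau = 0,
    perceived_slant = c(20, 30, 25, 25), perceived_tilt = 0)
  map <- aggregate_weights(estimate_trial_weights(rec))
  cell <- map[map$delta_sigma == 30, ]
  est <- estimate_trial_weights(rec)
  expect_equal(cell$mean_w_d, mean(est$w_d[1:3]))
  expect_equal(cell$n_trials, 3L)
  zero <- map[map$delta_sigma == 0, ]
  expect_equal(zero$n_dropped, 1L)
  expect_equal(zero$n_trials, 0L)

  # five identical trials: the mean is the common value
  rec5 <- tibble::tibble(subject = 1, phase = "pre", sigma_c = 25, tau_c = 0,
                         delta_sigma = 30, delta_tau = 0,
                         perceived_slant = rep(22, 5), perceived_tilt = 0)
  map5 <- aggregate_weights(estimate_trial_weights(rec5))
  one <- estimate_trial_weights(rec5[1, ])
  expect_equal(map5$mean_w_d, one$w_d)
  expect_equal(map5$sd_w_d, 0)
})

test_that("noiseless closure: the pipeline reproduces the generative field per cell", {
  d <- judgment_design(repetitions = 5)
  f <- weight_field()
  rec <- simulate_study(d, f, observer_noise(kappa = Inf), n_subjects = 2,
                        subject_sd = 0, seed = 21)
  map <- aggregate_weights(estimate_trial_weights(rec))
  truth <- predict_wd(f, map$sigma_c, map$tau_c)
  expect_lt(max(abs(map$mean_w_d - truth)), 1e-6)
})

test_that("trend fit recovers a constant field as zero slope with covering CI", {
  d <- judgment_design(repetitions = 2)
  f0 <- weight_field(intercept = 0.8, slope_logslant = 0, tilt_gain = 0)
  rec <- simulate_study(d, f0, observer_noise(kappa = 500), n_subjects = 6,
                        phases = "pre", subject_sd = 0.05, seed = 13)
  fit <- fit_trend(aggregate_weights(estimate_trial_weights(rec)),
                   n_boot = 200, seed = 14)
  sl <- tidy(fit)[tidy(fit)$term == "slope_logslant", ]
  expect_lt(abs(sl$estimate), 0.05)
  expect_true(sl$conf_low <= 0 && 0 <= sl$conf_high)
})

test_that("trend fit recovers slope and ordered tilt offsets from the default preset", {
  d <- judgment_design(repetitions = 5)
  f <- weight_field()   # slope -0.35, tilt gain +0.003/deg
  rec <- simulate_study(d, f, observer_noise(kappa = 5000), n_subjects = 6,
                        phases = "pre", subject_sd = 0.05, seed = 31)
  fit <- fit_trend(aggregate_weights(estimate_trial_weights(rec)),
                   n_boot = 200, seed = 32)
  co <- tidy(fit)
  sl <- co[co$term == "slope_logslant", ]
  expect_true(sl$conf_low <= f$slope_logslant &&
                f$slope_logslant <= sl$conf_high)
  # per-tilt offsets ordered 0 < 45 < 90 (baseline tilt 0 is the zero offset)
  t45 <- co$estimate[co$term == "tilt_45"]
  t90 <- co$estimate[co$term == "tilt_90"]
  expect_gt(t45, 0)
  expect_gt(t90, t45)
  # determinism under seed
  fit2 <- fit_trend(aggregate_weights(estimate_trial_weights(rec)),
                    n_boot = 200, seed = 32)
  expect_equal(tidy(fit), tidy(fit2))

  expect_error(fit_trend(dplyr::filter(aggregate_weights(
    estimate_trial_weights(rec)), sigma_c == 15)),
    class = "cueweights_config_error")
})

test_that("pre/post permutation test returns p = 1 for identical phases", {
  d <- judgment_design(repetitions = 2)
  rec <- simulate_study(d, weight_field(), observer_noise(kappa = Inf),
                        n_subjects = 3, subject_sd = 0.1, seed = 6)
  res <- tidy(pre_post_test(aggregate_weights(estimate_trial_weights(rec)),
                            n_perm = 499, seed = 8))
  expect_true(all(res$p_maxt == 1))
  expect_true(all(res$mean_diff == 0))
})

test_that("adjusted p-values dominate raw ones and survive subject relabeling", {
  d <- judgment_design(repetitions = 3)
  rec <- simulate_study(d, weight_field(post_shift = -0.1),
                        observer_noise(kappa = 300), n_subjects = 6,
                        subject_sd = 0.1, seed = 17)
  map <- aggregate_weights(estimate_trial_weights(rec))
  res <- tidy(pre_post_test(map, n_perm = 499, seed = 18))
  expect_true(all(res$p_maxt >= res$p_raw))
  expect_true(all(res$p_raw > 0 & res$p_raw <= 1))

  relabel <- map
  relabel$subject <- dplyr::recode(relabel$subject,
                                   `1` = 4, `2` = 6, `3` = 5,
                                   `4` = 2, `5` = 3, `6` = 1)
  res2 <- tidy(pre_post_test(relabel, n_perm = 499, seed = 18))
  expect_equal(res$p_raw, res2$p_raw)
  expect_equal(res$p_maxt, res2$p_maxt)
})

test_that("single-subject maps yield an insufficient-n warning with NA p-values", {
  d <- judgment_design(repetitions = 2)
  rec <- simulate_study(d, weight_field(), observer_noise(kappa = 200),
                        n_subjects = 1, subject_sd = 0, seed = 3)
  map <- aggregate_weights(estimate_trial_weights(rec))
  expect_warning(res <- pre_post_test(map, n_perm = 199, seed = 4),
                 "fewer than 2 subjects")
  expect_true(all(is.na(tidy(res)$p_raw)))
})
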