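#' Estimate cue weights for every trial record
#'
#' Expands each trial's cue-conflict configuration into texture and
#' disparity normals, converts the perceived slant/tilt into a perceived
#' normal, and solves the constrained vector-sum system per trial. Trials
#' whose weights are unidentifiable (near-parallel cues, or a perceived
#' orientation with undefined tilt) are flagged `degenerate` rather than
#' aborting the batch.
#'
#' @param records A trial-record tibble (see [simulate_study()]): design
#'   columns plus `perceived_slant`, `perceived_tilt`.
#' @param solver `"levenberg_marquardt"` (default; handles percepts off the
#'   cue plane), `"closed_form"` (in-plane percepts only) or
#'   `"pseudoinverse"` (unconstrained least squares).
#' @return `records` with columns `w_t`, `w_d`, `residual_norm`, `method`,
#'   `degenerate`, `converged` appended.
#' @examples
#' d <- judgment_design(repetitions = 1)
#' rec <- simulate_study(d, weight_field(), observer_noise(kappa = Inf),
#'                       n_subjects = 1, subject_sd = 0, seed = 1)
#' estimate_trial_weights(rec)
#' @export
estimate_trial_weights <- function(records,
                                   solver = c("levenberg_marquardt",
                                              "closed_form",
                                              "pseudoinverse")) {
  solver <- match.arg(solver)
  records <- expand_conflict(records)
  need <- c("perceived_slant", "perceived_tilt")
  if (!all(need %in% names(records))) {
    rlang::abort("`records` must contain `perceived_slant` and `perceived_tilt`.",
                 class = "cueweights_config_error")
  }
  nm <- conflict_normals(records)
  tilt <- records$perceived_tilt
  undef <- is.na(tilt) | is.na(records$perceived_slant)
  tilt_f <- ifelse(undef, 0, tilt)
  slant_f <- ifelse(undef, 0, records$perceived_slant)
  n_p <- normal_from_orientation(slant_f, tilt_f)
  est <- switch(solver,
    levenberg_marquardt = weights_constrained(n_p, nm$n_t, nm$n_d),
    closed_form = weights_closed_form(n_p, nm$n_t, nm$n_d),
    pseudoinverse = weights_pseudoinverse(n_p, nm$n_t, nm$n_d))
  est$degenerate <- est$degenerate | undef
  est$w_t[undef] <- NA_real_
  est$w_d[undef] <- NA_real_
  dplyr::bind_cols(records, est)
}

#' Aggregate per-trial weights into a weight map
#'
#' Cell means of the estimated weights over repetitions, per cue
#' configuration cell (`sigma_c`, `tau_c`, `delta_sigma`, `delta_tau`) and
#' phase, either per subject or pooled across subjects. Degenerate trials
#' are excluded from the means and counted in `n_dropped`.
#'
#' @param records Output of [estimate_trial_weights()].
#' @param by `"subject"` (default; one row per subject and cell) or
#'   `"pooled"` (cell means over all trials of all subjects).
#' @return A tibble of class `weight_map` with columns `mean_w_d`,
#'   `mean_w_t`, `sd_w_d`, `n_trials`, `n_dropped` per cell.
#' @examples
#' d <- judgment_design(repetitions = 2)
#' rec <- simulate_study(d, weight_field(), observer_noise(kappa = Inf),
#'                       n_subjects = 2, subject_sd = 0, seed = 1)
#' aggregate_weights(estimate_trial_weights(rec))
#' @export
aggregate_weights <- function(records, by = c("subject", "pooled")) {
  by <- match.arg(by)
  if (!all(c("w_d", "degenerate") %in% names(records))) {
    rlang::abort("run `estimate_trial_weights()` before aggregating.",
                 class = "cueweights_config_error")
  }
  keys <- c("sigma_c", "tau_c", "delta_sigma", "delta_tau")
  if ("phase" %in% names(records)) keys <- c("phase", keys)
  if (by == "subject") {
    if (!"subject" %in% names(records)) {
      rlang::abort('`by = "subject"` needs a `subject` column.',
                   class = "cueweights_config_error")
    }
    keys <- c("subject", keys)
  }
  out <- records %>%
    group_by(across(dplyr::all_of(keys))) %>%
    summarise(
      mean_w_d = mean(.data$w_d[!.data$degenerate]),
      mean_w_t = mean(.data$w_t[!.data$degenerate]),
      sd_w_d = sd(.data$w_d[!.data$degenerate]),
      n_trials = sum(!.data$degenerate),
      n_dropped = sum(.data$degenerate),
      .groups = "drop")
  class(out) <- c("weight_map", class(out))
  attr(out, "by") <- by
  out
}

#' Log-slant trend fit of the disparity weight
#'
#' Ordinary least squares of the cell-mean disparity weight on the natural
#' log of the central slant with additive per-tilt offsets,
#' `mean_w_d ~ log(sigma_c) + factor(tau_c)`, fitted to subject-level cell
#' means. Uncertainty comes from a subject-level nonparametric bootstrap
#' (subjects resampled with replacement, model refitted) with percentile
#' confidence intervals; deterministic under `seed`.
#'
#' @param map A subject-level [aggregate_weights()] weight map (filter to
#'   one phase — typically `"pre"` — before fitting; rows from several
#'   discrepancy conditions are pooled).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level for the percentile intervals (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `trend_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods. `tidy()` returns one row per coefficient
#'   (`intercept`, `slope_logslant`, `tilt_<deg>` offsets) with bootstrap
#'   standard errors and confidence bounds.
#' @examples
#' d <- judgment_design(repetitions = 1)
#' rec <- simulate_study(d, weight_field(), observer_noise(kappa = Inf),
#'                       n_subjects = 3, phases = "pre", subject_sd = 0.05,
#'                       seed = 1)
#' fit <- fit_trend(aggregate_weights(estimate_trial_weights(rec)),
#'                  n_boot = 50, seed = 2)
#' tidy(fit)
#' @export
fit_trend <- function(map, n_boot = 1000, conf = 0.95, seed = NULL) {
  if (!"subject" %in% names(map)) {
    rlang::abort("`fit_trend()` needs a subject-level weight map.",
                 class = "cueweights_config_error")
  }
  if (dplyr::n_distinct(map$sigma_c) < 2) {
    rlang::abort("at least two slant levels are required for a trend fit.",
                 class = "cueweights_config_error")
  }
  df <- data.frame(w = map$mean_w_d, ls = log(map$sigma_c),
                   tau = factor(map$tau_c), subject = map$subject)
  df <- df[is.finite(df$w), , drop = FALSE]
  fit <- lm(w ~ ls + tau, data = df)
  est <- coef(fit)
  names(est) <- rename_trend_coefs(names(est))

  subjects <- unique(df$subject)
  idx_by_subject <- split(seq_len(nrow(df)), df$subject)
  boot <- with_seed_opt(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      rows <- unlist(idx_by_subject[as.character(take)], use.names = FALSE)
      cf <- tryCatch(coef(lm(w ~ ls + tau, data = df[rows, , drop = FALSE])),
                     error = function(e) rep(NA_real_, length(est)))
      if (length(cf) != length(est)) rep(NA_real_, length(est)) else cf
    }, numeric(length(est)))
  })
  boot <- matrix(boot, nrow = length(est))
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  coefs <- tibble(
    term = names(est),
    estimate = unname(est),
    std_error = apply(boot, 1L, sd, na.rm = TRUE),
    conf_low = ci[1L, ],
    conf_high = ci[2L, ])
  structure(list(coefficients = coefs, fit = fit, n_boot = n_boot,
                 conf = conf, seed = seed,
                 n_subjects = length(subjects), n_cells = nrow(df)),
            class = "trend_fit")
}

rename_trend_coefs <- function(x) {
  x <- sub("^\\(Intercept\\)$", "intercept", x)
  x <- sub("^ls$", "slope_logslant", x)
  sub("^tau", "tilt_", x)
}

#' Paired pre/post permutation test of cue reweighting
#'
#' For every cue-configuration cell, computes each subject's post-minus-pre
#' change in the mean disparity weight and tests it against zero with a
#' paired sign-flip permutation test on the one-sample t-statistic. With 14
#' or fewer subjects the full group of \eqn{2^n} sign assignments is
#' enumerated — an exact test whose p-values are deterministic and
#' invariant to subject relabeling; with more subjects, `n_perm` random
#' flips are drawn under `seed`. Familywise error over the 3 x 3
#' (slant x tilt) cell grid of each discrepancy condition is controlled
#' with the max-T method: the adjusted p-value of a cell compares its |t|
#' with the permutation distribution of the maximum |t| over the cells of
#' that condition, so adjusted p-values are never smaller than raw ones.
#'
#' @param map A subject-level weight map containing both phases for every
#'   subject.
#' @param n_perm Number of sign-flip permutations when random sampling is
#'   needed (default 10000; fewer than 100 triggers a warning).
#' @param seed Integer seed for the permutation draws (unused when the flip
#'   group is enumerated exactly; `NULL` uses the current RNG stream).
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   applied to the max-T adjusted p-value).
#' @return An object of class `pre_post_test` with [tidy()], [glance()] and
#'   [autoplot()] methods. `tidy()` returns one row per cell with
#'   `mean_diff`, `t`, `p_raw`, `p_maxt`, `significant`.
#' @examples
#' d <- judgment_design(repetitions = 1)
#' rec <- simulate_study(d, weight_field(post_shift = -0.2),
#'                       observer_noise(kappa = 500), n_subjects = 4,
#'                       subject_sd = 0.05, seed = 1)
#' tidy(pre_post_test(aggregate_weights(estimate_trial_weights(rec)),
#'                    n_perm = 199, seed = 2))
#' @export
pre_post_test <- function(map, n_perm = 10000, seed = NULL, alpha = 0.05) {
  if (!all(c("subject", "phase") %in% names(map))) {
    rlang::abort("`pre_post_test()` needs a subject-level weight map with a `phase` column.",
                 class = "cueweights_config_error")
  }
  if (!all(c("pre", "post") %in% unique(map$phase))) {
    rlang::abort("both phases ('pre', 'post') must be present.",
                 class = "cueweights_config_error")
  }
  if (n_perm < 100) {
    rlang::warn("`n_perm` < 100 gives a very coarse permutation p-value.")
  }
  wide <- map %>%
    select(dplyr::all_of(c("subject", "phase", "sigma_c", "tau_c",
                           "delta_sigma", "delta_tau", "mean_w_d"))) %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "mean_w_d") %>%
    mutate(diff = .data$post - .data$pre)

  n_sub <- dplyr::n_distinct(wide$subject)
  conds <- distinct(wide, .data$delta_sigma, .data$delta_tau)
  if (n_sub < 2) {
    rlang::warn("fewer than 2 subjects: pre/post permutation test is not identified; p-values set to NA.")
  }

  res <- purrr::pmap(conds, function(delta_sigma, delta_tau) {
    sub <- wide %>%
      filter(.data$delta_sigma == !!delta_sigma,
             .data$delta_tau == !!delta_tau) %>%
      arrange(.data$sigma_c, .data$tau_c, .data$subject)
    cells <- distinct(sub, .data$sigma_c, .data$tau_c)
    D <- matrix(sub$diff, nrow = n_sub)   # subjects x cells
    out <- cells
    out$delta_sigma <- delta_sigma
    out$delta_tau <- delta_tau
    out$mean_diff <- colMeans(D)
    if (n_sub < 2 || anyNA(D)) {
      out$t <- NA_real_; out$p_raw <- NA_real_; out$p_maxt <- NA_real_
      return(out)
    }
    p <- signflip_maxt(D, n_perm, seed)
    out$t <- p$t_obs
    out$p_raw <- p$p_raw
    out$p_maxt <- p$p_maxt
    out
  })
  res <- dplyr::bind_rows(res) %>%
    mutate(significant = !is.na(.data$p_maxt) & .data$p_maxt < alpha) %>%
    select(dplyr::all_of(c("delta_sigma", "delta_tau", "sigma_c", "tau_c",
                           "mean_diff", "t", "p_raw", "p_maxt", "significant")))
  structure(list(cells = res, n_perm = n_perm, n_subjects = n_sub,
                 seed = seed, alpha = alpha,
                 exact = n_sub >= 2 && n_sub <= 14),
            class = "pre_post_test")
}

# Sign-flip permutation of one-sample t statistics, with max-T familywise
# adjustment across the columns of D (subjects x cells). With up to 14
# subjects the full 2^n flip group is enumerated (an exact test, invariant
# to subject relabeling); beyond that, n_perm random flips are drawn and the
# observed assignment is counted among them (add-one convention).
signflip_maxt <- function(D, n_perm, seed = NULL) {
  n <- nrow(D); m <- ncol(D)
  ss <- colSums(D^2)
  t_obs <- {
    m_d <- colMeans(D)
    v <- (ss - n * m_d^2) / (n - 1)
    t0 <- m_d / sqrt(pmax(v, 0) / n)
    t0[v <= 0 & m_d == 0] <- 0
    t0
  }
  exact <- n <= 14L
  if (exact) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    denom <- nrow(S)
    extra <- 0
  } else {
    S <- with_seed_opt(seed,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm))
    denom <- n_perm + 1
    extra <- 1
  }
  M <- (S %*% D) / n                       # permuted means: draws x m
  V <- sweep(-n * M^2, 2L, ss, "+") / (n - 1)
  Tp <- abs(M) / sqrt(pmax(V, 1e-300) / n)
  Tp[V <= 0 & M == 0] <- 0
  abs_obs <- abs(t_obs)
  # compare with a hair of slack so the identity flip always counts itself
  ge <- sweep(Tp, 2L, abs_obs - 1e-9, ">=")
  p_raw <- (extra + colSums(ge)) / denom
  maxT <- apply(Tp, 1L, max)
  p_maxt <- vapply(abs_obs, function(a) (extra + sum(maxT >= a - 1e-9)) / denom,
                   numeric(1))
  list(t_obs = t_obs, p_raw = p_raw, p_maxt = pmax(p_maxt, p_raw),
       exact = exact, n_draws = nrow(S))
}
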