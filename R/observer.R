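#' Generative disparity-weight field
#'
#' The synthetic observer's disparity weight varies smoothly over the
#' conflict-centre parameter space:
#' \deqn{w_d(\sigma_c, \tau_c) = \beta_0 + \beta_\sigma \log\sigma_c +
#'   \beta_\tau \tau_c + \beta_{\sigma\tau}\, \tau_c \log\sigma_c
#'   \;(+\; \delta_{post}),}
#' with \eqn{\sigma_c} in degrees (natural log), \eqn{\tau_c} in degrees,
#' and an additive `post_shift` \eqn{\delta_{post}} applied in the post
#' phase of the designated joint-control (ATD) training condition. The
#' default preset has a negative log-slant slope (disparity down-weighted at
#' steeper slants) and a positive tilt gain (disparity up-weighted as the
#' tilt rotates toward vertical), the qualitative structure the analysis is
#' designed to recover; the magnitudes are package choices for simulation,
#' not measured values.
#'
#' @param intercept Baseline disparity weight at \eqn{\log\sigma_c = 0}.
#' @param slope_logslant Change in `w_d` per unit `log(sigma_c)` (negative by
#'   default).
#' @param tilt_gain Change in `w_d` per degree of central tilt (positive by
#'   default).
#' @param interaction Tilt-by-log-slant interaction (default 0).
#' @param post_shift Additive change applied in the post phase for the
#'   joint-control training group (negative = reweighting toward texture).
#' @return A list of class `weight_field`.
#' @examples
#' f <- weight_field()
#' predict_wd(f, sigma_c = c(15, 35), tau_c = c(0, 90))
#' @export
weight_field <- function(intercept = 1.9, slope_logslant = -0.35,
                         tilt_gain = 0.003, interaction = 0,
                         post_shift = 0) {
  for (nm in c("intercept", "slope_logslant", "tilt_gain", "interaction",
               "post_shift")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  structure(list(intercept = intercept, slope_logslant = slope_logslant,
                 tilt_gain = tilt_gain, interaction = interaction,
                 post_shift = post_shift),
            class = "weight_field")
}

#' @rdname weight_field
#' @param field A [weight_field()].
#' @param sigma_c,tau_c Conflict-centre slant and tilt in degrees.
#' @param phase `"pre"` or `"post"`.
#' @param group Training group; `post_shift` applies only to `"ATD"`.
#' @export
predict_wd <- function(field, sigma_c, tau_c, phase = "pre", group = "ATD") {
  stopifnot(inherits(field, "weight_field"))
  abort_if(sigma_c <= 0, "`sigma_c` must be positive for the log-slant field.",
           class = "cueweights_domain_error")
  ls <- log(sigma_c)
  w <- field$intercept + field$slope_logslant * ls +
    field$tilt_gain * tau_c + field$interaction * tau_c * ls
  shift <- ifelse(phase == "post" & group == "ATD", field$post_shift, 0)
  w + shift
}

#' Directional response noise of the synthetic observer
#'
#' Perceived normals are drawn from a von Mises-Fisher distribution on the
#' unit sphere centred on the model-predicted normal, with concentration
#' `kappa` (larger = less noisy; the angular standard deviation is roughly
#' \eqn{1/\sqrt{\kappa}} radians). `kappa = Inf` gives noiseless responses.
#'
#' @param kappa Concentration parameter (> 0, may be `Inf`).
#' @param seed Optional integer seed attached to the noise model.
#' @return A list of class `observer_noise`.
#' @export
observer_noise <- function(kappa = 200, seed = NULL) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa <= 0) {
    rlang::abort("`kappa` must be a single positive number (Inf allowed).",
                 class = "cueweights_config_error")
  }
  structure(list(kappa = kappa, seed = seed), class = "observer_noise")
}

#' Observer presets for the three training conditions
#'
#' Bundles a [weight_field()] and [observer_noise()] emulating each training
#' group: the joint-control group (`"ATD"`, both cues manipulated with the
#' conflict held invariant) carries a negative `post_shift` — a post-training
#' reweighting toward texture — while the single-cue control groups (`"AT"`,
#' `"AD"`) carry no shift.
#'
#' @param group One of `"ATD"`, `"AT"`, `"AD"`.
#' @param kappa Response-noise concentration (default 200).
#' @return A list with elements `group`, `field`, `noise`.
#' @examples
#' observer_preset("ATD")$field$post_shift
#' @export
observer_preset <- function(group = c("ATD", "AT", "AD"), kappa = 200) {
  group <- match.arg(group)
  shift <- if (group == "ATD") -0.15 else 0
  list(group = group,
       field = weight_field(post_shift = shift),
       noise = observer_noise(kappa = kappa))
}

#' Model-predicted perceived normal for a cue-conflict configuration
#'
#' Evaluates the weight field at each configuration's conflict centre to get
#' the disparity weight, chooses the texture weight so the pair lies on the
#' conflict ellipse (the combined vector has unit norm), and returns the
#' combined normal \eqn{w_t n_t + w_d n_d}. Of the two ellipse points with
#' the given \eqn{w_d}, the one with the larger \eqn{w_t} is taken, so the
#' predicted normal lies on the texture side of the disparity normal and
#' moves continuously from \eqn{n_t} (at \eqn{w_d = 0}) to \eqn{n_d} (at
#' \eqn{w_d = 1}).
#'
#' @param field A [weight_field()].
#' @param configs Data frame of cue-conflict configurations (see
#'   [expand_conflict()]).
#' @param phase `"pre"` or `"post"` (vector or scalar).
#' @param group Training group (`post_shift` applies to `"ATD"` only).
#' @param wd_offset Optional additive offset on the disparity weight
#'   (e.g. a per-subject intercept), scalar or per-row vector.
#' @return An n x 3 matrix of unit normals.
#' @examples
#' cfg <- data.frame(sigma_c = 25, tau_c = 45, delta_sigma = 30, delta_tau = 0)
#' predicted_normal(weight_field(), cfg)
#' @export
predicted_normal <- function(field, configs, phase = "pre", group = "ATD",
                             wd_offset = 0) {
  configs <- expand_conflict(configs)
  nm <- conflict_normals(configs)
  w_d <- predict_wd(field, configs$sigma_c, configs$tau_c, phase, group) + wd_offset
  g <- rowSums(nm$n_t * nm$n_d)
  disc <- 1 + w_d^2 * (g^2 - 1)
  abort_if(disc < 0,
           "requested disparity weight admits no texture weight on the conflict ellipse.",
           class = "cueweights_config_error")
  w_t <- -g * w_d + sqrt(disc)
  w_t * nm$n_t + w_d * nm$n_d
}

#' Draw perceived normals with von Mises-Fisher noise
#'
#' Samples one unit vector per row of `n_model` from a von Mises-Fisher
#' distribution with mean direction the model normal and concentration
#' `noise$kappa`. Sampling uses the exact inverse-CDF of the cosine of the
#' angular deviation (closed form on the 2-sphere) and is fully vectorised
#' and reproducible under a fixed seed.
#'
#' @param n_model An n x 3 matrix (or length-3 vector) of mean directions.
#' @param noise An [observer_noise()]; its `seed` (if any) is used unless
#'   `seed` is given.
#' @param seed Optional integer seed overriding `noise$seed`.
#' @return An n x 3 matrix of unit normals.
#' @examples
#' sample_perceived(c(0, 0, 1), observer_noise(kappa = 50, seed = 1))
#' @export
sample_perceived <- function(n_model, noise, seed = NULL) {
  stopifnot(inherits(noise, "observer_noise"))
  mu <- check_unit_rows(as_normal_matrix(n_model, "n_model"), "n_model")
  if (!is.finite(noise$kappa)) return(mu)
  if (is.null(seed)) seed <- noise$seed
  with_seed_opt(seed, rvmf_rows(mu, noise$kappa))
}

# vectorised vMF sampler on S^2: exact inverse-CDF for the cosine w
# (density of w on [-1, 1] proportional to exp(kappa * w))
rvmf_rows <- function(mu, kappa) {
  n <- nrow(mu)
  u <- runif(n)
  # w = 1 + log(u + (1 - u) exp(-2 kappa)) / kappa, computed stably
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- clamp(w, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  # tangent basis at mu (use x-axis helper where mu is near +-z)
  near_z <- abs(mu[, 3]) > 0.99
  a <- cbind(ifelse(near_z, 1, 0), 0, ifelse(near_z, 0, 1))
  t1 <- cross3(a, mu)
  t1 <- normalize_rows(t1)
  t2 <- cross3(mu, t1)
  s <- sqrt(pmax(1 - w^2, 0))
  w * mu + s * (cos(phi) * t1 + sin(phi) * t2)
}

#' Touchpad adjustment dynamics
#'
#' Replays the touch-to-orientation mapping of the adjustment task: a touch
#' at radial distance greater than `trigger_radius` from the touchpad centre
#' (coordinates in \eqn{[-1, 1]^2}) sets the surface tilt to the touch angle
#' (two-argument arctangent of `(y, x)`, so opposite touch directions give
#' opposite tilts) and advances the slant by `slant_step` degrees along that
#' tilt direction; touches inside the trigger radius leave the surface
#' unchanged.
#'
#' @param touch_stream Data frame (or 2-column matrix) of touch coordinates
#'   `x`, `y` in `[-1, 1]`, one row per frame.
#' @param start_slant,start_tilt Initial surface orientation (degrees).
#' @param trigger_radius Radial distance activating an adjustment
#'   (default 0.7).
#' @param slant_step Slant increment per active frame, degrees (default 0.1).
#' @param slant_max Upper clamp on slant, degrees (default 89.9).
#' @return A tibble with one row per frame: `frame`, `x`, `y`, `active`,
#'   `slant`, `tilt`.
#' @examples
#' simulate_adjustment(data.frame(x = c(0.3, 0.5, 0), y = c(0.3, 0.5, 0.9)))
#' @export
simulate_adjustment <- function(touch_stream, start_slant = 0, start_tilt = 0,
                                trigger_radius = 0.7, slant_step = 0.1,
                                slant_max = 89.9) {
  ts <- as.data.frame(touch_stream)
  if (is.null(ts$x) || is.null(ts$y)) {
    ts <- as.data.frame(as.matrix(touch_stream))
    names(ts)[1:2] <- c("x", "y")
  }
  abort_if(abs(ts$x) > 1 | abs(ts$y) > 1,
           "touch coordinates must lie in [-1, 1].",
           class = "cueweights_validation_error")
  r <- sqrt(ts$x^2 + ts$y^2)
  active <- r > trigger_radius
  n <- nrow(ts)
  slant <- numeric(n); tilt <- numeric(n)
  cur_s <- start_slant; cur_t <- wrap360(start_tilt)
  for (i in seq_len(n)) {
    if (active[i]) {
      cur_t <- wrap360(rad2deg(atan2(ts$y[i], ts$x[i])))
      cur_s <- clamp(cur_s + slant_step, 0, slant_max)
    }
    slant[i] <- cur_s; tilt[i] <- cur_t
  }
  tibble(frame = seq_len(n), x = ts$x, y = ts$y, active = active,
         slant = slant, tilt = tilt)
}

#' Simulate a full pre/post judgment study
#'
#' Generates one trial record per design row, per subject, per phase: the
#' weight field (plus a Gaussian per-subject intercept on the disparity
#' weight) fixes the model-predicted normal for each configuration, von
#' Mises-Fisher noise perturbs it, and the perceived orientation is recorded
#' as slant/tilt. Deterministic for a fixed `seed`.
#'
#' @param design A judgment trial table from [judgment_design()] (columns
#'   `sigma_c`, `tau_c`, `delta_sigma`, `delta_tau`, `repetition`).
#' @param field A [weight_field()].
#' @param noise An [observer_noise()].
#' @param n_subjects Number of simulated subjects.
#' @param group Training group label recorded on each trial; the field's
#'   `post_shift` applies in the post phase only for `"ATD"`.
#' @param phases Character vector of phases to simulate.
#' @param subject_sd Standard deviation of the per-subject additive intercept
#'   on `w_d` (default 0.1; 0 for homogeneous subjects).
#' @param seed Integer seed for subject effects and response noise.
#' @return A tibble of trial records: `subject`, `group`, `phase`, the design
#'   columns, and `perceived_slant`, `perceived_tilt` (degrees).
#' @examples
#' d <- judgment_design(repetitions = 1)
#' simulate_study(d, weight_field(), observer_noise(kappa = Inf),
#'                n_subjects = 2, subject_sd = 0, seed = 1)
#' @export
simulate_study <- function(design, field, noise = observer_noise(),
                           n_subjects = 10, group = "ATD",
                           phases = c("pre", "post"), subject_sd = 0.1,
                           seed = NULL) {
  stopifnot(inherits(field, "weight_field"), inherits(noise, "observer_noise"))
  if (n_subjects < 1) {
    rlang::abort("`n_subjects` must be >= 1.", class = "cueweights_config_error")
  }
  design <- expand_conflict(design)
  nm <- conflict_normals(design)
  g <- rowSums(nm$n_t * nm$n_d)
  n_cfg <- nrow(design)

  with_seed_opt(seed, {
    subj_int <- rnorm(n_subjects, 0, subject_sd)
    blocks <- vector("list", length(phases) * n_subjects)
    k <- 0L
    for (ph in phases) {
      w_d_base <- predict_wd(field, design$sigma_c, design$tau_c, ph, group)
      for (s in seq_len(n_subjects)) {
        w_d <- w_d_base + subj_int[s]
        disc <- 1 + w_d^2 * (g^2 - 1)
        abort_if(disc < 0,
                 "simulated disparity weight leaves the conflict ellipse; reduce `subject_sd` or the field magnitudes.",
                 class = "cueweights_config_error")
        w_t <- -g * w_d + sqrt(disc)
        n_mod <- w_t * nm$n_t + w_d * nm$n_d
        n_per <- if (is.finite(noise$kappa)) rvmf_rows(n_mod, noise$kappa) else n_mod
        ori <- orientation_from_normal(normalize_rows(n_per))
        k <- k + 1L
        blocks[[k]] <- dplyr::bind_cols(
          tibble(subject = s, group = group, phase = ph),
          design,
          tibble(perceived_slant = ori$slant, perceived_tilt = ori$tilt)
        )
      }
    }
    dplyr::bind_rows(blocks)
  })
}
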