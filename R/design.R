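#' Factorial trial table for the perceptual judgment task
#'
#' Crosses three central slants (15, 25, 35 degrees) with three central
#' tilts (0, 45, 90 degrees) and two cue-discrepancy conditions
#' (`[delta_sigma = 30, delta_tau = 0]` and `[30, 45]`): 18 distinct
#' cue-conflict configurations, each repeated `repetitions` times (90 trials
#' at the default 5 repetitions). Trial order is a uniform random
#' permutation when a `seed` is given, design order otherwise.
#'
#' @param repetitions Repetitions per configuration (>= 1, default 5).
#' @param seed Optional integer seed for trial-order randomization.
#' @return A tibble with columns `trial`, `task`, `sigma_c`, `tau_c`,
#'   `delta_sigma`, `delta_tau`, `repetition`.
#' @examples
#' nrow(judgment_design())            # 90
#' nrow(judgment_design(repetitions = 1))
#' @export
judgment_design <- function(repetitions = 5, seed = NULL) {
  if (!is.numeric(repetitions) || repetitions < 1 ||
      repetitions != round(repetitions)) {
    rlang::abort("`repetitions` must be a positive integer.",
                 class = "cueweights_config_error")
  }
  disc <- tibble(delta_sigma = c(30, 30), delta_tau = c(0, 45))
  configs <- tidyr::crossing(sigma_c = c(15, 25, 35),
                             tau_c = c(0, 45, 90),
                             disc)
  out <- tidyr::crossing(configs, repetition = seq_len(repetitions))
  ord <- with_seed_opt(seed, if (is.null(seed)) seq_len(nrow(out)) else
    sample.int(nrow(out)))
  out <- out[ord, ]
  out %>%
    mutate(trial = dplyr::row_number(), task = "judgment",
           .before = 1L)
}

#' Trial tables for the visuomotor training conditions
#'
#' Builds the training-phase trial tables of the direction-alignment task.
#' In the joint-control condition (`"ATD"`) both cue planes move together
#' with a fixed tilt discrepancy of +/-45 or +/-90 degrees (4 levels), for
#' each of 2 target-axis positions and 3 repetitions — 24 trials; the slant
#' discrepancy is carried at 30 degrees. In the single-control conditions
#' (`"AT"`: texture moves, disparity fixed; `"AD"`: the reverse) the fixed
#' cue plane takes one of 3 slants (15, 25, 35) and 8 tilts (0 to 315 in
#' 45-degree steps), for each of 2 target positions — 48 trials.
#'
#' @param group One of `"ATD"`, `"AT"`, `"AD"`.
#' @param seed Optional integer seed for trial-order randomization.
#' @return A tibble with columns `trial`, `task`, `group`, `target_axis`
#'   (degrees; the two diametral target placements, 45 or 135), `repetition`,
#'   and either `delta_sigma`/`delta_tau` (ATD) or `sigma_fixed`/`tau_fixed`
#'   (AT, AD).
#' @examples
#' nrow(training_design("ATD"))   # 24
#' nrow(training_design("AT"))    # 48
#' @export
training_design <- function(group, seed = NULL) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% c("ATD", "AT", "AD")) {
    rlang::abort('`group` must be one of "ATD", "AT", "AD".',
                 class = "cueweights_config_error")
  }
  if (group == "ATD") {
    out <- tidyr::crossing(delta_tau = c(-90, -45, 45, 90),
                           target_axis = c(45, 135),
                           repetition = 1:3) %>%
      mutate(delta_sigma = 30)
  } else {
    out <- tidyr::crossing(sigma_fixed = c(15, 25, 35),
                           tau_fixed = seq(0, 315, by = 45),
                           target_axis = c(45, 135)) %>%
      mutate(repetition = 1L)
  }
  ord <- with_seed_opt(seed, if (is.null(seed)) seq_len(nrow(out)) else
    sample.int(nrow(out)))
  out <- out[ord, ]
  out %>%
    mutate(trial = dplyr::row_number(), task = "training", group = group,
           .before = 1L)
}
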