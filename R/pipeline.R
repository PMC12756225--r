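#' Run configuration for the end-to-end pipeline
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. All angles are degrees; all seeds are integers; every
#' stochastic stage derives its own child seed from `seed`, so a re-run with
#' the same configuration is bit-identical.
#'
#' @param seed Study-level integer seed.
#' @param group Training group simulated (`"ATD"`, `"AT"`, `"AD"`).
#' @param n_subjects Simulated subjects (default 10).
#' @param repetitions Judgment-design repetitions per configuration
#'   (default 5).
#' @param kappa Observer noise concentration (default 200).
#' @param subject_sd Per-subject intercept standard deviation (default 0.1).
#' @param n_perm Permutations for the pre/post test (default 10000).
#' @param n_boot Bootstrap replicates for the trend fit (default 1000).
#' @param field Optional [weight_field()] override; by default the
#'   [observer_preset()] field for `group`.
#' @param viewing Optional [viewing_geometry()] recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, group = "ATD", n_subjects = 10,
                       repetitions = 5, kappa = 200, subject_sd = 0.1,
                       n_perm = 10000, n_boot = 1000, field = NULL,
                       viewing = viewing_geometry()) {
  preset <- observer_preset(group, kappa = kappa)
  if (is.null(field)) field <- preset$field
  stopifnot(inherits(field, "weight_field"),
            inherits(viewing, "viewing_geometry"))
  structure(list(seed = as.integer(seed), group = preset$group,
                 n_subjects = n_subjects, repetitions = repetitions,
                 kappa = kappa, subject_sd = subject_sd,
                 n_perm = n_perm, n_boot = n_boot,
                 field = field, viewing = viewing),
            class = "run_config")
}

#' Read and write run configurations and presets as JSON
#'
#' @param config A [run_config()] (or [weight_field()] for the preset
#'   writers).
#' @param path File path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `read_weight_field()` a `weight_field`. Writers return `path`
#'   invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$field <- unclass(x$field)
  x$viewing <- unclass(x$viewing)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(seed = x$seed, group = x$group, n_subjects = x$n_subjects,
             repetitions = x$repetitions, kappa = x$kappa,
             subject_sd = x$subject_sd, n_perm = x$n_perm,
             n_boot = x$n_boot,
             field = do.call(weight_field, as.list(x$field)),
             viewing = do.call(viewing_geometry, as.list(x$viewing)))
}

#' @rdname write_run_config
#' @param field A [weight_field()].
#' @export
write_weight_field <- function(field, path) {
  stopifnot(inherits(field, "weight_field"))
  jsonlite::write_json(unclass(field), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_weight_field <- function(path) {
  do.call(weight_field, as.list(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' Read and write trial-record tables
#'
#' CSV schema (comma-separated, UTF-8, header row, `.` decimal): one row per
#' trial with columns `subject`, `group`, `phase`, `trial`, `task`,
#' `sigma_c`, `tau_c`, `delta_sigma`, `delta_tau`, `repetition`,
#' `perceived_slant`, `perceived_tilt` — all angles in degrees.
#'
#' @param records A trial-record tibble.
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run the full synthetic-study pipeline
#'
#' Executes design -> simulate -> estimate -> aggregate -> trend fit ->
#' pre/post test for one training group, writes every table as CSV into
#' `out_dir`, and returns a manifest (also written as JSON) recording the
#' configuration, child seeds, output files and their MD5 checksums.
#' Re-running the same configuration reproduces identical checksums. If a
#' stage fails, the manifest records the completed stages and the failure
#' instead of aborting silently.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (a list; also saved as `manifest.json`).
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 7, n_subjects = 3, repetitions = 2,
#'                   n_perm = 499, n_boot = 100)
#' m <- run_pipeline(cfg, tempfile("run"))
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(design = derive_seed(config$seed, 1L),
                study = derive_seed(config$seed, 2L),
                trend = derive_seed(config$seed, 3L),
                perm = derive_seed(config$seed, 4L))
  manifest <- list(package_version = as.character(utils::packageVersion("cueweights")),
                   config = jsonlite::fromJSON(jsonlite::toJSON(
                     list(seed = config$seed, group = config$group,
                          n_subjects = config$n_subjects,
                          repetitions = config$repetitions,
                          kappa = config$kappa, subject_sd = config$subject_sd,
                          n_perm = config$n_perm, n_boot = config$n_boot,
                          field = unclass(config$field),
                          viewing = unclass(config$viewing)),
                     auto_unbox = TRUE, digits = NA)),
                   seeds = seeds, stages = character(), files = list(),
                   failure = NULL)
  paths <- character()
  emit <- function(name, tbl) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, p)
    paths[[name]] <<- p
    manifest$stages <<- c(manifest$stages, name)
  }
  result <- tryCatch({
    design <- judgment_design(config$repetitions, seed = seeds$design)
    emit("design", design)
    records <- simulate_study(design, config$field,
                              observer_noise(config$kappa),
                              n_subjects = config$n_subjects,
                              group = config$group,
                              subject_sd = config$subject_sd,
                              seed = seeds$study)
    emit("trials", records)
    est <- estimate_trial_weights(records)
    emit("trial_weights", est)
    map <- aggregate_weights(est)
    emit("weight_map", as_tibble(map))
    trend <- fit_trend(dplyr::filter(map, .data$phase == "pre"),
                       n_boot = config$n_boot, seed = seeds$trend)
    emit("trend_fit", tidy(trend))
    pp <- pre_post_test(map, n_perm = config$n_perm, seed = seeds$perm)
    emit("pre_post", tidy(pp))
    TRUE
  }, error = function(e) {
    manifest$failure <<- list(stage_after = utils::tail(manifest$stages, 1L),
                              message = conditionMessage(e))
    FALSE
  })
  manifest$completed <- result
  manifest$files <- lapply(paths, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
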