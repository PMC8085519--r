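#' Default run configuration
#'
#' A single configuration list governs all pipeline stages; every
#' tunable default of the package appears here so no constant is buried
#' in code. Serialize with [write_config()] and load with
#' [read_config()].
#'
#' @return A named list: `spans`, `sparc` (padlevel, f_max,
#'   amp_threshold), `noise` (peak_mean, bandwidth), `alpha`,
#'   `transforms` (sparc_log, pks_offset), `grs_subscores`, `broadcast`,
#'   `tukey_method`, `peak_prominence`, `seed`, and `cohort` (the
#'   [cohort_spec()] fields).
#' @export
default_config <- function() {
  list(
    spans = c(5L, 25L, 51L, 101L, 201L),
    sparc = list(padlevel = 4, f_max = 10, amp_threshold = 0.05),
    noise = list(peak_mean = 0.06, peak_cv = 0.3, bandwidth = 15),
    alpha = 0.05,
    transforms = list(sparc_log = TRUE, pks_offset = 1),
    grs_subscores = c("needle_holding", "needle_movement",
                      "flashback_quality", "overall_quality"),
    broadcast = TRUE,
    tukey_method = "pooled",
    peak_prominence = 0,
    seed = 1,
    cohort = list(n_participants = 52, trials_per_participant = 16,
                  fs = 100, skill_mean = 0.7, skill_sd = 0.2,
                  skin_z = 0,
                  effect_map = list(submovement_rate = 6, pause_scale = 0.5,
                                    flash_interrupt_max = 0.6,
                                    flash_delay_max = 0.5,
                                    trial_skill_sd = 0.2,
                                    grs_noise_sd = 2.0,
                                    exp_skill_weight = 0.1))
  )
}

.validate_config <- function(config) {
  if (any(config$spans %% 2 != 1) || any(config$spans < 5))
    .stopf("config error: spans must all be odd and >= 5 (got %s)",
           paste(config$spans, collapse = ", "), class = "config_error")
  if (config$alpha <= 0 || config$alpha >= 1)
    .stopf("config error: alpha must lie in (0, 1)", class = "config_error")
  invisible(config)
}

#' Write a configuration template to JSON
#' @param path output path.
#' @param config configuration list (default [default_config()]).
#' @return Invisibly, `path`.
#' @export
write_config <- function(path, config = default_config()) {
  .validate_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a JSON configuration
#'
#' Missing fields fall back to [default_config()]; invalid values (even
#' spans, alpha outside (0, 1)) raise a `config_error` before any I/O.
#'
#' @param path JSON path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  config <- utils::modifyList(default_config(), user)
  .validate_config(config)
  config
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Generates the synthetic cohort described by `config$cohort` and
#' writes it (trial CSV/JSON pairs, participants table, latent-skill
#' ground truth, manifest with checksums) to `out_dir`.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, the cohort object.
#' @export
run_simulate <- function(config = default_config(), out_dir,
                         seed = NULL) {
  .validate_config(config)
  if (is.null(seed)) seed <- config$seed
  cs <- config$cohort
  spec <- cohort_spec(n_participants = cs$n_participants,
                      trials_per_participant = cs$trials_per_participant,
                      fs = cs$fs, skill_mean = cs$skill_mean,
                      skill_sd = cs$skill_sd,
                      noise_peak_mean = config$noise$peak_mean,
                      noise_peak_cv = config$noise$peak_cv,
                      noise_bandwidth = config$noise$bandwidth,
                      effect_map = cs$effect_map, skin_z = cs$skin_z)
  cohort <- simulate_cohort(spec, seed = seed)
  write_cohort(cohort, out_dir)
  invisible(cohort)
}

#' Pipeline stage: compute the metrics table from a trial directory
#'
#' Reads every trial in `trials_dir`, computes all process metrics at
#' every configured window span, and writes the tidy metrics CSV.
#' Corrupt or unusable trials are logged to `exclusions.csv` next to
#' the output and the run continues.
#'
#' @param config configuration list.
#' @param trials_dir directory of trial CSV/JSON pairs.
#' @param out_csv output metrics CSV path.
#' @return Invisibly, the metrics data.frame.
#' @export
run_compute <- function(config = default_config(), trials_dir, out_csv) {
  .validate_config(config)
  csvs <- sort(setdiff(list.files(trials_dir, pattern = "\\.csv$",
                                  full.names = TRUE),
                       file.path(trials_dir,
                                 c("participants.csv", "latent_skill.csv"))))
  if (!length(csvs))
    .stopf("no trial files found in '%s'", trials_dir,
           class = "validation_error")
  trials <- list(); excl <- list()
  for (f in csvs) {
    tr <- tryCatch(read_trial(f), error = function(e) e)
    if (inherits(tr, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(
        trial_id = basename(f), reason = conditionMessage(tr),
        stringsAsFactors = FALSE)
      message(sprintf("excluding %s: %s", basename(f),
                      conditionMessage(tr)))
    } else trials[[length(trials) + 1L]] <- tr
  }
  metrics <- compute_metrics(trials, spans = config$spans,
                             sparc_args = config$sparc,
                             peak_prominence = config$peak_prominence)
  ex <- rbind(if (length(excl)) do.call(rbind, excl),
              attr(metrics, "exclusions"))
  write_metrics_table(metrics, out_csv)
  utils::write.csv(ex, file.path(dirname(out_csv), "exclusions.csv"),
                   row.names = FALSE)
  invisible(metrics)
}

#' Pipeline stage: run the association analysis and write the report
#'
#' Loads the metrics table and the participants table, fits
#' [skill_assoc()] and writes the report CSVs + JSON summary via
#' [write_report()]. Deterministic given its inputs.
#'
#' @param config configuration list.
#' @param metrics_csv metrics table path (from [run_compute()]).
#' @param participants_csv participants table path (from
#'   [run_simulate()]'s output directory).
#' @param out_dir report directory.
#' @return Invisibly, the `"skill_assoc"` fit.
#' @export
run_analyze <- function(config = default_config(), metrics_csv,
                        participants_csv, out_dir) {
  .validate_config(config)
  metrics <- read_metrics_table(metrics_csv)
  participants <- utils::read.csv(participants_csv,
                                  colClasses = c(participant_id = "character"))
  fit <- skill_assoc(metrics, participants,
                     grs_subscores = config$grs_subscores,
                     broadcast = config$broadcast,
                     sparc_log = config$transforms$sparc_log,
                     pks_offset = config$transforms$pks_offset)
  write_report(fit, out_dir, alpha = config$alpha,
               method = config$tukey_method)
  invisible(fit)
}
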