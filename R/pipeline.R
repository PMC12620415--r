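#' Default run configuration
#'
#' One flat configuration list drives the end-to-end pipeline. Every field
#' has a documented default; [validate_config()] rejects unknown keys before
#' any computation.
#'
#' Fields (and defaults):
#' * `mode` — cohort mode, `"statistical"` (default) or `"mechanistic"`.
#' * `sizes` — group sizes, `c(30, 30, 30)`.
#' * `seed` — master seed, 1.
#' * `threshold` — fixed TAWSS decision threshold, 27.0 dyn/cm^2.
#' * `dt` — solver time step, 1e-3 s; `min_cycles` 6; `max_cycles` 20;
#'   `periodicity_tol` 0.005.
#' * `systolic_fraction` — inflow systole fraction, 0.35; `n_samples` 1000.
#' * `murray_exponent` — resistance distribution exponent, 2.25.
#' * `rp_fraction` — proximal Windkessel resistance share, 0.1.
#' * `tolerance` — tuning tolerance, 0.02; `max_iterations` 20.
#' * `n_generations` — tree generations (mechanistic mode), 3.
#' * `scope` — proximal aggregation scope, `c("MPA", "LPA", "RPA")`.
#' * `output_dir` — where [run_pipeline()] writes artifacts.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    mode = "statistical",
    sizes = c(30, 30, 30),
    seed = 1L,
    threshold = 27.0,
    dt = 1e-3,
    min_cycles = 6,
    max_cycles = 20,
    periodicity_tol = 0.005,
    systolic_fraction = 0.35,
    n_samples = 1000,
    murray_exponent = 2.25,
    rp_fraction = 0.1,
    tolerance = 0.02,
    max_iterations = 20,
    n_generations = 3,
    scope = c("MPA", "LPA", "RPA"),
    output_dir = "pawss-run"
  )
}

#' Validate and complete a run configuration
#'
#' Merges user settings over [default_config()]; any key not present in the
#' defaults is rejected.
#'
#' @param config A named list of overrides (possibly read with
#'   [read_config()]).
#' @return The completed configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- utils::modifyList(defaults, config)
  if (!out$mode %in% c("statistical", "mechanistic")) {
    stop("config `mode` must be 'statistical' or 'mechanistic'", call. = FALSE)
  }
  out
}

#' @rdname validate_config
#' @param path A YAML configuration file.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the end-to-end pipeline
#'
#' Generates a cohort under the configuration, runs the diagnostic
#' statistics, and writes the artifacts to `config$output_dir`: the cohort
#' CSV, the diagnostics JSON report with ROC coordinates, and a config/seed
#' echo. Identical configurations produce byte-identical cohort CSVs.
#'
#' @param config A configuration list (see [default_config()]); validated
#'   with [validate_config()] before any computation.
#' @return Invisibly, a list with `cohort`, `diagnostics` and `paths`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- generate_cohort(
    mode = cfg$mode, sizes = cfg$sizes, seed = cfg$seed,
    n_generations = cfg$n_generations,
    solver = list(
      dt = cfg$dt, min_cycles = cfg$min_cycles,
      max_cycles = cfg$max_cycles, periodicity_tol = cfg$periodicity_tol
    ),
    tuning = list(
      tolerance = cfg$tolerance, max_iterations = cfg$max_iterations,
      rp_fraction = cfg$rp_fraction, exponent = cfg$murray_exponent,
      systolic_fraction = cfg$systolic_fraction, n_samples = cfg$n_samples
    )
  )
  diag <- diagnose_cohort(cohort, threshold = cfg$threshold)

  paths <- list(
    cohort = file.path(cfg$output_dir, "cohort.csv"),
    diagnostics = file.path(cfg$output_dir, "diagnostics.json"),
    config = file.path(cfg$output_dir, "config.yaml")
  )
  write_cohort(cohort, paths$cohort)
  export_diagnostics(diag, paths$diagnostics)
  yaml::write_yaml(cfg, paths$config)
  reports <- attr(cohort, "tuning_reports")
  if (!is.null(reports)) {
    paths$tuning_reports <- file.path(cfg$output_dir, "tuning_reports.csv")
    readr::write_csv(reports, paths$tuning_reports)
  }

  invisible(list(cohort = cohort, diagnostics = diag, paths = paths))
}

#' Replicate the study over seeded synthetic cohorts
#'
#' Runs `n_replicates` statistical-mode cohorts with seeds `base_seed`,
#' `base_seed + 1`, ... and aggregates the headline diagnostics per
#' replicate: ROC AUC of TAWSS for mismatch, Spearman correlation between
#' TAWSS and binary mismatch status, and sensitivity/specificity at the
#' fixed threshold. Monte-Carlo standard errors accompany the means.
#'
#' @param n_replicates Number of replicate cohorts (>= 1). Default 500.
#' @param base_seed First seed. Default 1.
#' @param sizes Group sizes per cohort. Default `c(30, 30, 30)`.
#' @param threshold Fixed TAWSS threshold, dyn/cm^2. Default 27.0.
#' @param summaries Calibration summaries, default [group_summaries()].
#' @return A list of class `replicate_summary`: `replicates` (tibble with
#'   one row per cohort: `seed`, `auc`, `rho`, `sensitivity`, `specificity`)
#'   and `summary` (means and Monte-Carlo SEs).
#' @export
replicate_study <- function(n_replicates = 500, base_seed = 1,
                            sizes = c(30, 30, 30), threshold = 27.0,
                            summaries = group_summaries()) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    seed <- as.integer(base_seed + i - 1)
    cohort <- generate_cohort(
      mode = "statistical", sizes = sizes,
      seed = seed, summaries = summaries
    )
    roc <- roc_analysis(cohort, TAWSS, mismatch_positive,
      orientation = "lower", threshold = threshold
    )
    rho <- spearman_cor(
      dplyr::mutate(cohort, status = as.numeric(.data$mismatch_positive)),
      TAWSS, status
    )$rho
    tibble::tibble(
      seed = seed,
      auc = roc$auc,
      rho = rho,
      sensitivity = roc$at_threshold$sensitivity,
      specificity = roc$at_threshold$specificity
    )
  })
  mc_se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- tibble::tibble(
    metric = c("auc", "rho", "sensitivity", "specificity"),
    mean = c(
      mean(reps$auc), mean(reps$rho),
      mean(reps$sensitivity), mean(reps$specificity)
    ),
    mc_se = c(
      mc_se(reps$auc), mc_se(reps$rho),
      mc_se(reps$sensitivity), mc_se(reps$specificity)
    ),
    n_replicates = n_replicates
  )
  structure(
    list(replicates = reps, summary = summary, threshold = threshold),
    class = "replicate_summary"
  )
}

#' @method tidy replicate_summary
#' @export
tidy.replicate_summary <- function(x, ...) x$replicates

#' @method glance replicate_summary
#' @export
glance.replicate_summary <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary[, c("metric", "mean")],
    names_from = "metric", values_from = "mean"
  )
}
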