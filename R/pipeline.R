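#' Experiment configuration
#'
#' Bundles everything one end-to-end run needs: the design (rotation axis and
#' angles), the observer population, the staircase protocol, analysis options
#' and the master seed. Percent-of-original-eye-size is the unit throughout.
#'
#' @param name Run label.
#' @param rotation_axis `"yaw"` or `"pitch"` (metadata; the analysis is
#'   identical).
#' @param angles Orientation angles in degrees, unique and non-empty.
#' @param population A [population_spec()]; its angle grid is aligned to
#'   `angles`.
#' @param staircase A [staircase_config()].
#' @param epsilon_method Sphericity epsilon for reported p-values
#'   (`"cm"`, `"gg"`, `"hf"`, `"none"`).
#' @param pse_method Reversal aggregation, `"pool"` or `"staircase_means"`.
#' @param bf_n_samples Importance samples per Bayes-factor marginal.
#' @param alpha Significance level used in reports.
#' @param seed Master seed (required); expanded into per-stage child seeds.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(name = "experiment",
                              rotation_axis = c("yaw", "pitch"),
                              angles = c(-60, -30, 0, 30, 60),
                              population = population_spec(angles = angles),
                              staircase = staircase_config(),
                              epsilon_method = "cm",
                              pse_method = "pool",
                              bf_n_samples = 10000,
                              alpha = 0.05,
                              seed) {
  rotation_axis <- match.arg(rotation_axis)
  if (missing(seed)) stop_config("experiment_config requires a seed")
  if (length(angles) == 0L || anyDuplicated(angles))
    stop_config("angles must be non-empty and unique")
  if (!identical(sort(population$angles), sort(as.numeric(angles))))
    population$angles <- as.numeric(angles)
  structure(
    list(name = name, rotation_axis = rotation_axis,
         angles = as.numeric(angles), population = population,
         staircase = staircase, epsilon_method = epsilon_method,
         pse_method = pse_method, bf_n_samples = bf_n_samples,
         alpha = alpha, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Presets shipped with the package (see
#' `system.file("extdata", package = "illusim")`): `exp1.yaml` (yaw rotation,
#' 0/±30/±60 degrees), `exp2.yaml` (pitch rotation, 0/±15/±30 degrees) and
#' `toy.yaml` (4 deterministic observers for fast checks). A `seed` given
#' here overrides the file's.
#'
#' @param path Path to a YAML config.
#' @param seed Optional seed override.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  pop <- do.call(population_spec,
                 c(raw$population %||% list(),
                   list(angles = raw$angles %||% c(-60, -30, 0, 30, 60))))
  sc <- do.call(staircase_config, raw$staircase %||% list())
  experiment_config(
    name = raw$name %||% sub("\\.ya?ml$", "", basename(path)),
    rotation_axis = raw$rotation_axis %||% "yaw",
    angles = raw$angles %||% c(-60, -30, 0, 30, 60),
    population = pop, staircase = sc,
    epsilon_method = raw$epsilon_method %||% "cm",
    pse_method = raw$pse_method %||% "pool",
    bf_n_samples = raw$bf_n_samples %||% 10000,
    alpha = raw$alpha %||% 0.05,
    seed = seed %||% raw$seed %||%
      stop_config("config needs a seed (in the file or as an argument)")
  )
}

#' Preset configuration shaped like the yaw- or pitch-rotation experiment
#'
#' @param which `"exp1"` (yaw, ±60), `"exp2"` (pitch, ±30) or `"toy"`.
#' @param seed Seed for the run.
#' @return An [experiment_config()].
#' @export
preset_config <- function(which = c("exp1", "exp2", "toy"), seed) {
  which <- match.arg(which)
  read_experiment_config(
    system.file("extdata", paste0(which, ".yaml"), package = "illusim",
                mustWork = TRUE),
    seed = seed)
}

#' Run a simulated experiment end-to-end
#'
#' Chains the whole pipeline: sample the observer population, run the
#' interleaved staircases, build the PSE table, summarise the illusion,
#' fit the within-subject ANOVA and compute the three Bayes factors. The
#' master seed is expanded into independent child seeds per stage, so any
#' stage can be reproduced in isolation. With `out_dir` set, all tables are
#' written as full-precision CSV/JSON plus a plain-text report; identical
#' config and seed yield byte-identical files.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `illusim_results`: `population`, `trials`,
#'   `pse`, `magnitude`, `anova`, `bf`, `manifest` (and `paths` if written).
#' @export
#' @examples
#' cfg <- experiment_config(angles = c(0, 30),
#'                          population = population_spec(n_subjects = 4,
#'                                                       angles = c(0, 30)),
#'                          bf_n_samples = 1000, seed = 7)
#' res <- run_pipeline(cfg)
#' res$magnitude
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, 3L)
  population <- sample_population(config$population, seed = seeds[1])
  trials <- withCallingHandlers(
    run_experiment(population, config$angles, config$staircase,
                   seed = seeds[2]),
    warning = function(w) invokeRestart("muffleWarning"))
  pse <- pse_table(trials, config$staircase, config$pse_method)
  magnitude <- illusion_magnitude(pse)
  anova <- two_way_rm_anova(pse, config$epsilon_method)
  bf <- withCallingHandlers(
    anova_bf(pse, n_samples = config$bf_n_samples, seed = seeds[3]),
    warning = function(w) invokeRestart("muffleWarning"))
  warnings <- c(
    if (length(attr(trials, "capped")) > 0L)
      paste0("capped staircases: ",
             paste(attr(trials, "capped"), collapse = ", ")),
    if (any(!bf$results$converged))
      paste0("BF above MC error threshold: ",
             paste(bf$results$effect[!bf$results$converged], collapse = ", "))
  )
  manifest <- list(
    name = config$name, seed = config$seed, stage_seeds = seeds,
    config = config_as_list(config),
    package_version = as.character(utils::packageVersion("illusim")),
    warnings = as.list(warnings %||% character(0))
  )
  res <- structure(
    list(population = population, trials = trials, pse = pse,
         magnitude = magnitude, anova = anova, bf = bf,
         manifest = manifest),
    class = "illusim_results")
  if (!is.null(out_dir)) res <- write_results(res, out_dir)
  res
}

config_as_list <- function(config) {
  list(name = config$name, rotation_axis = config$rotation_axis,
       angles = config$angles,
       population = unclass(config$population),
       staircase = unclass(config$staircase),
       epsilon_method = config$epsilon_method,
       pse_method = config$pse_method,
       bf_n_samples = config$bf_n_samples, alpha = config$alpha,
       seed = config$seed)
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wcsv <- function(x, f) utils::write.csv(x, p(f), row.names = FALSE)
  wcsv(res$trials, "trials.csv")
  wcsv(res$pse, "pse_table.csv")
  wcsv(res$magnitude, "illusion_summary.csv")
  wcsv(tidy(res$anova), "anova.csv")
  wcsv(tidy(res$bf), "bayes_factors.csv")
  jsonlite::write_json(tidy(res$anova), p("anova.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(tidy(res$bf), p("bayes_factors.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report_lines(res), p("report.txt"))
  res$paths <- list(
    trials = p("trials.csv"), pse = p("pse_table.csv"),
    illusion = p("illusion_summary.csv"), anova = p("anova.csv"),
    bf = p("bayes_factors.csv"), manifest = p("manifest.json"),
    report = p("report.txt"))
  res
}

report_lines <- function(res) {
  ov <- res$magnitude[res$magnitude$angle == "overall", ]
  c(sprintf("Run: %s (seed %d)", res$manifest$name, res$manifest$seed),
    sprintf("Eyeshadow illusion: %.2f%% on average (SE %.2f)",
            ov$mean_magnitude, ov$se),
    "",
    vapply(seq_len(nrow(res$anova$effects)),
           function(i) report_effect(res$anova$effects[i, ]), character(1)),
    "",
    sprintf("%s: BF = %s (%s)", res$bf$results$effect,
            format_bf(res$bf$results$bf10),
            gsub("_", " ", res$bf$results$interpretation)))
}

#' @export
print.illusim_results <- function(x, ...) {
  writeLines(report_lines(x))
  invisible(x)
}

#' Parameter-recovery study over replicated simulated experiments
#'
#' Repeats the full simulate-measure-estimate chain and scores how well the
#' illusion magnitude (mean eyeshadow shift) and the baseline PSE are
#' recovered. For every replicate a fresh population is drawn, the staircase
#' experiment run, and the recovered grand illusion magnitude compared with
#' that replicate's true mean subject-level shift; a t-based 95% interval
#' over subjects is scored for coverage of the replicate truth.
#'
#' @param config An [experiment_config()].
#' @param replicates Number of replicate experiments.
#' @param seed Master seed for the study.
#' @return A list of class `recovery_study`: `replicates` (per-replicate
#'   tibble) and `summary` (per-parameter bias, RMSE, coverage).
#' @export
recovery_study <- function(config, replicates = 200, seed) {
  stopifnot(inherits(config, "experiment_config"))
  if (missing(seed)) stop_config("a seed is required")
  seeds <- derive_seeds(seed, 2L * replicates)
  reps <- purrr::map_dfr(seq_len(replicates), function(r) {
    pop <- sample_population(config$population, seed = seeds[2L * r - 1L])
    trials <- withCallingHandlers(
      run_experiment(pop, config$angles, config$staircase,
                     seed = seeds[2L * r]),
      warning = function(w) invokeRestart("muffleWarning"))
    tbl <- pse_table(trials, config$staircase, config$pse_method)
    mag <- illusion_magnitude(tbl)
    ov <- mag[mag$angle == "overall", ]
    tcrit <- stats::qt(0.975, ov$n - 1)
    true_shift <- mean(pop$shadow_shift)
    base_rec <- mean(tbl$pse[!tbl$shadow])
    tibble::tibble(
      replicate = r,
      recovered_shift = ov$mean_magnitude,
      true_shift = true_shift,
      shift_covered = abs(ov$mean_magnitude - true_shift) <= tcrit * ov$se,
      recovered_baseline = base_rec,
      true_baseline = mean(pop$baseline_pse)
    )
  })
  summary <- tibble::tibble(
    parameter = c("shadow_shift", "baseline_pse"),
    bias = c(mean(reps$recovered_shift - reps$true_shift),
             mean(reps$recovered_baseline - reps$true_baseline)),
    rmse = c(sqrt(mean((reps$recovered_shift - reps$true_shift)^2)),
             sqrt(mean((reps$recovered_baseline - reps$true_baseline)^2))),
    coverage = c(mean(reps$shift_covered), NA_real_),
    n_replicates = replicates
  )
  structure(list(replicates = reps, summary = summary),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("Parameter recovery over", x$summary$n_replicates[1], "replicates\n")
  print(x$summary)
  invisible(x)
}
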