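#' Simulate a PSE table directly from the measurement model
#'
#' Bypasses the staircase procedure: each cell's PSE estimate is the
#' observer's true PSE plus independent Gaussian measurement noise. This is
#' the fast generator used to calibrate the analysis layer (e.g. type-I
#' error of the interaction test over many replicates), where the quantity
#' under study is the inference chain, not the staircase estimator.
#'
#' @param population An [sample_population()] tibble.
#' @param measurement_sd SD of the per-cell estimation noise (percent).
#'   The default 0.5 is of the order of the reversal-averaging estimator's
#'   cell-level noise at the default staircase settings.
#' @param seed Integer seed.
#' @return A [pse_table()].
#' @export
simulate_pse_table <- function(population, measurement_sd = 0.5, seed) {
  if (missing(seed)) stop_config("a seed is required")
  if (measurement_sd < 0) stop_config("measurement_sd must be >= 0")
  set.seed(as.integer(seed))
  truth <- observer_truth(population)
  out <- truth |>
    dplyr::transmute(.data$subject_id, .data$shadow, .data$angle,
                     pse = .data$true_pse +
                       rnorm(dplyr::n(), 0, measurement_sd))
  validate_pse_table(out)
}
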