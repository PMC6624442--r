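# Recompute reversal trials from a staircase's ordered response sequence.
# A reversal is a trial whose intended movement direction (down after
# "comparative larger", up after "standard larger") differs from the previous
# trial's; the first trial only initialises the direction. Clamping at the
# grid bounds never affects this, so reversals depend on responses alone.
# Only the first `criterion` reversals are used (the run stops there anyway).
reversal_levels <- function(levels, responses, criterion = Inf) {
  dir <- ifelse(responses == "comparative_larger", "down", "up")
  if (length(dir) < 2L) return(numeric(0))
  idx <- which(dir[-1] != dir[-length(dir)]) + 1L
  levels[head(idx, criterion)]
}

#' Estimate the PSE of one design cell
#'
#' The point of subjective equality is the mean of the comparative eye sizes
#' at which the staircase direction reversed, pooled across the cell's
#' staircases (default) or averaged staircase-wise first. Reversals are
#' recomputed from each staircase's ordered response sequence, so the
#' estimate is invariant to row order in the log. All reversals up to the
#' termination criterion are used; none are discarded.
#'
#' @param trials Trial records of one subject in one shadow-by-angle cell
#'   (columns `staircase_id`, `trial_index`, `comparative_level`, `response`).
#' @param config The [staircase_config()] used (for the reversal criterion).
#' @param method `"pool"` (pool reversal levels across the cell's staircases,
#'   then average) or `"staircase_means"` (average within staircases first).
#'   Both agree when reversal counts are balanced.
#' @return The PSE estimate in percent.
#' @export
estimate_pse <- function(trials, config = staircase_config(),
                         method = c("pool", "staircase_means")) {
  method <- match.arg(method)
  per_sc <- trials |>
    dplyr::group_by(.data$staircase_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::summarise(revs = list(reversal_levels(
      .data$comparative_level, .data$response, config$reversal_criterion)),
      .groups = "drop")
  counts <- lengths(per_sc$revs)
  if (any(counts == 0L))
    stop_structure("staircase(s) with zero reversals in cell: ",
                   paste(per_sc$staircase_id[counts == 0L], collapse = ", "))
  if (method == "pool") mean(unlist(per_sc$revs))
  else mean(vapply(per_sc$revs, mean, numeric(1)))
}

#' Build the subject-by-condition PSE table from a trial log
#'
#' Aggregates a trial table into one PSE per subject, eyeshadow level and
#' orientation. The design must be complete: every subject must contribute
#' every shadow-by-angle cell, and every cell's staircases must contain at
#' least one reversal; violations are structural errors (the downstream
#' within-subject ANOVA requires a balanced table), not silent drops.
#'
#' @param trials A trial table from [run_experiment()] (or read from CSV with
#'   the same columns).
#' @inheritParams estimate_pse
#' @return A tibble of class `pse_table` with columns `subject_id`, `shadow`,
#'   `angle`, `pse`, sorted by subject, shadow, angle.
#' @export
pse_table <- function(trials, config = staircase_config(),
                      method = c("pool", "staircase_means")) {
  method <- match.arg(method)
  needed <- c("subject_id", "shadow", "angle", "staircase_id", "trial_index",
              "comparative_level", "response")
  miss <- setdiff(needed, names(trials))
  if (length(miss) > 0L)
    stop_structure("trial table lacks columns: ", paste(miss, collapse = ", "))
  # vectorized equivalent of estimate_pse() per cell: recompute reversal
  # trials within each staircase from its ordered response sequence, keep
  # the first `reversal_criterion` of them, then average per cell
  sc <- interaction(trials$subject_id, trials$shadow, trials$angle,
                    trials$staircase_id, drop = TRUE)
  ord <- order(sc, trials$trial_index)
  sc_o <- sc[ord]
  dir_o <- trials$response[ord] == "comparative_larger"
  lev_o <- trials$comparative_level[ord]
  first <- c(TRUE, sc_o[-1] != sc_o[-length(sc_o)])
  rev_o <- !first & dir_o != c(FALSE, dir_o[-length(dir_o)])
  rev_o[first] <- FALSE
  rev_rank <- stats::ave(as.numeric(rev_o), sc_o, FUN = cumsum)
  keep <- rev_o & rev_rank <= config$reversal_criterion
  n_rev <- tapply(keep, sc_o, sum)
  if (any(n_rev == 0L))
    stop_structure("staircase(s) with zero reversals: ",
                   paste(head(names(n_rev)[n_rev == 0L], 5), collapse = ", "))
  key_o <- data.frame(subject_id = trials$subject_id[ord],
                      shadow = trials$shadow[ord],
                      angle = trials$angle[ord],
                      staircase_id = trials$staircase_id[ord],
                      revs = NA_real_)[keep, ]
  key_o$revs <- lev_o[keep]
  out <- if (method == "pool") {
    stats::aggregate(revs ~ subject_id + shadow + angle, data = key_o,
                     FUN = mean)
  } else {
    per_sc <- stats::aggregate(
      revs ~ subject_id + shadow + angle + staircase_id, data = key_o,
      FUN = mean)
    stats::aggregate(revs ~ subject_id + shadow + angle, data = per_sc,
                     FUN = mean)
  }
  names(out)[names(out) == "revs"] <- "pse"
  out |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$subject_id, .data$shadow, .data$angle) |>
    validate_pse_table()
}

#' Validate (and class) a PSE table
#'
#' Checks the table is a complete, balanced subject-by-shadow-by-angle grid
#' with exactly one finite PSE per cell.
#'
#' @param table A data frame with columns `subject_id`, `shadow`, `angle`,
#'   `pse`.
#' @return The table as a `pse_table` tibble.
#' @export
validate_pse_table <- function(table) {
  needed <- c("subject_id", "shadow", "angle", "pse")
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0L)
    stop_structure("PSE table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$pse))) stop_structure("non-finite PSE values")
  full <- tidyr::expand_grid(subject_id = unique(table$subject_id),
                             shadow = unique(table$shadow),
                             angle = unique(table$angle))
  tab <- dplyr::count(table, .data$subject_id, .data$shadow, .data$angle)
  if (nrow(tab) != nrow(full) || any(tab$n != 1L)) {
    missing_cells <- dplyr::anti_join(
      full, table, by = c("subject_id", "shadow", "angle"))
    stop_structure(
      "PSE table is not a complete balanced design; ",
      nrow(missing_cells), " missing cell(s)",
      if (nrow(missing_cells) > 0L)
        paste0(", e.g. ", missing_cells$subject_id[1], "/",
               missing_cells$shadow[1], "/", missing_cells$angle[1]))
  }
  out <- tibble::as_tibble(table)
  if (!inherits(out, "pse_table")) class(out) <- c("pse_table", class(out))
  out
}

#' Illusion magnitude: eyeshadow minus no-eyeshadow PSE
#'
#' Summarises the eyeshadow illusion from a PSE table. For each subject and
#' angle the magnitude is the eyeshadow-condition PSE minus the no-eyeshadow
#' PSE (positive = eyeshadow enlarges perceived eye size); per-angle rows
#' average over subjects and the `"overall"` row averages each subject's
#' across-angle mean.
#'
#' @param table A [pse_table()].
#' @return A tibble with columns `angle` (angles plus `"overall"`),
#'   `mean_magnitude`, `sd`, `se`, `n`.
#' @export
#' @examples
#' tbl <- tidyr::expand_grid(subject_id = c("a", "b"),
#'                           shadow = c(FALSE, TRUE), angle = c(0, 30))
#' tbl$pse <- 100 + 2 * tbl$shadow
#' illusion_magnitude(validate_pse_table(tbl))
illusion_magnitude <- function(table) {
  table <- validate_pse_table(table)
  diffs <- table |>
    tidyr::pivot_wider(names_from = "shadow", values_from = "pse",
                       names_prefix = "shadow_") |>
    dplyr::mutate(magnitude = .data$shadow_TRUE - .data$shadow_FALSE)
  per_angle <- diffs |>
    dplyr::group_by(angle = as.character(.data$angle)) |>
    dplyr::summarise(mean_magnitude = mean(.data$magnitude),
                     sd = sd(.data$magnitude),
                     se = sd(.data$magnitude) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  overall <- diffs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(m = mean(.data$magnitude), .groups = "drop") |>
    dplyr::summarise(angle = "overall", mean_magnitude = mean(.data$m),
                     sd = sd(.data$m), se = sd(.data$m) / sqrt(dplyr::n()),
                     n = dplyr::n())
  dplyr::bind_rows(per_angle, overall)
}
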