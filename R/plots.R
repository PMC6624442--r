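#' Plot the trajectory of each staircase in a trial log
#'
#' Comparative level against trial index, one panel per subject-by-angle
#' block, coloured by staircase, reversals marked.
#'
#' @param trials A trial table from [run_experiment()], optionally filtered.
#' @param subjects Subset of subject ids to show (default: first subject).
#' @return A ggplot object.
#' @export
plot_staircases <- function(trials, subjects = NULL) {
  subjects <- subjects %||% trials$subject_id[1]
  dat <- dplyr::filter(trials, .data$subject_id %in% subjects)
  ggplot2::ggplot(dat, ggplot2::aes(.data$trial_index,
                                    .data$comparative_level,
                                    colour = .data$staircase_id)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$reversal),
                        shape = 21, fill = "white") +
    ggplot2::facet_grid(subject_id ~ angle) +
    ggplot2::labs(x = "trial (within block)",
                  y = "comparative eye size (% of original)",
                  colour = "staircase") +
    ggplot2::theme_minimal()
}

#' Plot mean PSEs by condition
#'
#' Means and standard errors of the estimated PSEs per orientation, split by
#' eyeshadow presence — the package's analogue of a condition-means figure.
#'
#' @param object A [pse_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pse_table
#' @export
autoplot.pse_table <- function(object, ...) {
  sumdat <- object |>
    dplyr::group_by(.data$shadow, .data$angle) |>
    dplyr::summarise(mean_pse = mean(.data$pse),
                     se = sd(.data$pse) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(sumdat, ggplot2::aes(.data$angle, .data$mean_pse,
                                       colour = .data$shadow,
                                       group = .data$shadow)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_pse - .data$se,
                                          ymax = .data$mean_pse + .data$se)) +
    ggplot2::labs(x = "face orientation (degrees)",
                  y = "PSE (% of original eye size)",
                  colour = "eyeshadow") +
    ggplot2::theme_minimal()
}

#' Plot per-angle illusion magnitudes
#'
#' @param object An [illusion_magnitude()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_illusion <- function(object, ...) {
  dat <- dplyr::filter(object, .data$angle != "overall")
  ggplot2::ggplot(dat, ggplot2::aes(.data$angle, .data$mean_magnitude)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_magnitude - .data$se,
                                        ymax = .data$mean_magnitude + .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "face orientation (degrees)",
                  y = "eyeshadow illusion (percentage points)") +
    ggplot2::theme_minimal()
}
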