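#' Specify a simulated observer population
#'
#' Defines the between-subject distribution from which simulated observers
#' are drawn. Each observer carries a condition-wise true point of subjective
#' equality (PSE, in percent of the original eye size): a baseline near 100,
#' an eyeshadow shift (the true illusion magnitude for that subject), optional
#' per-orientation shifts, and optional shadow-by-orientation interaction
#' shifts. All shifts are additive on the percent scale. Responses follow a
#' lapse-mixed cumulative-Gaussian psychometric function with a common slope
#' and lapse rate.
#'
#' The defaults describe a population of 20 observers with a mean illusion of
#' 2.42 percent, no orientation dependence of the illusion, subject-level
#' standard deviations of 1 percent for baseline and illusion, a 2 percent
#' psychometric slope and a 2 percent lapse rate.
#'
#' @param n_subjects Number of observers (>= 2).
#' @param angles Orientation angles (degrees) defining the design cells.
#' @param baseline_mean,baseline_sd Mean and SD of the no-shadow frontal PSE
#'   (percent of original size).
#' @param shadow_mean,shadow_sd Mean and SD of the per-subject eyeshadow shift
#'   (percent; positive = eyeshadow enlarges perceived eye size).
#' @param orientation_mean Named or unnamed numeric vector of per-angle PSE
#'   shifts (percent), recycled to `length(angles)`; default all 0.
#' @param orientation_sd SD of subject-level noise added to each orientation
#'   shift; default 0.
#' @param interaction_mean Numeric vector of per-angle shifts applied only in
#'   the eyeshadow condition (percent), recycled; default all 0, i.e. a
#'   viewpoint-invariant illusion.
#' @param interaction_sd SD of subject-level noise on the interaction shifts.
#' @param slope Psychometric slope (percent; SD of the cumulative Gaussian).
#'   `slope = 0` is the deterministic limit used for test observers: the
#'   response is then "comparative larger" iff the comparative level strictly
#'   exceeds the true PSE.
#' @param lapse_rate Probability in [0, 0.5) of a stimulus-independent random
#'   response, mixed symmetrically into the psychometric function.
#'
#' @return A list of class `population_spec`.
#' @seealso [sample_population()], [respond()]
#' @export
population_spec <- function(n_subjects = 20,
                            angles = c(-60, -30, 0, 30, 60),
                            baseline_mean = 100, baseline_sd = 1,
                            shadow_mean = 2.42, shadow_sd = 1,
                            orientation_mean = 0, orientation_sd = 0,
                            interaction_mean = 0, interaction_sd = 0,
                            slope = 2, lapse_rate = 0.02) {
  if (n_subjects < 2) stop_config("n_subjects must be >= 2, got ", n_subjects)
  if (length(angles) < 1 || anyDuplicated(angles))
    stop_config("angles must be non-empty and unique")
  sds <- c(baseline_sd, shadow_sd, orientation_sd, interaction_sd)
  if (any(sds < 0)) stop_config("all SDs must be >= 0")
  if (slope < 0) stop_config("slope must be >= 0 (0 = deterministic observer)")
  if (lapse_rate < 0 || lapse_rate >= 0.5)
    stop_config("lapse_rate must lie in [0, 0.5)")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      angles = as.numeric(angles),
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      shadow_mean = shadow_mean, shadow_sd = shadow_sd,
      orientation_mean = rep_len(as.numeric(orientation_mean), length(angles)),
      orientation_sd = orientation_sd,
      interaction_mean = rep_len(as.numeric(interaction_mean), length(angles)),
      interaction_sd = interaction_sd,
      slope = slope, lapse_rate = lapse_rate
    ),
    class = "population_spec"
  )
}

#' Draw a population of simulated observers
#'
#' Samples subject-level parameters independently from the normal
#' distributions of the population spec. The result is one row per observer,
#' with
#' list-columns holding the per-angle orientation and interaction shifts.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; the same spec and seed always yield the same
#'   population.
#' @return A tibble of class `observer_population` with columns `subject_id`,
#'   `baseline_pse`, `shadow_shift`, `orientation_shifts` (list),
#'   `interaction_shifts` (list), `slope`, `lapse_rate`, plus the angle grid
#'   in `attr(, "angles")`.
#' @export
#' @examples
#' pop <- sample_population(population_spec(n_subjects = 4), seed = 1)
#' pop$shadow_shift
sample_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (missing(seed)) stop_config("a seed is required to sample a population")
  set.seed(as.integer(seed))
  n <- spec$n_subjects
  k <- length(spec$angles)
  out <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    baseline_pse = rnorm(n, spec$baseline_mean, spec$baseline_sd),
    shadow_shift = rnorm(n, spec$shadow_mean, spec$shadow_sd),
    orientation_shifts = lapply(seq_len(n), function(i)
      setNames(rnorm(k, spec$orientation_mean, spec$orientation_sd),
               spec$angles)),
    interaction_shifts = lapply(seq_len(n), function(i)
      setNames(rnorm(k, spec$interaction_mean, spec$interaction_sd),
               spec$angles)),
    slope = spec$slope,
    lapse_rate = spec$lapse_rate
  )
  attr(out, "angles") <- spec$angles
  class(out) <- c("observer_population", class(out))
  out
}

#' True PSE of one observer in one design cell
#'
#' The latent point of subjective equality is additive:
#' baseline + shadow shift (if the standard wears eyeshadow) + orientation
#' shift + interaction shift. Only the standard stimulus can carry eyeshadow;
#' comparatives never do.
#'
#' @param observer One row of an [sample_population()] tibble (a list or a
#'   one-row data frame).
#' @param shadow Logical: does the standard stimulus wear eyeshadow?
#' @param angle Orientation angle; must be one of the population's angles.
#' @return True PSE in percent of original eye size.
#' @export
true_pse <- function(observer, shadow, angle) {
  ori <- observer$orientation_shifts
  int <- observer$interaction_shifts
  if (is.list(ori) && !is.null(names(ori[[1]]))) { ori <- ori[[1]]; int <- int[[1]] }
  key <- as.character(as.numeric(angle))
  if (!key %in% names(ori)) stop_usage("angle ", angle, " not in the design")
  pse <- observer$baseline_pse + as.numeric(shadow) * observer$shadow_shift +
    ori[[key]] + if (shadow) int[[key]] else 0
  if (!is.finite(pse)) stop_usage("non-finite true PSE in cell")
  pse
}

#' Probability that the comparative stimulus looks larger
#'
#' Lapse-mixed cumulative-Gaussian psychometric function:
#' \deqn{P = \lambda + (1 - 2\lambda)\,\Phi((x - \mathrm{PSE})/\sigma)}
#' where \eqn{x} is the comparative eye size, \eqn{\sigma} the slope and
#' \eqn{\lambda} the lapse rate. At \eqn{x = \mathrm{PSE}} the probability is
#' exactly 0.5 for any lapse rate. With `slope = 0` the observer is
#' deterministic: the Gaussian term is replaced by the strict indicator
#' \eqn{x > \mathrm{PSE}}.
#'
#' @inheritParams true_pse
#' @param comparative_size Comparative eye size (percent).
#' @return Probability of the response "comparative larger".
#' @export
p_comparative_larger <- function(observer, shadow, angle, comparative_size) {
  if (!all(is.finite(comparative_size)))
    stop_usage("comparative_size must be finite")
  pse <- true_pse(observer, shadow, angle)
  core <- if (observer$slope[[1]] > 0) {
    pnorm((comparative_size - pse) / observer$slope[[1]])
  } else {
    as.numeric(comparative_size > pse)
  }
  lam <- observer$lapse_rate[[1]]
  lam + (1 - 2 * lam) * core
}

#' Simulate one two-alternative forced-choice response
#'
#' Draws a Bernoulli response from [p_comparative_larger()]. Uses the current
#' RNG stream; seed control belongs to the caller.
#'
#' @inheritParams p_comparative_larger
#' @return `"comparative_larger"` or `"standard_larger"`.
#' @export
respond <- function(observer, shadow, angle, comparative_size) {
  p <- p_comparative_larger(observer, shadow, angle, comparative_size)
  if (runif(1) < p) "comparative_larger" else "standard_larger"
}

#' Export true observer parameters for recovery scoring
#'
#' @param population An [sample_population()] result.
#' @return A tidy tibble with one row per subject, shadow level and angle,
#'   holding the cell's true PSE and the subject's parameters.
#' @export
observer_truth <- function(population) {
  angles <- attr(population, "angles")
  n <- nrow(population)
  k <- length(angles)
  key <- as.character(angles)
  ori <- matrix(unlist(lapply(population$orientation_shifts, `[`, key)),
                nrow = n, byrow = TRUE)
  int <- matrix(unlist(lapply(population$interaction_shifts, `[`, key)),
                nrow = n, byrow = TRUE)
  s_idx <- rep(seq_len(n), each = 2L * k)
  shadow <- rep(rep(c(FALSE, TRUE), each = k), times = n)
  a_idx <- rep(seq_len(k), times = 2L * n)
  tibble::tibble(
    subject_id = population$subject_id[s_idx],
    shadow = shadow,
    angle = angles[a_idx],
    true_pse = population$baseline_pse[s_idx] +
      shadow * population$shadow_shift[s_idx] +
      ori[cbind(s_idx, a_idx)] + shadow * int[cbind(s_idx, a_idx)],
    shadow_shift = population$shadow_shift[s_idx],
    baseline_pse = population$baseline_pse[s_idx]
  )
}
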