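#' Staircase configuration
#'
#' Parameters of the 1-up/1-down adaptive procedure: the comparative-stimulus
#' grid runs from `level_min` to `level_max` percent of original eye size in
#' `step`-percent increments; ascending staircases start at `start_ascending`
#' and descending ones at `start_descending`; a staircase terminates after
#' `reversal_criterion` direction reversals, or at `max_trials` as a safety
#' cap (capped staircases are flagged).
#'
#' @param level_min,level_max Grid bounds (percent). Defaults 92 and 108.
#' @param step Grid step (percent), default 1.
#' @param start_ascending,start_descending Start levels, on the grid.
#' @param reversal_criterion Number of reversals that terminates a staircase.
#' @param max_trials Per-staircase trial cap.
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(level_min = 92, level_max = 108, step = 1,
                             start_ascending = level_min,
                             start_descending = level_max,
                             reversal_criterion = 6, max_trials = 200) {
  if (level_min >= level_max) stop_config("level_min must be < level_max")
  if (step <= 0) stop_config("step must be > 0")
  if (abs((level_max - level_min) / step -
          round((level_max - level_min) / step)) > 1e-9)
    stop_config("(level_max - level_min) must be divisible by step")
  on_grid <- function(x) abs((x - level_min) / step -
                             round((x - level_min) / step)) < 1e-9
  if (!on_grid(start_ascending) || !on_grid(start_descending))
    stop_config("start levels must lie on the level grid")
  if (reversal_criterion < 1) stop_config("reversal_criterion must be >= 1")
  if (max_trials < 1) stop_config("max_trials must be >= 1")
  structure(
    list(level_min = level_min, level_max = level_max, step = step,
         start_ascending = start_ascending,
         start_descending = start_descending,
         reversal_criterion = as.integer(reversal_criterion),
         max_trials = as.integer(max_trials)),
    class = "staircase_config"
  )
}

#' Initialise one staircase
#'
#' @param staircase_id Identifier, conventionally `"<shadow|noshadow>_<asc|desc>"`.
#' @param direction `"ascending"` (start low) or `"descending"` (start high).
#' @param config A [staircase_config()].
#' @return A list of class `staircase_state`: current level, last movement
#'   direction (`"none"` before the first response), recorded reversal levels,
#'   trial count, termination and cap flags.
#' @export
new_staircase <- function(staircase_id, direction = c("ascending", "descending"),
                          config = staircase_config()) {
  direction <- match.arg(direction)
  structure(
    list(staircase_id = staircase_id,
         direction = direction,
         current_level = if (direction == "ascending") config$start_ascending
                         else config$start_descending,
         last_move = "none",
         reversal_levels = numeric(0),
         trial_count = 0L,
         terminated = FALSE,
         capped = FALSE),
    class = "staircase_state"
  )
}

#' Advance a staircase by one response
#'
#' The 1-up/1-down rule: "comparative larger" moves the comparative level one
#' step down, "standard larger" one step up. A reversal is recorded — at the
#' level presented on this trial — when the intended movement direction
#' differs from the previous one (the first response only initialises the
#' direction). Levels clamp at the grid bounds; a clamped non-move is not
#' itself a reversal, but the response still updates the movement direction.
#' The staircase terminates when the reversal criterion is met, or at the
#' trial cap (then flagged `capped`).
#'
#' @param state A [new_staircase()] state, not yet terminated.
#' @param response `"comparative_larger"` or `"standard_larger"`.
#' @param config A [staircase_config()].
#' @return The updated `staircase_state`; `attr(, "reversal")` on the return
#'   says whether this trial was a reversal.
#' @export
update_staircase <- function(state, response, config) {
  if (state$terminated) stop_usage("cannot update a terminated staircase")
  if (!response %in% c("comparative_larger", "standard_larger"))
    stop_usage("unknown response: ", response)
  intended <- if (response == "comparative_larger") "down" else "up"
  reversal <- state$last_move != "none" && intended != state$last_move
  state$trial_count <- state$trial_count + 1L
  if (reversal) state$reversal_levels <- c(state$reversal_levels,
                                           state$current_level)
  new_level <- state$current_level + if (intended == "down") -config$step
                                     else config$step
  state$current_level <- min(max(new_level, config$level_min), config$level_max)
  state$last_move <- intended
  if (length(state$reversal_levels) >= config$reversal_criterion) {
    state$terminated <- TRUE
  } else if (state$trial_count >= config$max_trials) {
    state$terminated <- TRUE
    state$capped <- TRUE
  }
  attr(state, "reversal") <- reversal
  state
}

#' Run one block: four interleaved staircases for one orientation
#'
#' A block measures one face orientation. It interleaves four concurrent
#' staircases — ascending and descending, standard with and without
#' eyeshadow — choosing uniformly at random among the non-terminated
#' staircases on every trial, until all four have terminated. The left/right
#' position of the standard stimulus is drawn uniformly per trial and logged
#' as metadata (it never affects the response model).
#'
#' @param observer One observer (one row of [sample_population()], or a list).
#' @param angle Orientation angle of this block.
#' @param config A [staircase_config()].
#' @return A tibble of trial records: `staircase_id`, `shadow`, `direction`,
#'   `trial_index` (within block), `comparative_level`, `standard_side`,
#'   `response`, `reversal`, plus `attr(, "capped_staircases")`.
#' @export
run_block <- function(observer, angle, config = staircase_config()) {
  grid <- expand.grid(shadow = c(FALSE, TRUE),
                      direction = c("ascending", "descending"),
                      stringsAsFactors = FALSE)
  ids <- paste0(ifelse(grid$shadow, "shadow", "noshadow"), "_",
                ifelse(grid$direction == "ascending", "asc", "desc"))
  states <- purrr::pmap(list(ids, grid$direction), function(id, dir)
    new_staircase(id, dir, config))
  names(states) <- ids

  # response probabilities precomputed over the level grid, one lookup per
  # staircase (the model depends only on the standard's shadow flag)
  lv_grid <- seq(config$level_min, config$level_max, by = config$step)
  ptab <- lapply(grid$shadow, function(sh)
    p_comparative_larger(observer, sh, angle, lv_grid))

  cap <- 4L * config$max_trials
  sc_id <- integer(cap); level <- numeric(cap)
  side <- character(cap); resp <- character(cap); rev_flag <- logical(cap)
  t <- 0L
  live <- rep(TRUE, 4L)
  repeat {
    alive <- which(live)
    if (length(alive) == 0L) break
    i <- if (length(alive) == 1L) alive
         else alive[sample.int(length(alive), 1L)]
    st <- states[[i]]
    t <- t + 1L
    lev <- st$current_level
    p <- ptab[[i]][round((lev - config$level_min) / config$step) + 1L]
    r <- if (runif(1) < p) "comparative_larger" else "standard_larger"
    st <- update_staircase(st, r, config)
    states[[i]] <- st
    live[i] <- !st$terminated
    sc_id[t] <- i; level[t] <- lev
    side[t] <- if (runif(1) < 0.5) "left" else "right"
    resp[t] <- r; rev_flag[t] <- attr(st, "reversal")
  }
  idx <- sc_id[seq_len(t)]
  out <- tibble::tibble(
    staircase_id = ids[idx],
    shadow = grid$shadow[idx],
    direction = grid$direction[idx],
    trial_index = seq_len(t),
    comparative_level = level[seq_len(t)],
    standard_side = side[seq_len(t)],
    response = resp[seq_len(t)],
    reversal = rev_flag[seq_len(t)]
  )
  attr(out, "capped_staircases") <-
    ids[vapply(states, `[[`, logical(1), "capped")]
  out
}

#' Run a full experiment over a population
#'
#' One block per orientation per subject, block order randomised
#' independently for each subject. The whole run is reproducible from the
#' seed: per-subject child seeds are derived from it, so any subject's data
#' can be regenerated in isolation.
#'
#' @param population An [sample_population()] tibble.
#' @param angles Orientation angles (one block each).
#' @param config A [staircase_config()].
#' @param seed Integer master seed (required).
#' @return A trial-table tibble with columns `subject_id`, `block_order`,
#'   `angle`, then the [run_block()] columns. Capped staircases, if any, are
#'   listed in `attr(, "capped")` and raised as a warning.
#' @export
#' @examples
#' pop <- sample_population(population_spec(n_subjects = 2, angles = c(0, 30)),
#'                          seed = 1)
#' trials <- run_experiment(pop, angles = c(0, 30), seed = 2)
#' dplyr::count(trials, subject_id, angle)
run_experiment <- function(population, angles, config = staircase_config(),
                           seed) {
  if (nrow(population) == 0L || length(angles) == 0L)
    stop_config("population and angles must be non-empty")
  if (missing(seed)) stop_config("a seed is required to run an experiment")
  seeds <- derive_seeds(seed, nrow(population))
  capped <- list()
  out <- purrr::map_dfr(seq_len(nrow(population)), function(i) {
    obs <- as.list(population[i, ])
    set.seed(seeds[i])
    order_i <- sample(seq_along(angles))
    purrr::map_dfr(seq_along(order_i), function(b) {
      ang <- angles[order_i[b]]
      blk <- run_block(obs, ang, config)
      cs <- attr(blk, "capped_staircases")
      if (length(cs) > 0L)
        capped[[length(capped) + 1L]] <<-
          paste0(obs$subject_id, "/", ang, "/", cs)
      dplyr::mutate(blk, subject_id = obs$subject_id,
                    block_order = b, angle = ang, .before = 1)
    })
  })
  capped <- unlist(capped)
  if (length(capped) > 0L)
    warning("staircases hit the trial cap: ", paste(capped, collapse = ", "))
  attr(out, "capped") <- capped %||% character(0)
  out
}
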