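#' @importFrom stats pnorm qnorm rnorm runif rbinom rchisq pf var cov sd
#'   aggregate optim setNames complete.cases
#' @importFrom utils head tail
NULL

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state. Keeps every derived seed < 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr_seed <- function() {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    out <- sample.int(.Machine$integer.max - 1L, n)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  withr_seed()
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("illusim_config_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("illusim_usage_error", "error")))
}

stop_structure <- function(...) {
  stop(errorCondition(paste0(...), class = c("illusim_structure_error", "error")))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
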