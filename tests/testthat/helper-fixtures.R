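# A deterministic threshold observer: responds "comparative larger" iff the
# comparative level strictly exceeds the threshold (slope-0 limit, no lapses).
det_observer <- function(threshold = 100, angles = 0, shadow_shift = 0) {
  list(subject_id = "det",
       baseline_pse = threshold,
       shadow_shift = shadow_shift,
       orientation_shifts = setNames(rep(0, length(angles)), angles),
       interaction_shifts = setNames(rep(0, length(angles)), angles),
       slope = 0, lapse_rate = 0)
}

# A random balanced PSE table with optional true effects baked in.
rand_pse_table <- function(n_subj = 6, angles = c(0, 30, 60), seed = 1,
                           noise_sd = 1, shadow_effect = 0) {
  set.seed(seed)
  tbl <- tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                            shadow = c(FALSE, TRUE), angle = angles)
  tbl$pse <- 100 + shadow_effect * tbl$shadow + rnorm(nrow(tbl), 0, noise_sd)
  validate_pse_table(tbl)
}

# Reference within-subject ANOVA via stats::aov error strata.
aov_oracle <- function(table) {
  dat <- data.frame(pse = table$pse,
                    subject_id = factor(table$subject_id),
                    shadow = factor(table$shadow),
                    angle = factor(table$angle))
  fit <- stats::aov(pse ~ shadow * angle + Error(subject_id / (shadow * angle)),
                    data = dat)
  s <- summary(fit)
  pull <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    list(ss = tab[row, "Sum Sq"], ss_err = tab["Residuals", "Sum Sq"],
         f = tab[row, "F value"])
  }
  list(shadow = pull("Error: subject_id:shadow", "shadow"),
       orientation = pull("Error: subject_id:angle", "angle"),
       interaction = pull("Error: subject_id:shadow:angle", "shadow:angle"))
}

# Dense trapezoid integration of the g-prior marginal over log g, using the
# exact conditional marginal; independent of the importance sampler. The
# conditional evaluator is hoisted out of the grid loop (the per-point
# quantity equals conditional_log_marginal(); spot-checked below).
grid_log_marginal <- function(table, effects, r_fixed = 0.5, r_random = 1,
                              lo = -18, hi = 26, n_grid = 220) {
  r_vec <- ifelse(effects == "subject", r_random, r_fixed)
  lpt <- function(t, r) 0.5 * log(r^2 / 2) - lgamma(0.5) - 0.5 * t -
    r^2 / (2 * exp(t))
  prep <- illusim:::prep_model(illusim:::bf_design(table), effects)
  cond <- function(g) illusim:::logml_given_g(prep, g)
  stopifnot(abs(cond(rep(1, length(effects))) -
                  conditional_log_marginal(table, effects,
                                           rep(1, length(effects)))) < 1e-10)
  tg <- seq(lo, hi, length.out = n_grid)
  h <- diff(tg)[1]
  d <- length(effects)
  grids <- as.matrix(do.call(expand.grid, rep(list(tg), d)))
  lf <- vapply(seq_len(nrow(grids)), function(i) {
    tv <- grids[i, ]
    cond(exp(tv)) + sum(lpt(tv, r_vec))
  }, numeric(1))
  m <- max(lf)
  m + log(sum(exp(lf - m))) + d * log(h)
}
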