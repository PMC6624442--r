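# --- design construction ----------------------------------------------------
# Sum-to-zero orthonormal coding per effect family. Each factor contributes
# indicator %*% Q columns (Q from orthonormal_contrasts); the interaction
# contributes element-wise products of the two main-effect codes; the subject
# family is coded the same way and is always a random ("nuisance") family
# with its own prior scale.
bf_design <- function(table) {
  table <- validate_pse_table(table)
  factors <- list(shadow = factor(table$shadow),
                  orientation = factor(table$angle),
                  subject = factor(table$subject_id))
  list(y = table$pse, n = nrow(table), factors = factors)
}

family_matrix <- function(design, fam) {
  code <- function(f) {
    if (nlevels(f) < 2)
      stop_structure("family needs >= 2 levels to enter a model")
    Q <- orthonormal_contrasts(nlevels(f))
    Q[as.integer(f), , drop = FALSE]
  }
  X <- if (fam == "interaction") {
    Xa <- code(design$factors$shadow)
    Xb <- code(design$factors$orientation)
    do.call(cbind, lapply(seq_len(ncol(Xa)), function(i) Xa[, i] * Xb))
  } else code(design$factors[[fam]])
  if (qr(X)$rank < ncol(X))
    stop_structure("rank-deficient design for family ", fam)
  X
}

# log marginal likelihood of y given the g vector, with the grand mean given
# a flat prior and sigma^2 a Jeffreys prior, effects integrated analytically:
#   log p(y | g) = lgamma((N-1)/2) - ((N-1)/2) log(pi R)
#                  - log|V|/2 - log(1'V^-1 1)/2,
# V = I + X G X', R = y'V^-1 y - (1'V^-1 y)^2 / (1'V^-1 1).
# Woodbury keeps everything p x p.
logml_given_g <- function(prep, g) {
  if (length(g) == 0L) {
    R0 <- prep$yty - prep$sumy^2 / prep$n
    return(lgamma((prep$n - 1) / 2) - (prep$n - 1) / 2 * log(pi * R0) -
             0.5 * log(prep$n))
  }
  sg <- sqrt(g[prep$col_fam])
  M <- diag(length(sg)) + (sg %o% sg) * prep$XtX
  ch <- chol(M)
  a_y <- sg * prep$Xty
  a_1 <- sg * prep$Xt1
  u_y <- backsolve(ch, forwardsolve(t(ch), a_y))
  u_1 <- backsolve(ch, forwardsolve(t(ch), a_1))
  yVy <- prep$yty - sum(a_y * u_y)
  oVo <- prep$n - sum(a_1 * u_1)
  yVo <- prep$sumy - sum(a_1 * u_y)
  # floor the residual quadratic form at machine precision relative to y'y:
  # exactly collinear (noise-free) data would otherwise send the marginal to
  # infinity through rounding noise
  R <- max(yVy - yVo^2 / oVo, .Machine$double.eps * prep$yty)
  lgamma((prep$n - 1) / 2) - (prep$n - 1) / 2 * log(pi * R) -
    sum(log(diag(ch))) - 0.5 * log(oVo)
}

prep_model <- function(design, effects) {
  fams <- lapply(setNames(effects, effects),
                 function(f) family_matrix(design, f))
  X <- do.call(cbind, fams)
  list(n = design$n, y = design$y,
       X = X,
       col_fam = rep(seq_along(fams), vapply(fams, ncol, integer(1))),
       fam_names = names(fams),
       XtX = crossprod(X), Xty = drop(crossprod(X, design$y)),
       Xt1 = colSums(X), yty = sum(design$y^2), sumy = sum(design$y))
}

#' Log marginal likelihood conditional on the g hyperparameters
#'
#' The repeated-measures design is expressed as a linear model with
#' orthonormal sum-to-zero codes per effect family (eyeshadow, orientation,
#' their interaction, subject). Given one variance multiplier g per family,
#' the standardized effects carry normal g-priors, the grand mean a flat
#' prior and the error variance a Jeffreys prior; all of those integrate
#' analytically, leaving an exact multivariate-t-type log marginal that this
#' function evaluates. It is the deterministic core that the Bayes factor
#' integrations average over g.
#'
#' @param table A [pse_table()].
#' @param effects Character subset of
#'   `c("shadow", "orientation", "interaction", "subject")`; the interaction
#'   requires both main effects. Empty set = intercept-only model.
#' @param g Named (or positional) positive vector, one g per family in
#'   `effects`.
#' @return The log marginal likelihood (a scalar).
#' @export
conditional_log_marginal <- function(table, effects, g) {
  check_effect_set(effects)
  design <- bf_design(table)
  if (length(effects) == 0L)
    return(logml_given_g(list(n = design$n, yty = sum(design$y^2),
                              sumy = sum(design$y)), numeric(0)))
  if (length(g) != length(effects))
    stop_usage("need one g per effect family")
  if (any(g <= 0)) stop_usage("g values must be > 0")
  if (!is.null(names(g))) g <- g[effects]
  logml_given_g(prep_model(design, effects), as.numeric(g))
}

check_effect_set <- function(effects) {
  known <- c("shadow", "orientation", "interaction", "subject")
  bad <- setdiff(effects, known)
  if (length(bad) > 0L) stop_usage("unknown effect(s): ",
                                   paste(bad, collapse = ", "))
  if ("interaction" %in% effects &&
      !all(c("shadow", "orientation") %in% effects))
    stop_usage("the interaction may enter only with both main effects")
  invisible(effects)
}

# prior on each g: scaled inverse chi-square with 1 df and scale r^2
# (equivalently inverse-gamma(1/2, r^2/2)); density in t = log g includes
# the Jacobian g.
log_prior_t <- function(t, r) {
  0.5 * log(r^2 / 2) - lgamma(0.5) - 0.5 * t - r^2 / (2 * exp(t))
}
sample_prior_t <- function(n, r) log(r^2 / rchisq(n, df = 1))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log of \int p(y|g) p(g) dg for one model, by importance sampling over
# t = log g with a defensive mixture of the prior and a Gaussian fitted at
# the integrand's mode (Laplace step). Returns log value and relative MC
# error (delta method on the normalized weights).
integrate_marginal <- function(prep, r_vec, n_samples, defensive = 0.3) {
  d <- length(r_vec)
  f <- function(t) logml_given_g(prep, exp(t)) + sum(log_prior_t(t, r_vec))
  opt <- optim(rep(0, d), function(t) -f(t),
               method = if (d == 1) "Brent" else "Nelder-Mead",
               lower = if (d == 1) -15 else -Inf,
               upper = if (d == 1) 25 else Inf,
               control = list(maxit = 500))
  mode <- opt$par
  h <- 1e-3
  H <- matrix(0, d, d)
  f0 <- f(mode)
  for (i in seq_len(d)) for (j in i:d) {
    ei <- ej <- rep(0, d); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <- if (i == j)
      (f(mode + ei) - 2 * f0 + f(mode - ei)) / h^2
    else (f(mode + ei + ej) - f(mode + ei - ej) -
            f(mode - ei + ej) + f(mode - ei - ej)) / (4 * h^2)
  }
  Sig <- tryCatch(solve(-H) * 1.5, error = function(e) diag(d))
  ch <- tryCatch(chol(Sig), error = function(e) chol(diag(d)))
  log_det_sig <- 2 * sum(log(diag(ch)))

  n_prior <- rbinom(1, n_samples, defensive)
  t_prior <- matrix(vapply(r_vec, function(r) sample_prior_t(n_prior, r),
                           numeric(n_prior)), ncol = d)
  z <- matrix(rnorm((n_samples - n_prior) * d), ncol = d)
  t_gauss <- sweep(z %*% ch, 2, mode, `+`)
  tmat <- rbind(t_prior, t_gauss)

  log_q <- function(tm) {
    lp <- rowSums(vapply(seq_len(d), function(k)
      log_prior_t(tm[, k], r_vec[k]), numeric(nrow(tm))))
    dev <- sweep(tm, 2, mode)
    u <- t(forwardsolve(t(ch), t(dev)))
    lg <- -0.5 * rowSums(u^2) - 0.5 * d * log(2 * pi) - 0.5 * log_det_sig
    apply(cbind(log(defensive) + lp, log(1 - defensive) + lg), 1, logsumexp)
  }
  lw <- vapply(seq_len(n_samples), function(i) f(tmat[i, ]), numeric(1)) -
    log_q(tmat)
  log_val <- logsumexp(lw) - log(n_samples)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  rel_err <- sqrt(max(0, sum(w^2) - 1 / n_samples))
  list(log_marginal = log_val, rel_mc_error = rel_err, n_samples = n_samples,
       mode = mode)
}

#' Integrated log marginal likelihood of one model
#'
#' Integrates [conditional_log_marginal()] over the g-priors of the model's
#' effect families by seeded defensive-mixture importance sampling. Ratios
#' of these marginals are Bayes factors; [bayes_factor()] is a convenience
#' wrapper around two such calls.
#'
#' @inheritParams bayes_factor
#' @param effects Effect families in the model (see
#'   [conditional_log_marginal()]); the empty set gives the exact
#'   intercept-only marginal.
#' @return A list: `log_marginal`, `rel_mc_error`, `n_samples`.
#' @export
log_marginal <- function(table, effects, r_fixed = 0.5, r_random = 1,
                         n_samples = 10000, seed) {
  check_effect_set(effects)
  if (length(effects) == 0L)
    return(list(log_marginal = conditional_log_marginal(table, character(0),
                                                        numeric(0)),
                rel_mc_error = 0, n_samples = 0L))
  if (missing(seed)) stop_config("a seed is required")
  design <- bf_design(table)
  set.seed(as.integer(seed))
  r_vec <- ifelse(effects == "subject", r_random, r_fixed)
  out <- integrate_marginal(prep_model(design, effects), r_vec, n_samples)
  out[c("log_marginal", "rel_mc_error", "n_samples")]
}

bf_models <- function(effect) {
  switch(effect,
    shadow = list(alt = c("shadow", "subject"), null = "subject"),
    orientation = list(alt = c("orientation", "subject"), null = "subject"),
    interaction = list(
      alt = c("shadow", "orientation", "interaction", "subject"),
      null = c("shadow", "orientation", "subject")),
    stop_usage("effect must be shadow, orientation or interaction"))
}

#' Default g-prior Bayes factor for one repeated-measures effect
#'
#' Computes BF10 for an effect of the eyeshadow-by-orientation design under
#' default g-priors: standardized effects receive normal priors whose
#' variance multiplier g (one per effect family) carries a scaled
#' inverse-chi-square prior with scale `r_fixed` (fixed families, default
#' 1/2) or `r_random` (the subject family, default 1). Main effects compare
#' the model \{effect + subject\} against the subject-only null; the
#' interaction compares the full model against \{both main effects +
#' subject\}. Subject effects are retained in every model. The g integrals
#' use seeded defensive-mixture importance sampling over log g with a
#' reported relative Monte Carlo error; runs with the same seed and
#' `n_samples` are identical.
#'
#' @param table A complete balanced [pse_table()].
#' @param effect `"shadow"`, `"orientation"` or `"interaction"`; or
#'   `"all"` via [anova_bf()].
#' @param r_fixed,r_random Prior scales for fixed and random effect families.
#' @param n_samples Importance samples per marginal.
#' @param seed Integer seed (required).
#' @param mc_error_threshold Relative MC error above which the result is
#'   flagged as non-converged (never silently dropped).
#' @return A `bf_result` object; `tidy()` gives `effect`, `bf10`, `log_bf10`,
#'   `mc_error`, `n_samples`, `interpretation`, `converged`.
#' @export
#' @examples
#' pop <- sample_population(population_spec(n_subjects = 8,
#'                                          angles = c(0, 30)), seed = 1)
#' tbl <- simulate_pse_table(pop, seed = 2)
#' bayes_factor(tbl, "shadow", n_samples = 2000, seed = 3)
bayes_factor <- function(table, effect, r_fixed = 0.5, r_random = 1,
                         n_samples = 10000, seed,
                         mc_error_threshold = 0.05) {
  if (missing(seed)) stop_config("a seed is required for the BF integration")
  if (r_fixed <= 0 || r_random <= 0) stop_config("prior scales must be > 0")
  mods <- bf_models(effect)
  design <- bf_design(table)
  set.seed(as.integer(seed))
  marg <- function(effects) {
    r_vec <- ifelse(effects == "subject", r_random, r_fixed)
    integrate_marginal(prep_model(design, effects), r_vec, n_samples)
  }
  m_alt <- marg(mods$alt)
  m_null <- marg(mods$null)
  log_bf <- m_alt$log_marginal - m_null$log_marginal
  mc <- sqrt(m_alt$rel_mc_error^2 + m_null$rel_mc_error^2)
  new_bf_result(tibble::tibble(
    effect = effect, bf10 = exp(log_bf), log_bf10 = log_bf,
    mc_error = mc, n_samples = n_samples,
    interpretation = interpret_bf(exp(log_bf)),
    converged = mc <= mc_error_threshold
  ), r_fixed, r_random)
}

#' All three Bayes factors of the design
#'
#' Runs [bayes_factor()] for the eyeshadow and orientation main effects and
#' the interaction, sharing the model marginals so each distinct model is
#' integrated once.
#'
#' @inheritParams bayes_factor
#' @return A `bf_result` with one row per effect.
#' @export
anova_bf <- function(table, r_fixed = 0.5, r_random = 1, n_samples = 10000,
                     seed, mc_error_threshold = 0.05) {
  if (missing(seed)) stop_config("a seed is required for the BF integration")
  design <- bf_design(table)
  set.seed(as.integer(seed))
  cache <- new.env(parent = emptyenv())
  marg <- function(effects) {
    key <- paste(sort(effects), collapse = "+")
    if (!is.null(cache[[key]])) return(cache[[key]])
    r_vec <- ifelse(effects == "subject", r_random, r_fixed)
    cache[[key]] <- integrate_marginal(prep_model(design, effects), r_vec,
                                       n_samples)
    cache[[key]]
  }
  rows <- purrr::map_dfr(c("shadow", "orientation", "interaction"),
    function(eff) {
      mods <- bf_models(eff)
      m_alt <- marg(mods$alt); m_null <- marg(mods$null)
      log_bf <- m_alt$log_marginal - m_null$log_marginal
      mc <- sqrt(m_alt$rel_mc_error^2 + m_null$rel_mc_error^2)
      tibble::tibble(effect = eff, bf10 = exp(log_bf), log_bf10 = log_bf,
                     mc_error = mc, n_samples = n_samples,
                     interpretation = interpret_bf(exp(log_bf)),
                     converged = mc <= mc_error_threshold)
    })
  if (any(!rows$converged))
    warning("BF integration above the MC error threshold for: ",
            paste(rows$effect[!rows$converged], collapse = ", "))
  new_bf_result(rows, r_fixed, r_random)
}

new_bf_result <- function(rows, r_fixed, r_random) {
  structure(list(results = rows, r_fixed = r_fixed, r_random = r_random),
            class = "bf_result")
}

#' Interpret a Bayes factor on Jeffreys' bands
#'
#' BF10 below 1/10 is strong and 1/10 to 1/3 substantial evidence for the
#' null; 3 to 10 substantial and above 10 strong evidence for the
#' alternative; 1/3 to 3 is inconclusive.
#'
#' @param bf10 Positive Bayes factor(s), alternative over null.
#' @return Character label(s): `"strong_null"`, `"substantial_null"`,
#'   `"inconclusive"`, `"substantial_alternative"`, `"strong_alternative"`.
#' @export
#' @examples
#' interpret_bf(c(0.05, 1, 20))
interpret_bf <- function(bf10) {
  if (any(!is.finite(bf10) | bf10 <= 0))
    stop_usage("bf10 must be positive and finite")
  cut_labels <- c("strong_null", "substantial_null", "inconclusive",
                  "substantial_alternative", "strong_alternative")
  as.character(cut(bf10, c(0, 1 / 10, 1 / 3, 3, 10, Inf),
                   labels = cut_labels, right = TRUE))
}

format_bf <- function(bf10) {
  vapply(bf10, function(b) {
    if (b >= 1000 || (b > 0 && b < 1e-3)) {
      e <- floor(log10(b))
      sprintf("%.2f x 10^%d", b / 10^e, e)
    } else sprintf("%.2f", b)
  }, character(1))
}

#' @export
print.bf_result <- function(x, ...) {
  cat("Default g-prior Bayes factors (r_fixed = ", x$r_fixed,
      ", r_random = ", x$r_random, ")\n", sep = "")
  r <- x$results
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %s: BF10 = %s (%s; rel. MC error %.1f%%)\n",
                r$effect[i], format_bf(r$bf10[i]),
                gsub("_", " ", r$interpretation[i]), 100 * r$mc_error[i]))
  invisible(x)
}

#' @rdname bayes_factor
#' @param x A `bf_result` object.
#' @param ... Unused.
#' @method tidy bf_result
#' @export
tidy.bf_result <- function(x, ...) x$results

#' @rdname bayes_factor
#' @method glance bf_result
#' @export
glance.bf_result <- function(x, ...) {
  tibble::tibble(r_fixed = x$r_fixed, r_random = x$r_random,
                 n_effects = nrow(x$results),
                 all_converged = all(x$results$converged))
}
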