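# Orthonormal basis of the sum-to-zero (contrast) space of a k-level factor:
# k x (k-1), columns orthonormal and orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  if (k < 2) stop_usage("a within factor needs >= 2 levels")
  qr.Q(qr(cbind(rep(1 / sqrt(k), k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

eps_from_contrast <- function(Y, C) {
  S <- cov(Y %*% C)
  d <- ncol(C)
  tr <- sum(diag(S))
  if (tr <= .Machine$double.eps * nrow(Y)) return(list(gg = 1, d = d, S = S))
  list(gg = tr^2 / (d * sum(S^2)), d = d, S = S)
}

# Huynh-Feldt family from the GG estimate; n subjects, n_groups grouping
# levels (1 for fully within designs), d = numerator df of the effect.
# hf: Huynh & Feldt (1976) as printed; cm: Lecoutre's corrected formula
# (identical when n_groups = 1). Both clamped to [1/d, 1].
hf_family <- function(gg, n, d, n_groups = 1) {
  clamp <- function(e) min(max(e, 1 / d), 1)
  den <- d * (n - n_groups - d * gg)
  hf <- if (den <= 0) 1 else (n * d * gg - 2) / den
  cm <- if (den <= 0) 1 else ((n - n_groups + 1) * d * gg - 2) / den
  list(gg = clamp(gg), hf = clamp(hf), cm = clamp(cm))
}

#' Sphericity epsilon of a within-subject factor
#'
#' Estimates the sphericity correction factor from the covariance of the
#' orthonormally contrast-transformed repeated measures. `"gg"` is the
#' Greenhouse-Geisser estimate \eqn{(\sum\lambda)^2 / ((k-1)\sum\lambda^2)}
#' on the eigenvalues of that covariance; `"hf"` is the Huynh-Feldt
#' adjustment and `"cm"` its Lecoutre-corrected variant (used for the
#' reported, capped epsilon; the two coincide in a single-group fully
#' within-subject design). All estimates are clamped to
#' \eqn{[1/(k-1),\ 1]}. A factor with 2 levels has a single contrast, so
#' every epsilon is exactly 1.
#'
#' @param cell_data Numeric matrix, subjects in rows, the factor's k levels
#'   in columns.
#' @param method `"gg"`, `"hf"` or `"cm"`; or `"all"` for a named list.
#' @return A single epsilon, or a list of all three.
#' @export
sphericity_epsilon <- function(cell_data, method = c("cm", "gg", "hf", "all")) {
  method <- match.arg(method)
  cell_data <- as.matrix(cell_data)
  k <- ncol(cell_data)
  n <- nrow(cell_data)
  if (k < 2) stop_usage("sphericity needs >= 2 levels")
  if (n <= k)
    warning("fewer subjects than factor levels + 1; epsilon is unstable")
  e <- eps_from_contrast(cell_data, orthonormal_contrasts(k))
  fam <- hf_family(e$gg, n, e$d)
  if (method == "all") fam else fam[[method]]
}

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta_p^2 = F\,df_1 / (F\,df_1 + df_2)}, algebraically identical to
#' \eqn{SS_{effect} / (SS_{effect} + SS_{error})} for the matching error term.
#' Kept at full precision; round only for reporting.
#'
#' @param f_stat F ratio (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0); may be
#'   epsilon-corrected, the identity is invariant to a common multiplier.
#' @return Effect-size proportion in [0, 1].
#' @export
#' @examples
#' partial_eta_squared(35.45, 1, 19) # 0.651 to 3 decimals
partial_eta_squared <- function(f_stat, df1, df2) {
  if (any(f_stat < 0) || any(df1 <= 0) || any(df2 <= 0))
    stop_usage("f_stat must be >= 0 and dfs > 0")
  f_stat * df1 / (f_stat * df1 + df2)
}

#' Epsilon-corrected p-value of a within-subject F test
#'
#' Upper-tail F probability at \eqn{(\epsilon\,df_1,\ \epsilon\,df_2)}.
#'
#' @inheritParams partial_eta_squared
#' @param epsilon Sphericity correction factor in (0, 1].
#' @return The corrected p-value.
#' @export
corrected_p <- function(f_stat, df1, df2, epsilon = 1) {
  if (any(epsilon <= 0) || any(epsilon > 1))
    stop_usage("epsilon must lie in (0, 1]")
  if (any(f_stat < 0)) stop_usage("f_stat must be >= 0")
  pf(f_stat, epsilon * df1, epsilon * df2, lower.tail = FALSE)
}

#' Two-way fully-within-subject ANOVA of a PSE table
#'
#' Classical repeated-measures decomposition for the eyeshadow (2 levels) by
#' orientation (k levels) design: each effect is tested against its own
#' effect-by-subject interaction mean square. Sphericity epsilons
#' (Greenhouse-Geisser, Huynh-Feldt, Lecoutre-corrected Huynh-Feldt) are
#' estimated per effect from the orthonormal-contrast covariance, and the
#' reported p-value uses the selected epsilon applied to both dfs. Cells with
#' zero error variance yield flagged infinite (or undefined) F ratios rather
#' than silent numbers.
#'
#' @param table A complete balanced [pse_table()].
#' @param epsilon_method Which epsilon corrects the reported dfs and p:
#'   `"cm"` (default), `"gg"`, `"hf"` or `"none"`.
#' @return An object of class `rm_anova`; `tidy()` returns the per-effect
#'   table (`effect`, `ss_effect`, `ss_error`, `df1`, `df2`, `f_stat`,
#'   `partial_eta_sq`, `epsilon_gg`, `epsilon_hf`, `epsilon_cm`, `epsilon`,
#'   `df1_corr`, `df2_corr`, `p_uncorrected`, `p_corr`, `flag`).
#' @export
#' @examples
#' pop <- sample_population(population_spec(n_subjects = 6,
#'                                          angles = c(-30, 0, 30)), seed = 1)
#' tbl <- simulate_pse_table(pop, seed = 2)
#' two_way_rm_anova(tbl)
two_way_rm_anova <- function(table, epsilon_method = c("cm", "gg", "hf", "none")) {
  epsilon_method <- match.arg(epsilon_method)
  table <- validate_pse_table(table)
  subj <- factor(table$subject_id)
  A <- factor(table$shadow)        # eyeshadow
  B <- factor(table$angle)         # orientation
  n <- nlevels(subj); a <- nlevels(A); b <- nlevels(B)
  if (n < 2) stop_structure("need >= 2 subjects")
  y <- table$pse

  m   <- mean(y)
  m_i <- tapply(y, A, mean); m_j <- tapply(y, B, mean)
  m_s <- tapply(y, subj, mean)
  m_ij <- tapply(y, list(A, B), mean)
  m_is <- tapply(y, list(A, subj), mean)
  m_js <- tapply(y, list(B, subj), mean)

  ss_A  <- n * b * sum((m_i - m)^2)
  ss_B  <- n * a * sum((m_j - m)^2)
  ss_S  <- a * b * sum((m_s - m)^2)
  ss_AB <- n * sum(sweep(sweep(m_ij - m, 1, m_i - m), 2, m_j - m)^2)
  ss_AS <- b * sum(sweep(sweep(m_is - m, 1, m_i - m), 2, m_s - m)^2)
  ss_BS <- a * sum(sweep(sweep(m_js - m, 1, m_j - m), 2, m_s - m)^2)
  fit <- m + (m_is[cbind(A, subj)] - m) + (m_js[cbind(B, subj)] - m) +
    (m_ij[cbind(A, B)] - m) - (m_i[A] - m) - (m_j[B] - m) - (m_s[subj] - m)
  ss_ABS <- sum((y - fit)^2)
  ss_total <- sum((y - m)^2)

  # subject x cell matrix, cells ordered angle-within-shadow to match the
  # Kronecker contrast ordering below
  wide <- tapply(y, list(subj, A, B), mean)
  cells <- matrix(aperm(wide, c(1, 3, 2)), nrow = n)  # columns: (i, j) i slow
  Qa <- orthonormal_contrasts(a); Qb <- orthonormal_contrasts(b)
  ones_a <- matrix(1 / a, a, 1); ones_b <- matrix(1 / b, b, 1)
  eps_of <- function(C) {
    e <- eps_from_contrast(cells, C)
    hf_family(e$gg, n, ncol(C))
  }
  eps <- list(shadow = eps_of(Qa %x% ones_b),
              orientation = eps_of(ones_a %x% Qb),
              interaction = eps_of(Qa %x% Qb))

  mk <- function(effect, ss_e, ss_err, df1, df2, ep) {
    if (ss_err <= .Machine$double.eps * length(y)) {
      f <- if (ss_e <= .Machine$double.eps * length(y)) NaN else Inf
      flag <- "zero_error_variance"
    } else {
      f <- (ss_e / df1) / (ss_err / df2)
      flag <- NA_character_
    }
    e_use <- if (epsilon_method == "none") 1 else ep[[epsilon_method]]
    tibble::tibble(
      effect = effect, ss_effect = ss_e, ss_error = ss_err,
      df1 = df1, df2 = df2, f_stat = f,
      partial_eta_sq = if (is.finite(f)) partial_eta_squared(f, df1, df2)
                       else if (is.nan(f)) NaN else 1,
      epsilon_gg = ep$gg, epsilon_hf = ep$hf, epsilon_cm = ep$cm,
      epsilon = e_use, df1_corr = e_use * df1, df2_corr = e_use * df2,
      p_uncorrected = if (is.finite(f)) pf(f, df1, df2, lower.tail = FALSE)
                      else if (is.nan(f)) NaN else 0,
      p_corr = if (is.finite(f)) corrected_p(f, df1, df2, e_use)
               else if (is.nan(f)) NaN else 0,
      flag = flag
    )
  }
  effects <- dplyr::bind_rows(
    mk("shadow", ss_A, ss_AS, a - 1, (a - 1) * (n - 1), eps$shadow),
    mk("orientation", ss_B, ss_BS, b - 1, (b - 1) * (n - 1), eps$orientation),
    mk("interaction", ss_AB, ss_ABS, (a - 1) * (b - 1),
       (a - 1) * (b - 1) * (n - 1), eps$interaction)
  )
  structure(
    list(effects = effects, ss_subject = ss_S, ss_total = ss_total,
         n_subjects = n, n_shadow = a, n_angles = b,
         epsilon_method = epsilon_method),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way within-subject ANOVA (", x$n_subjects, " subjects, ",
      x$n_shadow, " x ", x$n_angles, " design; epsilon = ",
      x$epsilon_method, ")\n\n", sep = "")
  for (i in seq_len(nrow(x$effects))) cat(" ", report_effect(x$effects[i, ]), "\n")
  invisible(x)
}

# inline statistics formatted the way psychophysics papers print them:
# F and epsilon to 2 decimals, eta_p^2 and p to 3
report_effect <- function(row) {
  pfmt <- function(p) {
    if (is.nan(p)) return("p undefined")
    if (p < .001) "p < .001"
    else paste0("p = ", sub("^0", "", sprintf("%.3f", p)))
  }
  sprintf("%s: F(%.2f, %.2f) = %.2f, eta_p^2 = %s, %s, epsilon = %.2f",
          row$effect, row$df1_corr, row$df2_corr, row$f_stat,
          sub("^0", "", sprintf("%.3f", row$partial_eta_sq)),
          pfmt(row$p_corr), row$epsilon)
}

#' @rdname two_way_rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @rdname two_way_rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_shadow = x$n_shadow,
                 n_angles = x$n_angles, ss_subject = x$ss_subject,
                 ss_total = x$ss_total, epsilon_method = x$epsilon_method)
}
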