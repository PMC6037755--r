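#' One-factor repeated-measures ANOVA across sessions
#'
#' Within-subject decomposition with session as the random factor and
#' condition as the fixed factor: `F = MS_condition / MS_error` where the
#' error term is the session-by-condition interaction, with
#' `df = (k - 1), (k - 1)(n - 1)`. No sphericity correction is applied.
#' Sessions with missing cells are dropped (and logged in the result).
#' Post-hoc pairwise comparisons use the Tukey-Kramer method on the
#' condition means with the ANOVA error mean square.
#'
#' @param x numeric matrix, sessions in rows, conditions in columns.
#' @return Object of class `rm_anova`: `F`, `df`, `p`, `means`, `sem`,
#'   `ms_error`, `posthoc` (pairwise Tukey-Kramer p-values),
#'   `dropped_sessions`.
#' @export
rm_anova <- function(x) {
  x <- as.matrix(x)
  keep <- complete.cases(x)
  dropped <- which(!keep)
  x <- x[keep, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("need at least 2 complete sessions")
  g <- mean(x)
  mc <- colMeans(x); ms <- rowMeans(x)
  ss_cond <- n * sum((mc - g)^2)
  ss_subj <- k * sum((ms - g)^2)
  ss_tot <- sum((x - g)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  ms_err <- ss_err / df2
  Fv <- if (ms_err > 0) (ss_cond / df1) / ms_err else 0
  p <- if (ms_err > 0) stats::pf(Fv, df1, df2, lower.tail = FALSE) else 1
  cn <- colnames(x) %||% paste0("c", seq_len(k))
  ph <- matrix(NA_real_, k, k, dimnames = list(cn, cn))
  if (ms_err > 0) {
    for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
      q <- abs(mc[i] - mc[j]) / sqrt(ms_err / n)
      ph[i, j] <- ph[j, i] <- ptukey(q, k, df2, lower.tail = FALSE)
    }
  }
  structure(list(F = Fv, df = c(df1, df2), p = p,
                 means = setNames(mc, cn),
                 sem = setNames(apply(x, 2L, sd) / sqrt(n), cn),
                 ms_error = ms_err, posthoc = ph,
                 dropped_sessions = dropped, n_sessions = n),
            class = "rm_anova")
}

#' @importFrom stats pf
NULL

#' Two-factor repeated-measures ANOVA
#'
#' Both factors within-subject (e.g. attention condition and microsaccade
#' direction), session as the random factor, one observation per cell.
#' Each effect is tested against its interaction with session.
#'
#' @param x 3-d array `sessions x factor A x factor B`.
#' @return List of `rm_anova`-style results for `A`, `B`, and `A:B`,
#'   each with `F`, `df`, `p`.
#' @export
rm_anova2 <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[1L]; a <- dim(x)[2L]; b <- dim(x)[3L]
  if (n < 2L) stop("need at least 2 sessions")
  g <- mean(x)
  m_s <- apply(x, 1L, mean); m_a <- apply(x, 2L, mean); m_b <- apply(x, 3L, mean)
  m_sa <- apply(x, c(1L, 2L), mean); m_sb <- apply(x, c(1L, 3L), mean)
  m_ab <- apply(x, c(2L, 3L), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1L, m_a), 2L, m_b) + g)^2)
  ss_sa <- b * sum((sweep(sweep(m_sa, 1L, m_s), 2L, m_a) + g)^2)
  ss_sb <- a * sum((sweep(sweep(m_sb, 1L, m_s), 2L, m_b) + g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_tot <- sum((x - g)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  eff <- function(ss, df, ss_e, df_e) {
    Fv <- (ss / df) / (ss_e / df_e)
    list(F = Fv, df = c(df, df_e), p = stats::pf(Fv, df, df_e, lower.tail = FALSE))
  }
  list(
    A = eff(ss_a, a - 1L, ss_sa, (a - 1L) * (n - 1L)),
    B = eff(ss_b, b - 1L, ss_sb, (b - 1L) * (n - 1L)),
    AB = eff(ss_ab, (a - 1L) * (b - 1L), ss_sab, (a - 1L) * (b - 1L) * (n - 1L))
  )
}

#' One-tailed contrast test for elevated Attend-Both values
#'
#' Per-session contrast `c = AB - (AI + AO) / 2`, tested against zero with
#' a one-sample, one-tailed t-test (alternative: AB greater), the planned
#' comparison for attention-state variability being largest when both
#' stimuli are relevant.
#'
#' @param x matrix or data frame with columns named `AI`, `AB`, `AO`,
#'   sessions in rows.
#' @return List with `t`, `df`, `p` (one-tailed), `mean_contrast`,
#'   `contrasts`.
#' @export
ab_contrast_test <- function(x) {
  x <- as.matrix(x)
  stopifnot(all(c("AI", "AB", "AO") %in% colnames(x)))
  keep <- complete.cases(x[, c("AI", "AB", "AO")])
  cc <- x[keep, "AB"] - (x[keep, "AI"] + x[keep, "AO"]) / 2
  n <- length(cc)
  if (n < 2L) stop("need at least 2 sessions with all three conditions")
  s <- sd(cc)
  if (s == 0) {
    warning("zero variance of contrast: degenerate test")
    t <- if (mean(cc) == 0) 0 else sign(mean(cc)) * Inf
    return(list(t = t, df = n - 1L, p = pt(t, n - 1L, lower.tail = FALSE),
                mean_contrast = mean(cc), contrasts = cc))
  }
  t <- mean(cc) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = pt(t, n - 1L, lower.tail = FALSE),
       mean_contrast = mean(cc), contrasts = cc)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level.
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) alpha / m
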