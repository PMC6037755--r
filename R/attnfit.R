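#' Fit a von Mises function to a tuning curve
#'
#' Nonlinear least squares of `Y = w1 + exp(w2 + w3 * cos(x - w4))` to a
#' 36-point tuning curve, where `x` is the doubled orientation angle in
#' radians so that the 180-degree periodicity of orientation tuning maps
#' onto the von Mises period. `w1` is the offset, `exp(w2)` the gain, `w3`
#' the shape (concentration) and `w4` the preferred orientation on the
#' doubled-angle circle. The fit is multi-started over a grid of `w4`
#' values and refined by Levenberg-Marquardt with `w3` bounded below at
#' zero; the best-residual start wins.
#'
#' @param tc a [estimate_tuning()] result, or a numeric vector of responses.
#' @param orient_deg orientations (deg) of the curve points; taken from the
#'   tuning curve when available.
#' @param n_starts number of `w4` starting values.
#' @return An object of class `von_mises_fit`: `w1`, `w2`, `w3`, `w4`
#'   (radians, doubled angle, in `[0, 2*pi)`), `pref_deg` (`w4` mapped back
#'   to orientation degrees), `residual_var`, `converged`, and
#'   `degenerate` (`TRUE` when the curve is flat and `w4` unidentifiable).
#' @export
fit_von_mises <- function(tc, orient_deg = NULL, n_starts = 8L) {
  y <- if (inherits(tc, "tuning_curve")) tc$curve else as.numeric(tc)
  if (is.null(orient_deg))
    orient_deg <- if (inherits(tc, "tuning_curve")) tc$grid
                  else (seq_along(y) - 1L) * 180 / length(y)
  x <- 2 * orient_deg * pi / 180
  if (var(y) == 0) {
    return(structure(list(w1 = mean(y), w2 = -Inf, w3 = 0, w4 = NA_real_,
                          pref_deg = NA_real_, residual_var = 0,
                          converged = TRUE, degenerate = TRUE),
                     class = "von_mises_fit"))
  }
  amp0 <- max(max(y) - min(y), 1e-3)
  best <- NULL
  for (w4s in (seq_len(n_starts) - 1L) * 2 * pi / n_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ w1 + exp(w2 + w3 * cos(x - w4)),
        start = list(w1 = min(y), w2 = log(amp0), w3 = 1, w4 = w4s),
        lower = c(-Inf, -Inf, 0, -Inf), upper = c(Inf, Inf, 50, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(w1 = NA_real_, w2 = NA_real_, w3 = NA_real_,
                          w4 = NA_real_, pref_deg = NA_real_,
                          residual_var = NA_real_, converged = FALSE,
                          degenerate = FALSE),
                     class = "von_mises_fit"))
  }
  cf <- coef(best$fit)
  w4 <- cf[["w4"]] %% (2 * pi)
  degen <- cf[["w3"]] < 1e-6
  structure(list(
    w1 = cf[["w1"]], w2 = cf[["w2"]], w3 = cf[["w3"]],
    w4 = if (degen) NA_real_ else w4,
    pref_deg = if (degen) NA_real_ else (w4 * 90 / pi) %% 180,
    residual_var = best$rss / (length(y) - 4L),
    converged = TRUE, degenerate = degen
  ), class = "von_mises_fit")
}

#' @importFrom stats residuals
NULL

#' Condition-wise gain/offset modulation of a tuning curve
#'
#' With the shape `w3` and preferred orientation `w4` fixed from the overall
#' fit, per-orientation responses in two attention conditions are regressed
#' on the von Mises basis `theta_i = exp(w3 * cos(x_i - w4))`:
#' `y_i = b0 + b1 * theta_i + b2 * X2 + b3 * theta_i * X2`,
#' where `X2` codes the comparison condition (0 = reference, e.g. Attend
#' Out; 1 = comparison, e.g. Attend In). An F-test of the full model
#' against the reduced model (`b0`, `b1` only) assesses attentional
#' modulation; when significant, t-tests on `b2` (offset) and `b3` (gain)
#' classify the modulation as gain, offset, mixed, or indeterminate.
#'
#' @param y_ref,y_cmp per-orientation mean responses in the reference and
#'   comparison condition.
#' @param base a converged [fit_von_mises()] result providing `w3`, `w4`.
#' @param orient_deg orientations (deg) of the responses.
#' @param n_ref,n_cmp optional per-orientation trial counts used as
#'   regression weights.
#' @param alpha significance level for the omnibus F and coefficient tests.
#' @return An object of class `condition_modulation_fit` with `betas`,
#'   `se`, `t`, `p_coef`, `F`, `df`, `p_F`, and `classification` in
#'   `c("none", "gain", "offset", "mixed")`.
#' @export
fit_condition_modulation <- function(y_ref, y_cmp, base, orient_deg = NULL,
                                     n_ref = NULL, n_cmp = NULL,
                                     alpha = 0.05) {
  if (!isTRUE(base$converged) || isTRUE(base$degenerate))
    stop("base von Mises fit did not converge or is degenerate")
  if (!length(y_ref) || !length(y_cmp))
    stop("both conditions need responses")
  if (is.null(orient_deg)) orient_deg <- (seq_along(y_ref) - 1L) * 180 / length(y_ref)
  x <- 2 * orient_deg * pi / 180
  theta <- exp(base$w3 * cos(x - base$w4))
  df <- data.frame(
    y = c(y_ref, y_cmp),
    X1 = rep(theta, 2L),
    X2 = rep(c(0, 1), each = length(theta))
  )
  w <- if (!is.null(n_ref)) c(n_ref, n_cmp) else rep(1, nrow(df))
  full <- lm(y ~ X1 + X2 + X1:X2, data = df, weights = w)
  red <- lm(y ~ X1, data = df, weights = w)
  an <- anova(red, full)
  Fstat <- an$F[2L]; pF <- an$`Pr(>F)`[2L]
  sm <- summary(full)$coefficients
  betas <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  tv <- sm[, "t value"]; pv <- sm[, "Pr(>|t|)"]
  names(betas) <- names(se) <- names(tv) <- names(pv) <-
    c("b0", "b1", "b2", "b3")[seq_len(nrow(sm))]
  cls <- "none"
  if (!is.na(pF) && pF < alpha) {
    off_sig <- pv[["b2"]] < alpha
    gain_sig <- pv[["b3"]] < alpha
    cls <- if (gain_sig && off_sig) "mixed"
           else if (gain_sig) "gain"
           else if (off_sig) "offset"
           else "mixed"  # omnibus-significant but diffuse: jointly modulated
  }
  structure(list(betas = betas, se = se, t = tv, p_coef = pv,
                 F = Fstat, df = c(an$Df[2L], an$Res.Df[2L]), p_F = pF,
                 theta = theta, classification = cls),
            class = "condition_modulation_fit")
}
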