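#' Remove extreme values
#'
#' Single-pass trimming: values farther than `k` standard deviations from
#' the mean of the full vector are dropped (strict inequality, so a value
#' at exactly k SD is retained). Applied per dependent measure before
#' modeling; not iterated.
#'
#' @param x Numeric vector (>= 3 values).
#' @param k Threshold in standard deviations.
#' @return A list: `values` (kept), `kept` (logical index), `removed`
#'   (indices dropped).
#' @export
remove_outliers <- function(x, k = 3) {
  if (length(x) < 3) stop("need at least 3 values")
  s <- stats::sd(x)
  keep <- if (s == 0) rep(TRUE, length(x)) else abs(x - mean(x)) <= k * s
  list(values = x[keep], kept = keep, removed = which(!keep))
}

model_result <- function(terms, coefficients, n_obs, n_participants = NA) {
  stopifnot(all(terms$p >= 0 & terms$p <= 1, na.rm = TRUE))
  structure(list(terms = terms, coefficients = coefficients, n_obs = n_obs,
                 n_participants = n_participants),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> n_obs = %d\n", x$n_obs))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Gaussian GLM of a feedback power measure on the discounting factor
#'
#' One row per participant: `measure ~ df`, Gaussian family with identity
#' link (equivalent to ordinary least squares), with the discounting-factor
#' effect tested by an F statistic on (1, n - 2) degrees of freedom.
#'
#' @param data Data.frame with columns named by `measure` and `"df"`.
#' @param measure Name of the dependent column.
#' @param family A [stats::family] object (Gaussian identity by default).
#' @return A `model_result` with the DF term's F test and the slope.
#' @export
fit_power_glm <- function(data, measure, family = stats::gaussian()) {
  f <- stats::as.formula(paste(measure, "~ df"))
  fit <- stats::glm(f, data = data, family = family)
  an <- stats::anova(fit, test = "F")
  terms <- data.frame(name = "df",
                      F = an["df", "F"],
                      df_num = an["df", "Df"],
                      df_den = fit$df.residual,
                      p = an["df", "Pr(>F)"])
  co <- summary(fit)$coefficients
  coefficients <- data.frame(name = rownames(co), estimate = co[, 1],
                             se = co[, 2], row.names = NULL)
  model_result(terms, coefficients, n_obs = nrow(data),
               n_participants = nrow(data))
}

#' Linear mixed model of anticipatory alpha PSD
#'
#' Fits `alpha_psd ~ delay_level * df + (1 | participant)` by REML, with
#' the delay level (7/15/30 s) as a categorical within-participant factor
#' (sum-to-zero contrasts), the discounting factor as a continuous
#' between-participant predictor, and a random intercept per participant.
#' Fixed effects are tested with Type-III F statistics and Satterthwaite
#' denominator degrees of freedom, which tolerates missing or unbalanced
#' cells.
#'
#' @param data Long-format data.frame with columns `alpha_psd`,
#'   `delay_level`, `df`, `participant` (at most one row per participant
#'   and level).
#' @return A `model_result`; `terms` has one row per fixed effect
#'   (`df`, `delay_level`, `delay_level:df`) and `coefficients` includes
#'   the DF slope (at the average delay level, given the sum contrasts).
#'   The fitted `lmerMod` is attached as attribute `"fit"`.
#' @export
fit_alpha_lmm <- function(data) {
  if (length(unique(data$participant)) < 2)
    stop("need at least 2 participants")
  data$delay_level <- factor(data$delay_level)
  data$participant <- factor(data$participant)
  fit <- lmerTest::lmer(
    alpha_psd ~ delay_level * df + (1 | participant), data = data,
    REML = TRUE,
    contrasts = list(delay_level = stats::contr.sum))
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  terms <- data.frame(name = rownames(an), F = an[, "F value"],
                      df_num = an[, "NumDF"], df_den = an[, "DenDF"],
                      p = an[, "Pr(>F)"], row.names = NULL)
  co <- summary(fit)$coefficients
  coefficients <- data.frame(name = rownames(co), estimate = co[, "Estimate"],
                             se = co[, "Std. Error"], row.names = NULL)
  res <- model_result(terms, coefficients, n_obs = nrow(data),
                      n_participants = length(unique(data$participant)))
  attr(res, "fit") <- fit
  res
}

#' FDR-adjusted post-hoc comparisons
#'
#' Pairwise comparisons of the factor's estimated marginal means with
#' Benjamini-Hochberg adjustment over the comparison family.
#'
#' @param model A `model_result` from [fit_alpha_lmm()] (the fitted model
#'   is read from its `"fit"` attribute) or a fitted model object.
#' @param factor Name of the categorical factor (e.g. `"delay_level"`).
#' @return Data.frame with `contrast`, `estimate`, `se`, `p_raw`, `p_fdr`.
#' @export
posthoc_tests <- function(model, factor = "delay_level") {
  fit <- if (inherits(model, "model_result")) attr(model, "fit") else model
  emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", factor)))
  ct <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  data.frame(contrast = as.character(ct$contrast), estimate = ct$estimate,
             se = ct$SE, p_raw = ct$p.value,
             p_fdr = stats::p.adjust(ct$p.value, method = "BH"))
}

#' Simple slopes of the continuous predictor per factor level
#'
#' The slope of the discounting factor within each delay level, with
#' standard errors and tests — the follow-up for a significant
#' continuous-by-categorical interaction.
#'
#' @inheritParams posthoc_tests
#' @param var Name of the continuous predictor (default `"df"`).
#' @return Data.frame with one row per factor level: `level`, `slope`,
#'   `se`, `df`, `p`.
#' @export
simple_slopes <- function(model, factor = "delay_level", var = "df") {
  fit <- if (inherits(model, "model_result")) attr(model, "fit") else model
  tr <- summary(emmeans::emtrends(
    fit, stats::as.formula(paste("~", factor)), var = var,
    infer = c(FALSE, TRUE)))
  data.frame(level = as.character(tr[[factor]]),
             slope = tr[[paste0(var, ".trend")]], se = tr$SE,
             df = tr$df, p = tr$p.value)
}
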