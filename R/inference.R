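#' Trial-level hierarchical models
#'
#' Thin, contract-stable wrappers around `lme4`/`lmerTest` fits with
#' `emmeans` marginal means and corrected pairwise contrasts, mirroring the
#' trial-level analysis chain: a linear model with a participant random
#' intercept for pre-event amplitude/power, a linear model with a
#' time-by-condition interaction and a participant random effect of
#' condition for pre-event slopes, and a logistic model with participant
#' random slopes for report probability over probe time.
#'
#' `fit_linear_random_intercept()` fits
#' `outcome ~ condition + (1 | participant)` (REML by default; the estimator
#' is recorded in the result). A singular fit (zero random-effect variance)
#' is flagged, not an error.
#'
#' @param data a data frame / tibble of single-trial records
#' @param outcome name of the outcome column
#' @param condition name of the categorical predictor (default "condition")
#' @param participant name of the grouping column (default "participant")
#' @param reml use REML (default) or ML
#' @param adjust default p-value adjustment for the pairwise contrasts
#'   (`"tukey"` or `"fdr"`)
#' @return a `pa_fit` object: the fitted model, per-condition marginal means,
#'   pairwise contrasts with corrected p-values, and method flags. Supports
#'   `tidy()`, `glance()`, and `posthoc_pairwise()`.
#' @export
fit_linear_random_intercept <- function(data, outcome,
                                        condition = "condition",
                                        participant = "participant",
                                        reml = TRUE, adjust = "tukey") {
  data <- as.data.frame(data)
  data[[condition]] <- factor(data[[condition]])
  data[[participant]] <- factor(data[[participant]])
  if (nlevels(data[[participant]]) < 2) {
    stop("Need at least 2 participants.", call. = FALSE)
  }
  if (nlevels(data[[condition]]) < 2) {
    stop("Need at least 2 condition levels.", call. = FALSE)
  }
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)",
                                   outcome, condition, participant))
  fit <- lmerTest::lmer(fml, data = data, REML = reml)
  emm <- emmeans::emmeans(fit, specs = condition,
                          lmer.df = "satterthwaite")
  new_pa_fit(fit, emm, outcome = outcome, predictor = condition,
             estimator = if (reml) "REML" else "ML", adjust = adjust,
             singular = lme4::isSingular(fit))
}

new_pa_fit <- function(model, emm, outcome, predictor, estimator, adjust,
                       singular = FALSE, downgraded = FALSE, extra = list()) {
  means <- if (!is.null(emm)) tibble::as_tibble(as.data.frame(emm)) else NULL
  contrasts <- if (!is.null(emm)) {
    tibble::as_tibble(as.data.frame(emmeans::contrast(
      emm, method = "pairwise", adjust = adjust)))
  } else NULL
  structure(
    c(list(model = model, emmeans = emm, means = means, contrasts = contrasts,
           outcome = outcome, predictor = predictor,
           method = list(estimator = estimator, df = "satterthwaite",
                         adjust = adjust),
           singular = singular, downgraded = downgraded), extra),
    class = "pa_fit")
}

#' @exportS3Method base::print
print.pa_fit <- function(x, ...) {
  cat(sprintf("<pa_fit> %s ~ %s (%s%s%s)\n", x$outcome, x$predictor,
              x$method$estimator,
              if (x$singular) ", singular fit" else "",
              if (x$downgraded) ", random structure downgraded" else ""))
  if (!is.null(x$means)) {
    print(x$means)
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' @describeIn fit_linear_random_intercept fixed-effect estimates as a tibble
#' @param x a `pa_fit`
#' @param ... unused
#' @export
tidy.pa_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  out <- tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                        std.error = sm[, "Std. Error"])
  if ("df" %in% colnames(sm)) out$df <- sm[, "df"]
  stat_col <- intersect(c("t value", "z value"), colnames(sm))[1]
  out$statistic <- sm[, stat_col]
  p_col <- intersect(c("Pr(>|t|)", "Pr(>|z|)"), colnames(sm))
  if (length(p_col)) out$p.value <- sm[, p_col[1]]
  out
}

#' @describeIn fit_linear_random_intercept one-row model summary
#' @export
glance.pa_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    nobs = stats::nobs(m),
    ngrps = sum(unlist(lapply(lme4::ranef(m), nrow))),
    sigma = stats::sigma(m),
    logLik = as.numeric(stats::logLik(m)),
    AIC = stats::AIC(m),
    singular = x$singular,
    downgraded = x$downgraded,
    estimator = x$method$estimator
  )
}

#' Linear model with a time-by-condition interaction
#'
#' Fits `outcome ~ time * condition + (condition | participant)` to
#' un-averaged single-trial samples, yielding per-condition slope estimates
#' and their contrasts (the pre-event slope analysis). If the full
#' random-condition structure fails to converge, the fit falls back to a
#' random intercept with a logged downgrade.
#'
#' @inheritParams fit_linear_random_intercept
#' @param time name of the continuous time column
#' @return a `pa_fit` whose `slopes` field holds per-condition trend
#'   estimates and `contrasts` their pairwise differences
#' @export
fit_linear_with_interaction <- function(data, outcome, time = "time",
                                        condition = "condition",
                                        participant = "participant",
                                        reml = TRUE, adjust = "tukey") {
  data <- as.data.frame(data)
  data[[condition]] <- factor(data[[condition]])
  data[[participant]] <- factor(data[[participant]])
  full <- stats::as.formula(sprintf("%s ~ %s * %s + (%s | %s)", outcome, time,
                                    condition, condition, participant))
  simple <- stats::as.formula(sprintf("%s ~ %s * %s + (1 | %s)", outcome, time,
                                      condition, participant))
  downgraded <- FALSE
  fit <- tryCatch(lmerTest::lmer(full, data = data, REML = reml), error = function(e) NULL)
  if (is.null(fit) || length(fit@optinfo$conv$lme4$messages) > 0) {
    if (!is.null(fit)) {
      message("Random-condition structure did not converge; ",
              "falling back to a random intercept.")
    }
    downgraded <- TRUE
    fit <- lmerTest::lmer(simple, data = data, REML = reml)
  }
  trends <- emmeans::emtrends(fit, specs = condition, var = time,
                              lmer.df = "satterthwaite")
  res <- new_pa_fit(fit, NULL, outcome = outcome, predictor = condition,
                    estimator = if (reml) "REML" else "ML", adjust = adjust,
                    singular = lme4::isSingular(fit), downgraded = downgraded,
                    extra = list(
                      slopes = tibble::as_tibble(as.data.frame(trends)),
                      trend_grid = trends))
  res$contrasts <- tibble::as_tibble(as.data.frame(
    emmeans::contrast(trends, method = "pairwise", adjust = adjust)))
  res
}

#' Logistic mixed model of report probability over probe time
#'
#' Fits `isprep ~ timeprobe + (timeprobe | participant)` (participant random
#' intercept and slope, correlated) by Laplace-approximate maximum
#' likelihood. Complete separation is flagged on the result rather than
#' raised.
#'
#' @inheritParams fit_linear_random_intercept
#' @param outcome binary outcome column (default `"isprep"`)
#' @param time continuous predictor column (default `"timeprobe"`)
#' @return a `pa_fit`; the time slope is the second row of `tidy()`
#' @export
fit_logistic_random_slope <- function(data, outcome = "isprep",
                                      time = "timeprobe",
                                      participant = "participant") {
  data <- as.data.frame(data)
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  y <- data[[outcome]]
  if (length(unique(y)) < 2) {
    stop("Binary outcome must contain both classes.", call. = FALSE)
  }
  data[[participant]] <- factor(data[[participant]])
  fml <- stats::as.formula(sprintf("%s ~ %s + (%s | %s)", outcome, time,
                                   time, participant))
  fit <- lme4::glmer(fml, data = data, family = stats::binomial,
                     control = lme4::glmerControl(optimizer = "bobyqa"))
  separated <- any(abs(lme4::fixef(fit)) > 10)
  res <- new_pa_fit(fit, NULL, outcome = outcome, predictor = time,
                    estimator = "ML (Laplace)", adjust = "none",
                    singular = lme4::isSingular(fit),
                    extra = list(separated = separated))
  if (separated) message("Possible complete separation; estimates flagged.")
  res
}

#' Corrected pairwise post hoc comparisons
#'
#' All pairwise condition contrasts from a fitted model, with Tukey
#' family-wise or Benjamini-Hochberg FDR correction. With two levels the
#' corrected p equals the raw p under either method.
#'
#' @param fit a `pa_fit` from `fit_linear_random_intercept()` (or any fit
#'   carrying an `emmeans` grid)
#' @param method `"tukey"` or `"fdr"`
#' @return tibble with one row per contrast: estimate, SE, df, statistic,
#'   raw and corrected p, and the method
#' @export
posthoc_pairwise <- function(fit, method = c("tukey", "fdr")) {
  method <- match.arg(method)
  grid <- fit$emmeans %||% fit$trend_grid
  if (is.null(grid)) {
    stop("Fit carries no marginal-means grid for contrasts.", call. = FALSE)
  }
  raw <- as.data.frame(emmeans::contrast(grid, method = "pairwise",
                                         adjust = "none"))
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(raw))[1]
  out <- tibble::tibble(
    contrast = as.character(raw$contrast),
    estimate = raw$estimate, se = raw$SE,
    df = if ("df" %in% names(raw)) raw$df else NA_real_,
    statistic = raw[[stat_col]],
    p.raw = raw$p.value
  )
  if (method == "fdr") {
    out$p.corrected <- p.adjust(out$p.raw, method = "BH")
  } else {
    adj <- as.data.frame(emmeans::contrast(grid, method = "pairwise",
                                           adjust = "tukey"))
    out$p.corrected <- pmax(adj$p.value, out$p.raw)
  }
  out$method <- method
  out
}

#' @describeIn fit_linear_random_intercept tidy export of means + contrasts
#' @param fit a `pa_fit`
#' @param path file path for the CSV
#' @export
write_fit_csv <- function(fit, path) {
  tb <- posthoc_pairwise(fit, fit$method$adjust)
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}
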