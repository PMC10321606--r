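# Behavioral stage: per-condition response-time summaries and a linear
# mixed-effects model with condition as fixed effect and crossed random
# intercepts for participant and item.

#' Per-condition response-time summaries
#'
#' Mean, median, SD and a histogram mode (midpoint of the densest 50 ms bin)
#' of the response time (response onset minus question offset), per condition.
#'
#' @param events kept trial-events table; both conditions must be non-empty.
#' @return data.frame with one row per condition: `n`, `mean_s`, `median_s`,
#'   `sd_s`, `mode_s` (all seconds).
#' @export
summarize_rt <- function(events) {
  validate_trial_events(events)
  rt <- response_time(events)
  out <- lapply(CONDITIONS, function(cond) {
    x <- rt[events$condition == cond]
    if (length(x) == 0L) stop("no trials for condition: ", cond)
    bw <- 0.050
    breaks <- seq(floor(min(x) / bw) * bw, ceiling(max(x) / bw) * bw + bw, by = bw)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(condition = cond, n = length(x),
               mean_s = mean(x), median_s = stats::median(x),
               sd_s = if (length(x) > 1L) stats::sd(x) else 0,
               mode_s = h$mids[which.max(h$counts)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the response-time linear mixed-effects model
#'
#' `RT ~ condition + (1 | participant) + (1 | item)` fitted by REML via
#' \pkg{lme4} (random slopes are deliberately absent; with these data they
#' produce singular fits). Reported in milliseconds with a cell-means view:
#' `beta_ep` and `beta_lp` are the model-implied condition means,
#' `condition_effect = beta_lp - beta_ep`, and `t_statistic` is the fixed
#' effect's estimate over its standard error, with `|t| > 2` read as
#' significance at the 5% level. A table with zero residual variance (all RTs
#' equal within condition) short-circuits to the exact closed form with an
#' infinite, flagged t. Singular fits return results with a warning;
#' non-convergence is a labelled error.
#'
#' @param events kept trial-events table with >= 2 participants, >= 2 items
#'   and both conditions.
#' @return list of class `artidelta_rt_model`: `beta_ep_ms`, `beta_lp_ms`,
#'   `condition_effect_ms`, `se_effect_ms`, `t_statistic`, `significant`,
#'   `variance_participant_ms2`, `variance_item_ms2`, `variance_residual_ms2`,
#'   `degenerate`, `singular`.
#' @export
fit_rt_model <- function(events) {
  validate_trial_events(events)
  if (length(unique(events$participant_id)) < 2L) stop("need >= 2 participants")
  if (length(unique(events$item_id)) < 2L) stop("need >= 2 items")
  if (!all(CONDITIONS %in% events$condition)) stop("both conditions must be present")
  rt_ms <- response_time(events) * 1000
  cond <- factor(events$condition, levels = CONDITIONS)

  within_var <- vapply(split(rt_ms, cond), function(x) stats::var(x), 0)
  if (all(within_var < 1e-12)) {
    # degenerate: zero noise, condition means exactly identified
    means <- vapply(split(rt_ms, cond), mean, 0)
    return(structure(list(
      beta_ep_ms = means[["early_planning"]],
      beta_lp_ms = means[["late_planning"]],
      condition_effect_ms = means[["late_planning"]] - means[["early_planning"]],
      se_effect_ms = 0,
      t_statistic = sign(means[["late_planning"]] - means[["early_planning"]]) * Inf,
      significant = TRUE,
      variance_participant_ms2 = 0, variance_item_ms2 = 0,
      variance_residual_ms2 = 0,
      degenerate = TRUE, singular = FALSE
    ), class = "artidelta_rt_model"))
  }

  dat <- data.frame(rt_ms = rt_ms, condition = cond,
                    participant_id = factor(events$participant_id),
                    item_id = factor(events$item_id))
  fit <- tryCatch(
    lme4::lmer(rt_ms ~ condition + (1 | participant_id) + (1 | item_id),
               data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed-model fit failed to converge: ",
                             conditionMessage(e)))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular mixed-model fit (a random-intercept variance is zero); results returned")
  fe <- lme4::fixef(fit)
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i) == 0L) 0 else vc$vcov[i[1L]]
  }
  effect <- unname(fe[2L])
  se <- sm[2L, "Std. Error"]
  structure(list(
    beta_ep_ms = unname(fe[1L]),
    beta_lp_ms = unname(fe[1L] + fe[2L]),
    condition_effect_ms = effect,
    se_effect_ms = se,
    t_statistic = effect / se,
    significant = abs(effect / se) > 2,
    variance_participant_ms2 = getv("participant_id"),
    variance_item_ms2 = getv("item_id"),
    variance_residual_ms2 = getv("Residual"),
    degenerate = FALSE, singular = singular
  ), class = "artidelta_rt_model")
}

#' @export
print.artidelta_rt_model <- function(x, ...) {
  cat("RT mixed model (ms): beta_ep =", round(x$beta_ep_ms, 1),
      " beta_lp =", round(x$beta_lp_ms, 1),
      " effect =", round(x$condition_effect_ms, 1),
      " t =", round(x$t_statistic, 2),
      if (x$significant) "(significant)" else "(n.s.)", "\n")
  cat("variances (ms^2): participant =", round(x$variance_participant_ms2, 1),
      " item =", round(x$variance_item_ms2, 1),
      " residual =", round(x$variance_residual_ms2, 1), "\n")
  invisible(x)
}
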