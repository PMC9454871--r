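## Survival evaluation statistics: Kaplan-Meier, time-dependent
## sensitivity/specificity/AUC with inverse-probability-of-censoring
## weighting (IPCW) and bootstrap SD, Bayes-rule time-dependent PPV/NPV,
## the HR-maximizing cutoff scan, multivariate Cox added-value analysis,
## and two-group cohort summary tables.

check_survival_data <- function(data) {
  stopifnot(all(c("time", "event") %in% names(data)))
  if (any(data$time <= 0)) stop("nonpositive survival times")
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(data)
}

#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator wrapped as a right-continuous step function.
#'
#' @param data data.frame with `time` (years, > 0) and `event` (0/1).
#' @return list of class `km_estimate`: `times`, `surv`, `n_risk`, and
#'   `surv_at(t)` evaluating S(t).
#' @export
km_estimate <- function(data) {
  check_survival_data(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(times = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 surv_at = sf), class = "km_estimate")
}

# Censoring survival G(t) = P(C > t) by reverse Kaplan-Meier, as a function;
# `minus` evaluates the left limit G(t-).
censoring_survival <- function(data) {
  d <- data
  d$cens <- 1 - d$event
  fit <- survival::survfit(survival::Surv(time, cens) ~ 1, data = d)
  right_cont <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(at = right_cont,
       minus = function(t) vapply(t, function(tt) {
         keep <- fit$time < tt
         if (!any(keep)) 1 else fit$surv[max(which(keep))]
       }, 0))
}

# IPCW case/control weights for the cumulative-case / dynamic-control
# definition at horizon t.
ipcw_sets <- function(scores, data, t, G = NULL) {
  if (is.null(G)) G <- censoring_survival(data)
  case <- data$time <= t & data$event == 1
  ctrl <- data$time > t
  g_case <- G$minus(data$time[case])
  g_ctrl <- G$at(t)
  if (any(g_case <= 0) || g_ctrl <= 0)
    stop("censoring survival vanished before the horizon")
  list(case_scores = scores[case], case_w = 1 / g_case,
       ctrl_scores = scores[ctrl], ctrl_w = rep(1 / g_ctrl, sum(ctrl)),
       case = case, ctrl = ctrl)
}

weighted_auc <- function(sc, wc, sd_, wd) {
  ord <- order(sd_)
  sd_ <- sd_[ord]; wd <- wd[ord]
  cw <- cumsum(wd)
  below <- findInterval(sc, sd_, left.open = TRUE)      # strictly smaller
  upto <- findInterval(sc, sd_)                         # smaller or equal
  w_below <- ifelse(below > 0, cw[pmax(below, 1)] * (below > 0), 0)
  w_tie <- ifelse(upto > 0, cw[pmax(upto, 1)], 0) - w_below
  sum(wc * (w_below + 0.5 * w_tie)) / (sum(wc) * sum(wd))
}

#' Time-dependent AUC with IPCW and bootstrap SD
#'
#' Cumulative-case / dynamic-control time-dependent AUC at horizon `t`,
#' weighting cases by the inverse reverse-KM censoring survival at their
#' event time and controls at `t`. The SD is the standard deviation of the
#' estimate over `n_boot` patient-level bootstrap resamples.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param data data.frame with `time`, `event`.
#' @param t horizon in years.
#' @param n_boot bootstrap replicates for the SD (0 skips it).
#' @param seed RNG seed for the bootstrap.
#' @return list `auc`, `sd`, `n_case`, `n_ctrl`.
#' @export
td_auc <- function(scores, data, t, n_boot = 500, seed = 1L) {
  check_survival_data(data)
  s <- ipcw_sets(scores, data, t)
  if (length(s$case_scores) == 0 || length(s$ctrl_scores) == 0)
    stop("no comparable case/control pairs at the horizon")
  auc <- weighted_auc(s$case_scores, s$case_w, s$ctrl_scores, s$ctrl_w)
  sd_boot <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    n <- nrow(data)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      sb <- tryCatch(ipcw_sets(scores[idx], data[idx, , drop = FALSE], t),
                     error = function(e) NULL)
      if (is.null(sb) || length(sb$case_scores) == 0 ||
          length(sb$ctrl_scores) == 0) return(NA_real_)
      weighted_auc(sb$case_scores, sb$case_w, sb$ctrl_scores, sb$ctrl_w)
    }, 0)
    sd_boot <- stats::sd(reps, na.rm = TRUE)
  }
  list(auc = auc, sd = sd_boot,
       n_case = length(s$case_scores), n_ctrl = length(s$ctrl_scores))
}

# IPCW-weighted sensitivity and specificity at cutoff c (positive = score > c).
# With no cases (or no controls) at t the corresponding rate is vacuous and
# taken as 1, so Bayes-rule PPV degenerates to 0 when 1 - S(t) = 0.
td_sens_spec <- function(sets, cutoff) {
  sens <- if (sum(sets$case_w) > 0)
    sum(sets$case_w * (sets$case_scores > cutoff)) / sum(sets$case_w) else 1
  spec <- if (sum(sets$ctrl_w) > 0)
    sum(sets$ctrl_w * (sets$ctrl_scores <= cutoff)) / sum(sets$ctrl_w) else 1
  c(sensitivity = sens, specificity = spec)
}

#' Time-dependent PPV/NPV curves by Bayes' rule
#'
#' For each target sensitivity, finds the highest cutoff whose IPCW-weighted
#' time-dependent sensitivity reaches the target (candidate cutoffs are the
#' observed score values, so coarse predictors may not reach high
#' sensitivities — such grid points are reported non-evaluable), then
#' computes `PPV(t) = sensitivity x (1 - S(t)) / P(test positive)` and
#' `NPV(t) = specificity x S(t) / P(test negative)`, with `S(t)` the
#' Kaplan-Meier progression-free survival.
#'
#' @inheritParams td_auc
#' @param sensitivity_grid target sensitivities in (0, 1].
#' @return data.frame: `sensitivity_target`, `cutoff`,
#'   `sensitivity_achieved`, `specificity`, `ppv`, `npv`, `evaluable`.
#' @export
td_ppv_npv <- function(scores, data, t, sensitivity_grid = seq(0.6, 0.95,
                                                               by = 0.05)) {
  check_survival_data(data)
  if (length(sensitivity_grid) == 0) stop("empty sensitivity grid")
  if (any(sensitivity_grid <= 0 | sensitivity_grid > 1))
    stop("sensitivity grid must lie in (0, 1]")
  sets <- ipcw_sets(scores, data, t)
  s_t <- km_estimate(data)$surv_at(t)
  # cutting at the maximum leaves an empty positive class; drop it
  cuts <- sort(unique(scores))
  if (length(cuts) > 1L) cuts <- cuts[-length(cuts)]
  ss <- t(vapply(cuts, function(cc) td_sens_spec(sets, cc), c(0, 0)))
  out <- lapply(sensitivity_grid, function(target) {
    ok <- which(ss[, 1] >= target - 1e-12)
    if (length(ok) == 0)
      return(data.frame(sensitivity_target = target, cutoff = NA_real_,
                        sensitivity_achieved = NA_real_,
                        specificity = NA_real_, ppv = NA_real_,
                        npv = NA_real_, evaluable = FALSE))
    j <- max(ok)    # highest cutoff still reaching the target
    cc <- cuts[j]
    sens <- ss[j, 1]; spec <- ss[j, 2]
    p_pos <- mean(scores > cc)
    p_neg <- 1 - p_pos
    ppv <- if (p_pos > 0) sens * (1 - s_t) / p_pos else NA_real_
    npv <- if (p_neg > 0) spec * s_t / p_neg else NA_real_
    data.frame(sensitivity_target = target, cutoff = cc,
               sensitivity_achieved = sens, specificity = spec,
               ppv = ppv, npv = npv, evaluable = TRUE)
  })
  do.call(rbind, out)
}

#' HR-maximizing cutoff for risk stratification
#'
#' Scans candidate cutoffs over the score quantiles (10th-90th percentile by
#' default, 1% steps), fits a univariate Cox model of high vs low group per
#' cutoff, and returns the cutoff maximizing the hazard ratio subject to a
#' minimum group size; ties resolve to the smaller cutoff. The scan is
#' rank-based, so any strictly monotone transform of the scores selects the
#' same partition.
#'
#' @inheritParams td_auc
#' @param quantile_range,step scan bounds and step on the quantile scale.
#' @param min_group smallest admissible group size.
#' @return list `cutoff`, `hr`, `ci` (length 2), `logrank_p`, `n_high`.
#' @export
optimal_cutoff_hr <- function(scores, data, quantile_range = c(0.1, 0.9),
                              step = 0.01, min_group = 10) {
  check_survival_data(data)
  if (length(unique(scores)) < 2L) stop("degenerate input: constant scores")
  cand <- unique(stats::quantile(scores, seq(quantile_range[1],
                                             quantile_range[2], by = step),
                                 names = FALSE, type = 7))
  best <- NULL
  for (cc in cand) {
    hi <- scores > cc
    if (sum(hi) < min_group || sum(!hi) < min_group) next
    # extreme cutoffs can separate the risk sets; such fits carry an
    # infinite HR and are discarded below, so the warnings are noise
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ hi,
                      data = data, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit)) next
    hr <- exp(stats::coef(fit))
    if (!is.finite(hr)) next
    if (is.null(best) || hr > best$hr) best <- list(cutoff = cc, hr = hr,
                                                    fit = fit)
  }
  if (is.null(best))
    stop("no admissible cutoff with the required group sizes")
  hi <- scores > best$cutoff
  ci <- exp(stats::confint(best$fit))
  lr <- survival::survdiff(survival::Surv(time, event) ~ hi, data = data)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  list(cutoff = best$cutoff, hr = unname(best$hr),
       ci = unname(ci[1, ]), logrank_p = unname(p), n_high = sum(hi))
}

#' Multivariate Cox proportional hazards table
#'
#' Partial-likelihood fit with Breslow ties; Wald confidence intervals and
#' p-values per coefficient.
#'
#' @param data data.frame with `time`, `event`.
#' @param covariates character vector of covariate columns in `data`.
#' @return data.frame: `term`, `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
cox_multivariate <- function(data, covariates) {
  check_survival_data(data)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "breslow")
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("collinear or separated design: coefficients not estimable")
  sm <- summary(fit)
  ci <- exp(stats::confint(fit))
  data.frame(term = names(cf), hr = unname(exp(cf)),
             ci_lower = unname(ci[, 1]), ci_upper = unname(ci[, 2]),
             p = unname(sm$coefficients[, "Pr(>|z|)"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group cohort summary table
#'
#' Compares variables between patients with and without progression:
#' continuous variables by mean (SD) and two-sided Welch t-test, categorical
#' variables by counts and two-sided Fisher's exact test.
#'
#' @param patients patient table with `patient_id`.
#' @param outcomes outcome table with `patient_id`, `event`.
#' @param variables columns of `patients` to summarize (default: all except
#'   the id).
#' @return data.frame: `variable`, `type`, `summary_no_progression`,
#'   `summary_progression`, `p`.
#' @export
cohort_summary <- function(patients, outcomes,
                           variables = setdiff(names(patients), "patient_id")) {
  ev <- outcomes$event[match(patients$patient_id, outcomes$patient_id)]
  if (any(is.na(ev))) stop("outcomes missing for some patients")
  g1 <- ev == 0; g2 <- ev == 1
  if (!any(g1) || !any(g2)) stop("empty comparison group")
  rows <- lapply(variables, function(v) {
    x <- patients[[v]]
    if (is.numeric(x)) {
      p <- stats::t.test(x[g1], x[g2])$p.value   # Welch by default
      data.frame(variable = v, type = "continuous",
                 summary_no_progression = sprintf("%.1f ± %.1f",
                                                  mean(x[g1]),
                                                  stats::sd(x[g1])),
                 summary_progression = sprintf("%.1f ± %.1f",
                                               mean(x[g2]),
                                               stats::sd(x[g2])),
                 p = p, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(x), factor(ev, levels = c(0, 1)))
      p <- stats::fisher.test(tab)$p.value
      fmt <- function(col) paste(sprintf("%s:%d", rownames(tab), tab[, col]),
                                 collapse = " ")
      data.frame(variable = v, type = "categorical",
                 summary_no_progression = fmt("0"),
                 summary_progression = fmt("1"),
                 p = p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
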