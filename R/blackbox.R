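## Decoding the fitted network: full-cohort refit with selection-frequency
## feature ranking, HR-maximizing dichotomization per endpoint, univariate
## screening of inputs + hidden-layer activations, the top-25 z-score
## heatmap matrix, and the cross-platform synergy comparison.

#' Refit on the full cohort and rank features by selection frequency
#'
#' Re-builds the network with every patient included and ranks the input
#' features by the number of hidden-layer units in which they survive
#' pruning (chained paths included); ties break by univariate logrank
#' p-value (median dichotomization), then by name.
#'
#' @param cohort an `idle_cohort`.
#' @param config a [network_config()].
#' @param platform feature platform (default integrated).
#' @return data.frame: `feature`, `selection_count`, `rank`, `platform_tag`
#'   (`CT`, `tissue` or `clinical`), `tie_logrank_p`; attribute `model`
#'   holds the full-cohort `trained_idle`.
#' @export
refit_full_and_rank <- function(cohort, config = network_config(),
                                platform = "integrated") {
  m <- idle_input_matrix(cohort, platform)
  out <- cohort$outcomes[match(rownames(m), cohort$outcomes$patient_id), ]
  model <- fit_idle(m, out, config)
  counts <- model$trace
  tie_p <- vapply(colnames(m), function(f) {
    x <- m[, f]
    if (length(unique(x)) < 2L) return(1)
    hi <- x > stats::median(x)
    if (!any(hi) || all(hi)) return(1)
    lr <- survival::survdiff(survival::Surv(out$time, out$event) ~ hi)
    stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  }, 0)
  tag <- ifelse(colnames(m) %in% attr(m, "ct_cols"), "CT",
                ifelse(colnames(m) %in% attr(m, "tissue_cols"),
                       "tissue", "clinical"))
  ord <- order(-counts, tie_p, colnames(m))
  data.frame(feature = colnames(m)[ord],
             selection_count = unname(counts[ord]),
             rank = seq_along(ord),
             platform_tag = tag[ord],
             tie_logrank_p = unname(tie_p[ord]),
             stringsAsFactors = FALSE) |>
    structure(model = model)
}

endpoint_outcomes <- function(outcomes, endpoint = c("progression",
                                                     "local_recurrence",
                                                     "distant_metastasis")) {
  endpoint <- match.arg(endpoint)
  out <- outcomes[, c("time", "event")]
  if (endpoint != "progression") {
    if (!"cause" %in% names(outcomes))
      stop("outcomes carry no cause labels for endpoint ", endpoint)
    # other-cause events censor the endpoint-specific time
    out$event <- as.integer(outcomes$event == 1 &
                              !is.na(outcomes$cause) &
                              outcomes$cause == endpoint)
  }
  out
}

#' Dichotomize a feature at its HR-maximizing threshold
#'
#' Threshold scan as in [optimal_cutoff_hr()] with the logrank test on the
#' requested endpoint (progression, local recurrence or distant metastasis;
#' the latter two censor events of the other cause).
#'
#' @param feature numeric feature values.
#' @param outcomes outcome table (with `cause` for cause-specific endpoints).
#' @param endpoint endpoint name.
#' @return list `threshold`, `hr`, `logrank_p`, `endpoint`.
#' @export
dichotomize_max_hr <- function(feature, outcomes, endpoint = "progression") {
  d <- endpoint_outcomes(outcomes, endpoint)
  res <- optimal_cutoff_hr(feature, d)
  list(threshold = res$cutoff, hr = res$hr, logrank_p = res$logrank_p,
       endpoint = endpoint)
}

#' Univariate screen of inputs and hidden-layer variables
#'
#' Tests each variable against the binary progression status: Welch t-test
#' for continuous variables, chi-square (no continuity correction) for
#' discrete ones, falling back to Fisher's exact test when an expected cell
#' count drops below 5. Returns the ascending-p table and the top 25.
#'
#' @param X numeric matrix of candidate variables (inputs + activations).
#' @param progressed binary vector (1 = progression) aligned to rows.
#' @param n_top size of the top list (default 25).
#' @return list `table` (all variables, ascending p), `top` (first
#'   `n_top` rows).
#' @export
univariate_screen <- function(X, progressed, n_top = 25) {
  X <- as.matrix(X)
  if (length(unique(progressed)) < 2L)
    stop("single-class labels: screen undefined")
  is_discrete <- apply(X, 2, function(x) length(unique(x)) <= 4)
  p <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) < 2L) return(1)
    if (is_discrete[j]) {
      tab <- table(x, progressed)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) stats::fisher.test(tab)$p.value
      else stats::chisq.test(tab, correct = FALSE)$p.value
    } else {
      stats::t.test(x[progressed == 0], x[progressed == 1])$p.value
    }
  }, 0)
  tab <- data.frame(feature = colnames(X),
                    test = ifelse(is_discrete, "chi_square", "t_test"),
                    p = p, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$feature), ]
  rownames(tab) <- NULL
  list(table = tab, top = utils::head(tab, n_top))
}

#' Z-score matrix for the heatmap of top variables
#'
#' Standardizes each variable across all patients (population SD); constant
#' variables are dropped with a warning. Row order follows the input.
#'
#' @param X numeric matrix, columns = variables, rows = patients.
#' @return matrix (rows = variables, columns = patients) of z-scores.
#' @export
zscore_heatmap_matrix <- function(X) {
  X <- as.matrix(X)
  pop_sd <- apply(X, 2, function(x) sqrt(mean((x - mean(x))^2)))
  keep <- pop_sd > 0
  if (!any(keep)) stop("all variables constant: z-score matrix undefined")
  if (any(!keep))
    warning("dropping constant variable(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  Z <- scale(X[, keep, drop = FALSE],
             center = TRUE, scale = pop_sd[keep])
  t(Z)
}

#' Cross-platform synergy comparison
#'
#' Compares the integrated, LDCT-only and tissue-only LOOCV score sets on
#' one cohort through time-dependent ROC (AUC ± bootstrap SD) at the
#' requested horizons, and flags synergy when the integrated AUC exceeds
#' both single-platform AUCs at every horizon.
#'
#' @param scores_by_platform named list of score data.frames (from
#'   [loocv_scores()]) for `integrated`, `ldct_only`, `tissue_only`.
#' @param outcomes outcome table.
#' @param horizons evaluation horizons in years (default 5 and 10).
#' @param n_boot bootstrap replicates for the AUC SD (0 skips).
#' @param seed RNG seed.
#' @return data.frame (3 platform rows per horizon): `platform`, `t`,
#'   `auc`, `auc_sd`; attribute `synergy` (logical).
#' @export
synergy_report <- function(scores_by_platform, outcomes, horizons = c(5, 10),
                           n_boot = 0, seed = 1L) {
  need <- c("integrated", "ldct_only", "tissue_only")
  if (!all(need %in% names(scores_by_platform)))
    stop("scores_by_platform must name ", paste(need, collapse = ", "))
  ids <- lapply(scores_by_platform[need], function(d) sort(d$patient_id))
  if (length(unique(vapply(ids, paste, "", collapse = ","))) != 1L)
    stop("mismatched cohorts across platforms")
  rows <- list()
  auc_tab <- matrix(NA_real_, length(horizons), 3,
                    dimnames = list(NULL, need))
  for (hi in seq_along(horizons)) {
    for (pf in need) {
      d <- scores_by_platform[[pf]]
      m <- match(d$patient_id, outcomes$patient_id)
      ok <- !is.na(d$score)
      a <- td_auc(d$score[ok], outcomes[m[ok], , drop = FALSE],
                  horizons[hi], n_boot = n_boot, seed = seed)
      auc_tab[hi, pf] <- a$auc
      rows[[length(rows) + 1L]] <-
        data.frame(platform = pf, t = horizons[hi], auc = a$auc,
                   auc_sd = a$sd, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  synergy <- all(auc_tab[, "integrated"] >
                   pmax(auc_tab[, "ldct_only"], auc_tab[, "tissue_only"]))
  structure(out, synergy = synergy)
}
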