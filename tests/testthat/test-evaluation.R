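test_that("Kaplan-Meier estimate matches hand product-limit results", {
  # no events: S(t) = 1 everywhere
  d0 <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_equal(km_estimate(d0)$surv_at(2.5), 1)
  # all events at 1, 2, 3: S(2.5) = (2/3) * (1/2) = 1/3
  d1 <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(km_estimate(d1)$surv_at(2.5), 1 / 3)
  expect_equal(km_estimate(d1)$surv_at(0.5), 1)
  expect_error(km_estimate(data.frame(time = c(-1, 2), event = c(1, 1))),
               "nonpositive")
  # no censoring: KM equals the empirical survival function
  set.seed(2)
  t <- stats::rexp(40, 0.3)
  dd <- data.frame(time = t, event = 1)
  km <- km_estimate(dd)
  for (q in c(1, 2, 5)) expect_equal(km$surv_at(q), mean(t > q))
})

test_that("IPCW AUC equals brute-force pair counting without censoring", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 8
    sc <- stats::rnorm(n)
    d <- data.frame(time = stats::rexp(n, 0.4) + 0.01, event = 1L)
    t0 <- stats::median(d$time)
    a <- td_auc(sc, d, t0, n_boot = 0)
    case <- d$time <= t0
    pairs <- outer(sc[case], sc[!case],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(a$auc, mean(pairs))
  }
})

test_that("outcome-independent scores give chance-level AUC", {
  set.seed(9)
  d <- sim_surv(500)
  a <- td_auc(stats::rnorm(500), d, 3, n_boot = 0)
  expect_lt(abs(a$auc - 0.5), 0.05)
})

test_that("perfectly separating scores give AUC 1 and invariance holds", {
  d <- data.frame(time = c(rep(1, 10), rep(9, 10)),
                  event = rep(1L, 20))
  sc <- c(rep(2, 10), rep(1, 10))
  a <- td_auc(sc, d, 5, n_boot = 0)
  expect_equal(a$auc, 1)
  # strictly monotone transform leaves the AUC unchanged
  set.seed(11)
  d2 <- sim_surv(80, beta = 0.8)
  a1 <- td_auc(d2$x, d2, 3, n_boot = 0)$auc
  a2 <- td_auc(exp(3 * d2$x), d2, 3, n_boot = 0)$auc
  expect_equal(a1, a2)
})

test_that("bootstrap SD is reported and stabilizes with more replicates", {
  set.seed(13)
  d <- sim_surv(120, beta = 0.7)
  a1 <- td_auc(d$x, d, 3, n_boot = 250, seed = 4)
  a2 <- td_auc(d$x, d, 3, n_boot = 500, seed = 4)
  expect_gt(a1$sd, 0)
  expect_lt(abs(a2$sd - a1$sd) / a1$sd, 0.10)
})

test_that("Bayes-rule PPV/NPV equal direct counting without censoring", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(20:50, 1)
    sc <- stats::rnorm(n)
    d <- data.frame(time = stats::rexp(n, 0.3) + 0.01, event = 1L)
    t0 <- stats::quantile(d$time, 0.6, names = FALSE)
    res <- td_ppv_npv(sc, d, t0, sensitivity_grid = c(0.6, 0.8, 0.95))
    for (k in which(res$evaluable)) {
      cc <- res$cutoff[k]
      case <- d$time <= t0
      tp <- sum(case & sc > cc); fp <- sum(!case & sc > cc)
      tn <- sum(!case & sc <= cc); fn <- sum(case & sc <= cc)
      if (tp + fp > 0) expect_equal(res$ppv[k], tp / (tp + fp))
      if (tn + fn > 0) expect_equal(res$npv[k], tn / (tn + fn))
      expect_true(res$ppv[k] >= 0 && res$ppv[k] <= 1)
      expect_true(res$npv[k] >= 0 && res$npv[k] <= 1)
    }
  }
})

test_that("PPV/NPV handles perfect classifiers and unreachable sensitivity", {
  d <- data.frame(time = c(rep(1, 8), rep(9, 12)), event = 1L)
  sc <- c(rep(1, 8), rep(0, 12))
  res <- td_ppv_npv(sc, d, 5, sensitivity_grid = c(0.6, 0.9))
  expect_true(all(res$ppv[res$evaluable] == 1))
  expect_true(all(res$npv[res$evaluable] == 1))
  # coarse score that cannot reach 90% sensitivity: flagged non-evaluable
  sc2 <- c(rep(1, 4), rep(0, 16))   # only half the cases flagged positive
  res2 <- td_ppv_npv(sc2, d, 5, sensitivity_grid = c(0.9))
  expect_false(res2$evaluable[1])
  # no events by t: PPV numerator zero
  d3 <- data.frame(time = rep(9, 10), event = 1L)
  res3 <- td_ppv_npv(stats::rnorm(10), d3, 5, sensitivity_grid = 1)
  expect_equal(res3$ppv[res3$evaluable], 0)
  expect_error(td_ppv_npv(sc, d, 5, numeric(0)), "empty")
})

test_that("HR-maximizing cutoff recovers a two-component design", {
  set.seed(23)
  ok <- replicate(10, {
    n <- 400
    grp <- stats::rbinom(n, 1, 0.5)
    sc <- grp + stats::rnorm(n, sd = 0.05)
    t_ev <- stats::rexp(n, 0.08 * 4^grp)
    t_c <- pmin(stats::rexp(n, 0.05), 12)
    d <- data.frame(time = pmax(pmin(t_ev, t_c), 1e-3),
                    event = as.integer(t_ev <= t_c))
    res <- optimal_cutoff_hr(sc, d)
    # the scan is rank-based: recovery means the chosen partition matches
    # the planted components (cutoff in or at the gap between them)
    c(partition = abs(sum(sc > res$cutoff) - sum(grp == 1)) <= 0.05 * n,
      hr_ok = abs(res$hr - 4) / 4 < 0.25)
  })
  expect_gte(mean(ok["partition", ]), 0.9)
  expect_gte(mean(ok["hr_ok", ]), 0.7)
})

test_that("cutoff scan is rank-based and guards degenerate input", {
  set.seed(29)
  d <- sim_surv(120, beta = 1)
  r1 <- optimal_cutoff_hr(d$x, d)
  r2 <- optimal_cutoff_hr(stats::plogis(d$x), d)
  expect_equal(sum(d$x > r1$cutoff), sum(stats::plogis(d$x) > r2$cutoff))
  expect_equal(r1$hr, r2$hr)
  expect_error(optimal_cutoff_hr(rep(1, 50), d[1:50, ]), "degenerate")
})

test_that("null scores give HR confidence intervals covering 1", {
  set.seed(31)
  cover <- replicate(20, {
    d <- sim_surv(150, beta = 0)
    res <- optimal_cutoff_hr(stats::rnorm(150), d)
    res$ci[1] <= 1 && res$ci[2] >= 1
  })
  # the scan maximizes HR, so coverage is conservative-ish but mostly holds
  expect_gte(mean(cover), 0.5)
})

test_that("Cox coefficient equals a brute-force partial likelihood search", {
  # 4 subjects, one binary covariate, no ties
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                  x = c(1, 0, 1, 0))
  fit <- cox_multivariate(d, "x")
  # hand-written partial likelihood maximized on a fine grid
  pl <- function(b) {
    risk <- exp(b * d$x)
    num <- 0
    for (i in which(d$event == 1)) {
      at_risk <- d$time >= d$time[i]
      num <- num + b * d$x[i] - log(sum(risk[at_risk]))
    }
    num
  }
  bgrid <- seq(-5, 5, by = 1e-4)
  b_hat <- bgrid[which.max(vapply(bgrid, pl, 0))]
  expect_lt(abs(log(fit$hr) - b_hat), 1e-3)
})

test_that("Cox recovery and null behavior on simulated data", {
  set.seed(37)
  # average the log-HR over replicates to beat single-sample noise
  log_hr <- replicate(4, {
    x <- stats::rbinom(500, 1, 0.5)
    d <- sim_surv(500, beta = log(2), x = x)
    log(cox_multivariate(d, "x")$hr)
  })
  expect_lt(abs(exp(mean(log_hr)) - 2) / 2, 0.15)
  # covariate independent of outcome: HR near 1
  null_hr <- replicate(4, {
    d <- sim_surv(500, beta = 0)
    d$z <- stats::rnorm(500)
    log(cox_multivariate(d, "z")$hr)
  })
  expect_lt(abs(exp(mean(null_hr)) - 1), 0.15)
  d <- sim_surv(100, beta = 0)
  expect_error(cox_multivariate(d, "missing_col"), "missing covariate")
  d$x2 <- d$x
  expect_error(cox_multivariate(d, c("x", "x2")), "collinear")
})

test_that("cohort summary applies Welch t and Fisher exact tests", {
  set.seed(41)
  n <- 60
  pat <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    age = stats::rnorm(n, 65, 5),
                    sex = sample(c("f", "m"), n, TRUE))
  out <- data.frame(patient_id = pat$patient_id,
                    event = stats::rbinom(n, 1, 0.3))
  tab <- cohort_summary(pat, out)
  expect_setequal(tab$variable, c("age", "sex"))
  g1 <- pat$age[out$event == 0]; g2 <- pat$age[out$event == 1]
  expect_equal(tab$p[tab$variable == "age"], stats::t.test(g1, g2)$p.value)
  ct <- table(pat$sex, out$event)
  expect_equal(tab$p[tab$variable == "sex"], stats::fisher.test(ct)$p.value)
  expect_error(cohort_summary(pat, transform(out, event = 0)), "empty")
})

test_that("Fisher p equals full hypergeometric enumeration on any 2x2", {
  # independent oracle: sum of hypergeometric probabilities <= observed's
  fisher_enum <- function(m) {
    rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
    p_obs <- stats::dhyper(m[1, 1], rs[1], rs[2], cs[1])
    ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- stats::dhyper(ks, rs[1], rs[2], cs[1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(matrix(c(21, 33, 27, 101), 2),
                matrix(c(5, 5, 5, 5), 2),
                matrix(c(2, 9, 7, 3), 2),
                matrix(c(1, 0, 12, 5), 2))
  for (m in cases)
    expect_equal(stats::fisher.test(m)$p.value, fisher_enum(m),
                 tolerance = 1e-10)
  expect_equal(stats::fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
})
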