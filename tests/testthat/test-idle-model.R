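make_label_cohort <- function(n, p = 6, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
  t_ev <- stats::rexp(n, 0.12 * exp(eta))
  t_c <- pmin(stats::rexp(n, 0.05), 12)
  list(X = X, outcomes = data.frame(time = pmax(pmin(t_ev, t_c), 1e-3),
                                    event = as.integer(t_ev <= t_c)))
}

test_that("pruning semantics match the threshold contract", {
  d <- make_label_cohort(80, beta = c(1, rep(0, 5)))
  cfg0 <- network_config(h1_units = 6, h2_units = 3, prune_threshold = 0,
                         subspace_fraction = 1, max_iter = 60, seed = 2)
  lay0 <- fit_hidden_layers(d$X, d$outcomes, cfg0)
  # threshold 0: nothing is zeroed; every feature reaches every unit
  expect_true(all(lay0$W1[-1, ] != 0))
  expect_true(all(lay0$trace == cfg0$h1_units + cfg0$h2_units))

  cfg80 <- network_config(h1_units = 6, h2_units = 3, prune_threshold = 80,
                          subspace_fraction = 1, max_iter = 60, seed = 2)
  lay80 <- fit_hidden_layers(d$X, d$outcomes, cfg80)
  expect_gte(mean(lay80$W1[-1, ] == 0), 0.75)
  # pruned weights are exactly zero
  expect_true(all(lay80$W1[-1, ][lay80$W1[-1, ] != 0] != 0))
})

test_that("pure-noise features are heavily pruned under a large L2", {
  frac_pruned <- replicate(10, {
    d <- make_label_cohort(80, seed = sample.int(1e6, 1))
    cfg <- network_config(h1_units = 8, h2_units = 4, l2_penalty = 5,
                          subspace_fraction = 1, prune_threshold = 80,
                          max_iter = 120, seed = 1)
    lay <- fit_hidden_layers(d$X, d$outcomes, cfg)
    mean(lay$W1[-1, ] == 0)
  })
  expect_gte(mean(frac_pruned >= 0.9), 0.8)
})

test_that("a label-aligned feature earns the top selection count", {
  top <- replicate(10, {
    seed <- sample.int(1e6, 1)
    d <- make_label_cohort(120, seed = seed)
    # plant a feature equal to the 5-year label
    y <- as.integer(d$outcomes$time <= 5 & d$outcomes$event == 1)
    d$X[, 1] <- y + stats::rnorm(120, sd = 0.01)
    cfg <- network_config(h1_units = 8, h2_units = 4, prune_threshold = 80,
                          max_iter = 150, seed = 1)
    lay <- fit_hidden_layers(d$X, d$outcomes, cfg)
    names(which.max(lay$trace))
  })
  expect_gte(mean(top == "f1"), 0.8)
})

test_that("hidden layers reject degenerate labels and inputs", {
  d <- make_label_cohort(40)
  cfg <- network_config(max_iter = 10)
  bad <- d$outcomes; bad$time <- rep(10, 40); bad$event <- 0L
  expect_error(fit_hidden_layers(d$X, bad, cfg), "one-class")
  Xb <- d$X; Xb[1, 1] <- Inf
  expect_error(fit_hidden_layers(Xb, d$outcomes, cfg), "non-finite")
})

test_that("survival forest risk tracks prognostic activations", {
  set.seed(5)
  conc_null <- replicate(8, {
    d <- make_label_cohort(300, seed = sample.int(1e6, 1))
    H <- matrix(stats::rnorm(300 * 4), 300, 4)
    f <- fit_survival_forest(H, d$outcomes,
                             network_config(n_trees = 150, seed = 1))
    1 - f$prediction.error   # OOB concordance
  })
  expect_lt(abs(mean(conc_null) - 0.5), 0.07)

  conc_strong <- replicate(8, {
    n <- 300
    x <- stats::rnorm(n)
    t_ev <- stats::rexp(n, 0.1 * exp(2 * x))
    out <- data.frame(time = pmax(t_ev, 1e-3), event = 1L)
    H <- cbind(x, matrix(stats::rnorm(n * 3), n, 3))
    f <- fit_survival_forest(H, out, network_config(n_trees = 150, seed = 1))
    1 - f$prediction.error
  })
  expect_gt(mean(conc_strong), 0.8)

  d <- make_label_cohort(50)
  no_ev <- d$outcomes; no_ev$event <- 0L
  expect_error(fit_survival_forest(d$X, no_ev, network_config()),
               "zero events")
})

test_that("risk prediction is normalized, clipped and schema-checked", {
  d <- make_label_cohort(80, beta = c(1.2, rep(0, 5)), seed = 9)
  cfg <- network_config(h1_units = 8, h2_units = 4, n_trees = 100,
                        max_iter = 80, seed = 4)
  model <- fit_idle(d$X, d$outcomes, cfg)
  sc <- predict_risk(model, d$X)
  expect_true(all(sc >= 0 & sc <= 1))
  # the training patient at the forest-risk maximum maps to score 1
  expect_equal(max(sc), 1)
  expect_equal(min(sc), 0)
  # fixed seed: identical refit, identical predictions
  model2 <- fit_idle(d$X, d$outcomes, cfg)
  expect_identical(predict_risk(model2, d$X), sc)
  bad <- d$X[, c(2, 1, 3:6)]
  expect_error(predict_risk(model, bad), "schema")
})

test_that("LOOCV runs one fit per patient and is deterministic", {
  co <- generate_cohort(cohort_spec(n_patients = 12, seed = 4))
  cfg <- light_config(seed = 2)
  s1 <- loocv_scores(co, cfg)
  s2 <- loocv_scores(co, cfg)
  expect_equal(nrow(s1), 12L)
  expect_identical(s1$score, s2$score)
  expect_true(all(s1$score >= 0 & s1$score <= 1, na.rm = TRUE))
  expect_error(loocv_scores(generate_cohort(cohort_spec(n_patients = 5,
                                                        seed = 1)), cfg),
               "n >= 10")
})

test_that("duplicated patients receive identical held-out scores", {
  co <- generate_cohort(cohort_spec(n_patients = 12, seed = 8))
  # duplicate patient 1 as a 13th patient under a new id
  dup <- function(d) { r <- d[d$patient_id == "P0001", ]
                       r$patient_id <- "P0099"; rbind(d, r) }
  co$patients <- dup(co$patients)
  co$outcomes <- dup(co$outcomes)
  co$ct_measurements <- dup(co$ct_measurements)
  rois <- co$roi_readings[co$roi_readings$patient_id == "P0001", ]
  rois$patient_id <- "P0099"
  co$roi_readings <- rbind(co$roi_readings, rois)
  sc <- loocv_scores(co, light_config(seed = 5))
  expect_equal(sc$score[sc$patient_id == "P0001"],
               sc$score[sc$patient_id == "P0099"])
})

test_that("no test-fold information enters training", {
  co <- generate_cohort(cohort_spec(n_patients = 30, seed = 6))
  cfg <- light_config(seed = 7)
  ids <- co$patients$patient_id
  held <- ids[1]
  fit_fold <- function(cohort) {
    raw <- idlelung:::idle_raw_inputs(cohort)
    m <- idlelung:::finalize_inputs(raw, "integrated", train_ids = ids[-1])
    out_tr <- cohort$outcomes[match(ids[-1], cohort$outcomes$patient_id), ]
    model <- fit_idle(m[ids[-1], , drop = FALSE], out_tr, cfg)
    list(model = model, m = m)
  }
  a <- fit_fold(co)
  # perturb every record of the held-out patient; the trained model and the
  # standardization of training rows must be unchanged
  co2 <- co
  co2$outcomes$time[1] <- co2$outcomes$time[1] + 3
  co2$ct_measurements[1, -1] <- co2$ct_measurements[1, -1] + 10
  co2$patients$age_at_surgery[1] <- 99
  b <- fit_fold(co2)
  expect_identical(a$model$layers$W1, b$model$layers$W1)
  expect_identical(a$model$bounds, b$model$bounds)
  expect_identical(a$m[ids[-1], ], b$m[ids[-1], ])
})

test_that("LOOCV discriminates under strong latent signal", {
  # hazard ratio across latent-risk quartiles well above 4
  aucs <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(
      n_patients = 150,
      effect_sizes = c(ct_signal = 1.2, tissue_signal = 1.2,
                       interaction_signal = 0.3),
      seed = 700 + s))
    sc <- loocv_scores(co, network_config(h1_units = 24, h2_units = 12,
                                          n_trees = 200, max_depth = 6,
                                          max_iter = 200, seed = 2))
    td_auc(sc$score, co$outcomes, 5, n_boot = 0)$auc
  }, 0)
  expect_gte(mean(aucs >= 0.75), 0.8)
})
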