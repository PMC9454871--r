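## The hybrid risk model: two layers of logistic units trained with
## cross-entropy + L2 that double as feature selectors (small weights are
## pruned), a random survival forest on the second-layer activations, min-max
## risk normalization to [0, 1], and leave-one-patient-out cross-validation.

#' Network configuration
#'
#' @param h1_units,h2_units logistic units in the first/second hidden layer.
#' @param l2_penalty L2 penalty; if a vector, the value minimizing
#'   unpenalized loss on an inner 70/30 validation split is used per layer.
#' @param subspace_fraction fraction of the layer's inputs each unit may use
#'   (its remaining weights are structurally zero). Subspacing keeps the
#'   units diverse — fully shared inputs make the layer's convex unit
#'   problems collapse to one solution — and is what makes the per-unit
#'   feature-selection counts informative. 1 disables subspacing.
#' @param prune_threshold percentile (0-100) of per-layer weight magnitudes
#'   below which weights are zeroed; 0 disables pruning.
#' @param horizon_tau label horizon in years for the cross-entropy stage and
#'   the forest risk (cumulative hazard at `horizon_tau`).
#' @param n_trees,min_node random survival forest size / node floor
#'   (`mtry` is `floor(sqrt(p))`, log-rank splitting).
#' @param max_depth tree depth cap for the forest (0 = unlimited).
#' @param learning_rate,max_iter,tol full-batch gradient-descent controls.
#' @param seed RNG seed for initialization and the forest.
#' @return list of class `network_config`.
#' @export
network_config <- function(h1_units = 32L, h2_units = 16L, l2_penalty = 0.01,
                           subspace_fraction = 0.4,
                           prune_threshold = 80, horizon_tau = 5,
                           n_trees = 500L, min_node = 5L, max_depth = 0L,
                           learning_rate = 0.5, max_iter = 300L, tol = 1e-6,
                           seed = 1L) {
  stopifnot(h1_units >= 1, h2_units >= 1, all(l2_penalty >= 0),
            subspace_fraction > 0, subspace_fraction <= 1,
            prune_threshold >= 0, prune_threshold <= 100, horizon_tau > 0)
  structure(list(h1_units = as.integer(h1_units),
                 h2_units = as.integer(h2_units),
                 l2_penalty = l2_penalty,
                 subspace_fraction = subspace_fraction,
                 prune_threshold = prune_threshold,
                 horizon_tau = horizon_tau,
                 n_trees = as.integer(n_trees), min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "network_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Train `units` parallel logistic units on (X, y) by full-batch gradient
# descent on cross-entropy + l2 * sum(w^2) (bias unpenalized). Units differ
# through random initialization and, when subspace_fraction < 1, through a
# random subset of inputs each unit is allowed to use (weights outside it
# stay structurally zero). Returns the (p + 1) x units weight matrix, bias
# in row 1.
train_logistic_layer <- function(X, y, units, l2, lr, max_iter, tol,
                                 subspace_fraction = 1) {
  n <- nrow(X); p <- ncol(X)
  Xb <- cbind(1, X)
  W <- matrix(stats::rnorm((p + 1) * units, sd = 0.5), p + 1, units)
  S <- matrix(TRUE, p + 1, units)
  if (subspace_fraction < 1 && p > 2) {
    k <- max(2L, ceiling(subspace_fraction * p))
    for (u in seq_len(units)) {
      drop_rows <- 1 + setdiff(seq_len(p), sample.int(p, k))
      S[drop_rows, u] <- FALSE
    }
    W[!S] <- 0
  }
  # keep the quadratic (penalty) part of the update contractive
  lr <- min(lr, 0.45 / max(2 * l2, 1e-9))
  loss_prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- sigmoid(Xb %*% W)
    G <- crossprod(Xb, A - y) / n
    G[-1, ] <- G[-1, ] + 2 * l2 * W[-1, ]
    G[!S] <- 0
    W <- W - lr * G
    if (it %% 10L == 0L || it == max_iter) {   # convergence check
      Ac <- pmin(pmax(A, 1e-12), 1 - 1e-12)
      loss <- -mean(y * log(Ac) + (1 - y) * log(1 - Ac)) +
        l2 * sum(W[-1, ]^2)
      if (abs(loss_prev - loss) < tol) break
      loss_prev <- loss
    }
  }
  W
}

# Choose an l2 value from a grid by unpenalized cross-entropy on an inner
# 70/30 validation split (a single value is returned as-is).
select_l2 <- function(X, y, units, grid, lr, max_iter, tol) {
  if (length(grid) == 1L) return(grid)
  n <- nrow(X)
  idx <- sample.int(n)
  n_tr <- max(2L, floor(0.7 * n))
  tr <- idx[seq_len(n_tr)]; va <- idx[-seq_len(n_tr)]
  if (length(va) == 0L || length(unique(y[tr])) < 2L) return(grid[1])
  losses <- vapply(grid, function(l2) {
    W <- train_logistic_layer(X[tr, , drop = FALSE], y[tr], units, l2, lr,
                              max_iter, tol)
    A <- sigmoid(cbind(1, X[va, , drop = FALSE]) %*% W)
    s <- pmin(pmax(rowMeans(A), 1e-12), 1 - 1e-12)
    -mean(y[va] * log(s) + (1 - y[va]) * log(1 - s))
  }, 0)
  grid[which.min(losses)]
}

# Zero weights with magnitude below the per-layer percentile; when pruning is
# active, negligible weights (|w| < w_floor, i.e. shifting a unit's input by
# no more than ~0.01 of an activation unit for standardized inputs) are
# zeroed regardless. Bias row is never pruned; threshold_pct = 0 disables
# pruning entirely.
prune_layer <- function(W, threshold_pct, w_floor = 0.01) {
  if (threshold_pct <= 0) return(W)
  w <- W[-1, , drop = FALSE]
  # the percentile is taken over the trainable weights only — structural
  # (subspace) zeros would otherwise drag it to ~0 and disable pruning
  live <- abs(w[w != 0])
  if (length(live) == 0L) return(W)
  thr <- stats::quantile(live, threshold_pct / 100, names = FALSE, type = 7)
  w[abs(w) < thr | abs(w) < w_floor] <- 0
  W[-1, ] <- w
  W
}

# Event-by-tau binary label; censored-before-tau patients carry NA (omitted
# from the cross-entropy stage, retained for the survival forest).
horizon_label <- function(time, event, tau) {
  ifelse(time > tau, 0L, ifelse(event == 1, 1L, NA_integer_))
}

#' Fit the two hidden layers
#'
#' Layer 1 trains `h1_units` logistic units on the inputs against the
#' event-by-`horizon_tau` binary label (cross-entropy + L2, full-batch
#' gradient descent); weights below the pruning percentile are zeroed.
#' Layer 2 repeats the procedure on the layer-1 activations. The trace
#' counts, per input feature, the units of both layers in which it survives
#' pruning (layer-2 units via chained nonzero paths).
#'
#' @param X numeric input matrix (no missing values; named columns).
#' @param outcomes data.frame with `time` and `event` aligned to `X` rows.
#' @param config a [network_config()].
#' @return list of class `idle_layers`: `W1`, `W2` (post-pruning weight
#'   matrices, bias in row 1), `trace` (named selection counts), `label_used`
#'   (logical, rows that entered the cross-entropy stage).
#' @export
fit_hidden_layers <- function(X, outcomes, config) {
  stopifnot(inherits(config, "network_config"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite input")
  y_all <- horizon_label(outcomes$time, outcomes$event, config$horizon_tau)
  use <- !is.na(y_all)
  y <- y_all[use]
  if (length(unique(y)) < 2L)
    stop("all-one-class labels at the horizon; cannot train hidden layers")
  set.seed(config$seed)
  Xl <- X[use, , drop = FALSE]
  l2_1 <- select_l2(Xl, y, config$h1_units, config$l2_penalty,
                    config$learning_rate, config$max_iter, config$tol)
  W1 <- train_logistic_layer(Xl, y, config$h1_units, l2_1,
                             config$learning_rate, config$max_iter,
                             config$tol, config$subspace_fraction)
  W1 <- prune_layer(W1, config$prune_threshold)
  A1 <- sigmoid(cbind(1, Xl) %*% W1)
  l2_2 <- select_l2(A1, y, config$h2_units, config$l2_penalty,
                    config$learning_rate, config$max_iter, config$tol)
  W2 <- train_logistic_layer(A1, y, config$h2_units, l2_2,
                             config$learning_rate, config$max_iter,
                             config$tol, config$subspace_fraction)
  W2 <- prune_layer(W2, config$prune_threshold)

  nz1 <- W1[-1, , drop = FALSE] != 0            # p x h1
  nz2 <- W2[-1, , drop = FALSE] != 0            # h1 x h2
  chain <- (nz1 %*% nz2) > 0                    # p x h2 nonzero paths
  trace <- rowSums(nz1) + rowSums(chain)
  names(trace) <- colnames(X)
  structure(list(W1 = W1, W2 = W2, trace = trace, label_used = use,
                 l2 = c(layer1 = l2_1, layer2 = l2_2)),
            class = "idle_layers")
}

layer_activations <- function(layers, X) {
  A1 <- sigmoid(cbind(1, as.matrix(X)) %*% layers$W1)
  A2 <- sigmoid(cbind(1, A1) %*% layers$W2)
  list(A1 = A1, A2 = A2)
}

#' Fit the survival-forest output layer
#'
#' Random survival forest (log-rank splitting) on the second-hidden-layer
#' activations; the forest risk of a subject is its ensemble cumulative
#' hazard at `horizon_tau`.
#'
#' @param H2 activation matrix (rows = patients).
#' @param outcomes data.frame with `time`, `event`.
#' @param config a [network_config()].
#' @return `ranger` fit with attribute `tau`.
#' @export
fit_survival_forest <- function(H2, outcomes, config) {
  if (sum(outcomes$event) == 0L) stop("zero events: cannot fit survival forest")
  d <- as.data.frame(H2)
  colnames(d) <- paste0("a", seq_len(ncol(d)))
  d$time <- outcomes$time
  d$event <- outcomes$event
  # canonical row order: predictions depend only on the training multiset,
  # so duplicated patients in different fold layouts score identically
  d <- d[do.call(order, d), , drop = FALSE]
  fit <- ranger::ranger(survival::Surv(time, event) ~ ., data = d,
                        num.trees = config$n_trees,
                        mtry = max(1L, floor(sqrt(ncol(H2)))),
                        min.node.size = config$min_node,
                        max.depth = config$max_depth,
                        seed = config$seed, num.threads = 1)
  attr(fit, "tau") <- config$horizon_tau
  fit
}

chf_at <- function(chf_matrix, times, tau) {
  if (is.null(dim(chf_matrix)))
    chf_matrix <- matrix(chf_matrix, nrow = 1)   # single-subject prediction
  pos <- findInterval(tau, times)
  if (pos == 0L) return(rep(0, nrow(chf_matrix)))
  chf_matrix[, pos]
}

#' Fit the full IDLE model on one training set
#'
#' @inheritParams fit_hidden_layers
#' @return list of class `trained_idle`: hidden `layers`, `forest`,
#'   normalization `bounds` (training-risk min/max), `trace`, `schema`
#'   (input column names), `config`.
#' @export
fit_idle <- function(X, outcomes, config) {
  X <- as.matrix(X)
  layers <- fit_hidden_layers(X, outcomes, config)
  A2 <- layer_activations(layers, X)$A2
  forest <- fit_survival_forest(A2, outcomes, config)
  # training risks through the same prediction path used at test time, so
  # the min-max bounds are exact for training patients
  dtr <- as.data.frame(A2)
  colnames(dtr) <- paste0("a", seq_len(ncol(dtr)))
  ptr <- stats::predict(forest, data = dtr, num.threads = 1)
  risks <- chf_at(ptr$chf, ptr$unique.death.times, config$horizon_tau)
  structure(list(layers = layers, forest = forest,
                 bounds = range(risks), trace = layers$trace,
                 schema = colnames(X), config = config),
            class = "trained_idle")
}

#' Predict the IDLE score
#'
#' Forward pass through the pruned layers, forest cumulative hazard at the
#' horizon, then min-max normalization by the training-risk bounds, clipped
#' to \[0, 1\] for out-of-range test risks.
#'
#' @param model a `trained_idle` from [fit_idle()].
#' @param X input matrix with the training schema's columns.
#' @return numeric scores in \[0, 1\].
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "trained_idle"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model$schema))
    stop("schema mismatch: input columns differ from the training schema")
  A2 <- layer_activations(model$layers, X)$A2
  d <- as.data.frame(A2)
  colnames(d) <- paste0("a", seq_len(ncol(d)))
  pr <- stats::predict(model$forest, data = d, num.threads = 1)
  raw <- chf_at(pr$chf, pr$unique.death.times, model$config$horizon_tau)
  lo <- model$bounds[1]; hi <- model$bounds[2]
  if (hi <= lo) return(rep(0.5, length(raw)))
  pmin(1, pmax(0, (raw - lo) / (hi - lo)))
}

#' Build the per-platform input matrix for a cohort
#'
#' Binds the clinical + tissue block (from [assemble_model_inputs()]) with
#' the measured CT descriptor block; `platform` selects columns: the
#' integrated model uses everything, `ldct_only` drops the tissue block and
#' `tissue_only` drops the CT block — demographics, surgical variables and
#' the LDCT-to-surgery interval are retained in all platforms. Continuous
#' columns are standardized with training-fold statistics.
#'
#' @param cohort an `idle_cohort`.
#' @param platform `"integrated"`, `"ldct_only"` or `"tissue_only"`.
#' @param train_ids ids supplying standardization statistics.
#' @return numeric matrix, rows aligned to `cohort$patients`.
#' @export
idle_input_matrix <- function(cohort, platform = c("integrated", "ldct_only",
                                                   "tissue_only"),
                              train_ids = NULL) {
  platform <- match.arg(platform)
  finalize_inputs(idle_raw_inputs(cohort), platform, train_ids)
}

# Fold-independent raw input blocks, computed once per cohort: the
# clinical + tissue frame (with highest_grade possibly NA) and the measured
# CT descriptor block.
idle_raw_inputs <- function(cohort) {
  tissue <- derive_tissue_features(cohort$roi_readings)
  base <- assemble_model_inputs(tissue, cohort$patients,
                                standardize = FALSE)
  ct <- as.matrix(cohort$ct_measurements[
    match(cohort$patients$patient_id, cohort$ct_measurements$patient_id),
    setdiff(colnames(cohort$ct_measurements), "patient_id"), drop = FALSE])
  rownames(ct) <- cohort$patients$patient_id
  list(base = base, ct = ct,
       tissue_cols = attr(base, "tissue_cols"),
       continuous = attr(base, "continuous_cols"))
}

# Fold-dependent finishing: grade imputation and standardization with
# training-set statistics, then platform column selection.
finalize_inputs <- function(raw, platform, train_ids = NULL) {
  m <- cbind(raw$base, raw$ct)
  if (is.null(train_ids)) train_ids <- rownames(m)
  tr <- rownames(m) %in% train_ids
  med_gr <- stats::median(m[tr, "highest_grade"], na.rm = TRUE)
  if (is.na(med_gr)) med_gr <- 0
  m[is.na(m[, "highest_grade"]), "highest_grade"] <- med_gr
  for (cc in c(raw$continuous, colnames(raw$ct))) {
    mu <- mean(m[tr, cc]); sdv <- stats::sd(m[tr, cc])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    m[, cc] <- (m[, cc] - mu) / sdv
  }
  if (platform == "ldct_only")
    m <- m[, setdiff(colnames(m), raw$tissue_cols), drop = FALSE]
  if (platform == "tissue_only")
    m <- m[, setdiff(colnames(m), colnames(raw$ct)), drop = FALSE]
  structure(m, tissue_cols = intersect(raw$tissue_cols, colnames(m)),
            ct_cols = intersect(colnames(raw$ct), colnames(m)))
}

#' Leave-one-patient-out cross-validated IDLE scores
#'
#' For each patient the model is trained on the remaining n - 1 patients
#' (fold-wise standardization, hidden layers, forest, normalization) and the
#' held-out patient is scored. Folds whose training labels collapse to one
#' class are recorded as failed and surfaced via the `failed_folds`
#' attribute.
#'
#' @param cohort an `idle_cohort` (n >= 10).
#' @param config a [network_config()].
#' @param platform feature platform, see [idle_input_matrix()].
#' @return data.frame `patient_id`, `platform`, `score`, with attribute
#'   `failed_folds`.
#' @export
loocv_scores <- function(cohort, config = network_config(),
                         platform = "integrated") {
  n <- nrow(cohort$patients)
  if (n < 10L) stop("leave-one-out requires n >= 10")
  ids <- cohort$patients$patient_id
  raw <- idle_raw_inputs(cohort)
  scores <- rep(NA_real_, n)
  failed <- character(0)
  for (i in seq_len(n)) {
    train_ids <- ids[-i]
    m <- finalize_inputs(raw, platform, train_ids = train_ids)
    out_tr <- cohort$outcomes[match(train_ids, cohort$outcomes$patient_id), ]
    res <- tryCatch({
      model <- fit_idle(m[train_ids, , drop = FALSE], out_tr, config)
      predict_risk(model, m[ids[i], , drop = FALSE])
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- c(failed, ids[i])
    else scores[i] <- res
  }
  structure(data.frame(patient_id = ids, platform = platform, score = scores,
                       stringsAsFactors = FALSE),
            failed_folds = failed)
}
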