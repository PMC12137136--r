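## Linear-SVM decoding harnesses: pseudotrials, F-score feature ranking,
## within-task 5-fold x 3-repeat and cross-task schemes, temporal
## generalization, balanced accuracy, cluster-mass permutation inference,
## beta-binomial Bayes factors, and the posterior vs posterior+PFC
## comparison with the repeated-CV variance-corrected paired t-test.

#' Average same-class trials into pseudotrials
#'
#' Within each class, partitions trials at random into disjoint groups of
#' `k` and averages each group (the remainder is dropped), preserving the
#' class labels; noise variance shrinks by about `1/k`.
#'
#' @param x numeric matrix `[n_trials, n_features]` or array
#'   `[n_trials, n_features, n_times]`.
#' @param y class label per trial.
#' @param k trials per pseudotrial (default 5).
#' @param seed integer seed.
#' @return list with `x` (same rank as input) and `y`.
#' @export
make_pseudotrials <- function(x, y, k = 5, seed = 1) {
  stopifnot(k >= 1)
  if (any(table(y) < k)) stop("class size smaller than k")
  set.seed(seed)
  is_mat <- is.matrix(x)
  if (is_mat) dim(x) <- c(dim(x), 1L)
  groups <- list()
  labels <- character(0)
  for (cl in unique(as.character(y))) {
    idx <- sample(which(as.character(y) == cl))
    n_g <- length(idx) %/% k
    for (g in seq_len(n_g)) {
      groups[[length(groups) + 1L]] <- idx[((g - 1) * k + 1):(g * k)]
      labels <- c(labels, cl)
    }
  }
  out <- array(NA_real_, dim = c(length(groups), dim(x)[2], dim(x)[3]))
  for (i in seq_along(groups)) {
    sl <- x[groups[[i]], , , drop = FALSE]
    out[i, , ] <- apply(sl, c(2, 3), mean)
  }
  if (is_mat) dim(out) <- dim(out)[1:2]
  list(x = out, y = labels)
}

#' Rank features by one-way F statistic
#'
#' Computes the between/within variance-ratio F statistic of each feature
#' against the class labels and returns the indices of the top `k`
#' features (ties broken by lower index; constant features rank last).
#'
#' @param x numeric matrix `[n_trials, n_features]` (training data only).
#' @param y class label per trial.
#' @param k number of features to keep (clipped to `n_features`).
#' @return integer vector of feature indices, best first.
#' @export
rank_features <- function(x, y, k) {
  stopifnot(is.matrix(x))
  y <- as.character(y)
  cls <- unique(y)
  n <- nrow(x)
  g <- matrix(0, n, length(cls))
  g[cbind(seq_len(n), match(y, cls))] <- 1
  ng <- colSums(g)
  gm <- crossprod(g, x) / ng                       # class means
  grand <- colMeans(x)
  ssb <- colSums(ng * (gm - rep(grand, each = length(cls)))^2)
  ssw <- colSums(x^2) - colSums(ng * gm^2)
  dfb <- length(cls) - 1
  dfw <- n - length(cls)
  f <- (ssb / dfb) / (ssw / dfw)
  f[!is.finite(f)] <- -Inf                         # constant features last
  k <- min(k, ncol(x))
  order(-f, seq_along(f))[seq_len(k)]
}

svm_weights <- function(y) {
  tab <- table(y)
  w <- sum(tab) / (length(tab) * tab)              # inverse class frequency
  stats::setNames(as.numeric(w), names(tab))
}

fit_predict_svm <- function(x_tr, y_tr, x_te, cost = 1) {
  y_tr <- factor(y_tr)
  fit <- e1071::svm(x_tr, y_tr, kernel = "linear", cost = cost,
                    class.weights = svm_weights(y_tr), scale = FALSE)
  as.character(stats::predict(fit, x_te))
}

#' Balanced accuracy
#'
#' Mean of per-class sensitivities (recall); equals plain accuracy for
#' balanced classes and the appropriate chance level (1/n_classes)
#' otherwise.
#'
#' @param y_true,y_pred true and predicted labels.
#' @return score in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) > 0, length(y_true) == length(y_pred))
  cls <- unique(y_true)
  if (any(table(y_true)[cls] == 0)) stop("empty true class")
  mean(vapply(cls, function(cl) {
    idx <- y_true == cl
    mean(y_pred[idx] == cl)
  }, numeric(1)))
}

score_metric <- function(y_true, y_pred, metric) {
  if (metric == "balanced_accuracy") balanced_accuracy(y_true, y_pred)
  else mean(as.character(y_true) == as.character(y_pred))
}

stratified_folds <- function(y, n_folds) {
  y <- as.character(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Time-resolved decoding with within-task or cross-task schemes
#'
#' At every time point, fits a class-weighted linear SVM and scores it on
#' held-out data. `within_cv` uses stratified 5-fold cross-validation with
#' 3 repeats. `cross_task` trains on one task condition and tests on the
#' other, with the same folding harness (train on 80% of condition A,
#' test on the held-out 20% of condition B) to provide fold-level scores.
#' Feature ranking (one-way F, top `n_features`) is computed on the
#' training partition only.
#'
#' @param x numeric array `[n_trials, n_features, n_times]`.
#' @param y class label per trial.
#' @param scheme `"within_cv"` or `"cross_task"`.
#' @param task task-condition label per trial (required for
#'   `cross_task`); training condition given by `train_task`.
#' @param train_task condition to train on (default the first level).
#' @param n_folds,n_repeats cross-validation structure (defaults 5 x 3).
#' @param n_features number of top-F features (default all).
#' @param metric `"accuracy"` or `"balanced_accuracy"`.
#' @param cost SVM regularization constant (default 1).
#' @param seed integer seed.
#' @return object of class `decoding_result`: list with `accuracy` (per
#'   time), `fold_scores` `[n_folds * n_repeats, n_times]`, `chance`,
#'   `metric`, `times` untouched indices.
#' @export
decode_timecourse <- function(x, y, scheme = c("within_cv", "cross_task"),
                              task = NULL, train_task = NULL,
                              n_folds = 5, n_repeats = 3,
                              n_features = NULL,
                              metric = c("accuracy", "balanced_accuracy"),
                              cost = 1, seed = 1) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  stopifnot(length(dim(x)) == 3L)
  y <- as.character(y)
  n_cls <- length(unique(y))
  stopifnot(n_cls >= 2)
  if (is.null(n_features)) n_features <- dim(x)[2]
  n_t <- dim(x)[3]
  set.seed(seed)
  if (scheme == "cross_task") {
    stopifnot(!is.null(task))
    task <- as.character(task)
    if (is.null(train_task)) train_task <- sort(unique(task))[1]
    tr_pool <- which(task == train_task)
    te_pool <- which(task != train_task)
    stopifnot(length(tr_pool) > 0, length(te_pool) > 0)
  }
  scores <- matrix(NA_real_, n_folds * n_repeats, n_t)
  for (r in seq_len(n_repeats)) {
    if (scheme == "within_cv") {
      fold <- stratified_folds(y, n_folds)
    } else {
      fold_tr <- stratified_folds(y[tr_pool], n_folds)
      fold_te <- stratified_folds(y[te_pool], n_folds)
    }
    for (f in seq_len(n_folds)) {
      if (scheme == "within_cv") {
        tr <- which(fold != f); te <- which(fold == f)
      } else {
        tr <- tr_pool[fold_tr != f]; te <- te_pool[fold_te == f]
      }
      if (length(unique(y[tr])) < n_cls || length(unique(y[te])) < 1)
        stop("a fold is missing a class")
      row <- (r - 1) * n_folds + f
      for (t in seq_len(n_t)) {
        xt <- matrix(x[, , t], dim(x)[1], dim(x)[2])
        feats <- rank_features(xt[tr, , drop = FALSE], y[tr], n_features)
        pred <- fit_predict_svm(xt[tr, feats, drop = FALSE], y[tr],
                                xt[te, feats, drop = FALSE], cost)
        scores[row, t] <- score_metric(y[te], pred, metric)
      }
    }
  }
  structure(list(accuracy = colMeans(scores), fold_scores = scores,
                 chance = 1 / n_cls, metric = metric, scheme = scheme,
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "decoding_result")
}

#' Temporal generalization matrix
#'
#' Trains a classifier at each time point and tests it at every time
#' point, reusing the training-time feature selection (top-F features
#' chosen at the training time on the training partition only).
#'
#' @inheritParams decode_timecourse
#' @return object of class `tempgen_result`: `accuracy` matrix
#'   `[n_train_times, n_test_times]`, `chance`, `metric`.
#' @export
temporal_generalization <- function(x, y, scheme = c("within_cv", "cross_task"),
                                    task = NULL, train_task = NULL,
                                    n_folds = 5, n_repeats = 3,
                                    n_features = NULL,
                                    metric = c("accuracy", "balanced_accuracy"),
                                    cost = 1, seed = 1) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  stopifnot(length(dim(x)) == 3L)
  y <- as.character(y)
  n_cls <- length(unique(y))
  if (is.null(n_features)) n_features <- dim(x)[2]
  n_t <- dim(x)[3]
  set.seed(seed)
  if (scheme == "cross_task") {
    stopifnot(!is.null(task))
    task <- as.character(task)
    if (is.null(train_task)) train_task <- sort(unique(task))[1]
    tr_pool <- which(task == train_task)
    te_pool <- which(task != train_task)
  }
  acc <- array(0, dim = c(n_t, n_t))
  n_models <- 0L
  for (r in seq_len(n_repeats)) {
    if (scheme == "within_cv") {
      fold <- stratified_folds(y, n_folds)
    } else {
      fold_tr <- stratified_folds(y[tr_pool], n_folds)
      fold_te <- stratified_folds(y[te_pool], n_folds)
    }
    for (f in seq_len(n_folds)) {
      if (scheme == "within_cv") {
        tr <- which(fold != f); te <- which(fold == f)
      } else {
        tr <- tr_pool[fold_tr != f]; te <- te_pool[fold_te == f]
      }
      if (length(unique(y[tr])) < n_cls) stop("a fold is missing a class")
      n_models <- n_models + 1L
      for (t1 in seq_len(n_t)) {
        xt1 <- matrix(x[, , t1], dim(x)[1], dim(x)[2])
        feats <- rank_features(xt1[tr, , drop = FALSE], y[tr], n_features)
        y_tr <- factor(y[tr])
        fit <- e1071::svm(xt1[tr, feats, drop = FALSE], y_tr,
                          kernel = "linear", cost = cost,
                          class.weights = svm_weights(y_tr), scale = FALSE)
        for (t2 in seq_len(n_t)) {
          xt2 <- matrix(x[, , t2], dim(x)[1], dim(x)[2])
          pred <- as.character(stats::predict(fit, xt2[te, feats, drop = FALSE]))
          acc[t1, t2] <- acc[t1, t2] + score_metric(y[te], pred, metric)
        }
      }
    }
  }
  structure(list(accuracy = acc / n_models, chance = 1 / n_cls,
                 metric = metric, scheme = scheme),
            class = "tempgen_result")
}

#' Cluster-mass permutation inference for decoding results
#'
#' Re-runs the decoding with permuted labels `n_perm` times, forms the
#' pointwise cluster threshold from the permutation null (per-tail
#' `1 - alpha/2` quantile for two-sided inference, matching a forming
#' threshold of p < 0.05), and scores observed clusters of above-chance
#' (or below-chance) time points by accuracy mass against the max-mass
#' permutation distribution.
#'
#' @param x,y,... data and arguments passed to the decoder.
#' @param decoder decoding function: [decode_timecourse()] (default) or a
#'   compatible wrapper.
#' @param n_perm number of label permutations (default 1,000).
#' @param tail `"two"` (default), `"upper"` or `"lower"`.
#' @param seed integer seed.
#' @return list with `observed` (the decoder output), `clusters` (a
#'   `cluster_result` on accuracy minus chance), `null_accuracy`
#'   `[n_perm, n_times]`.
#' @export
permutation_cluster_test <- function(x, y, ..., decoder = decode_timecourse,
                                     n_perm = 1000, tail = "two", seed = 1) {
  obs <- decoder(x, y, ..., seed = seed)
  acc_obs <- if (is.matrix(obs$accuracy)) obs$accuracy else obs$accuracy
  set.seed(seed + 1L)
  perms <- lapply(seq_len(n_perm), function(i) sample(seq_along(y)))
  null_acc <- lapply(seq_along(perms), function(i)
    decoder(x, y[perms[[i]]], ..., seed = seed + i)$accuracy - obs$chance)
  clusters <- cluster_permutation(acc_obs - obs$chance, null_acc,
                                  threshold = NULL, tail = tail)
  list(observed = obs, clusters = clusters,
       null_accuracy = null_acc, chance = obs$chance)
}

#' Beta-binomial Bayes factor for a decoding accuracy
#'
#' Compares the marginal likelihood of `k` correct out of `n` under a
#' point-ish null (a Beta(1000, 1000) prior centred at chance, updated
#' with the shuffle-null accuracies expressed as per-shuffle correct-trial
#' counts) against a flat Beta(1, 1) alternative. Returns BF01 (> 1
#' favours the null).
#'
#' @param k_correct number of correctly classified trials.
#' @param n_trials total trials.
#' @param null_samples shuffle-based accuracies in \[0, 1\].
#' @param prior_alpha,prior_beta tight null prior (defaults 1000, 1000).
#' @return list with `bf01`, `bf10`, and the null prior parameters after
#'   updating.
#' @export
beta_binomial_bf <- function(k_correct, n_trials, null_samples,
                             prior_alpha = 1000, prior_beta = 1000) {
  stopifnot(k_correct >= 0, k_correct <= n_trials, length(null_samples) > 0,
            all(null_samples >= 0 & null_samples <= 1))
  k_null <- round(null_samples * n_trials)
  a0 <- prior_alpha + sum(k_null)
  b0 <- prior_beta + sum(n_trials - k_null)
  log_marg <- function(a, b)
    lchoose(n_trials, k_correct) +
      lbeta(k_correct + a, n_trials - k_correct + b) - lbeta(a, b)
  l0 <- log_marg(a0, b0)
  l1 <- log_marg(1, 1)
  list(bf01 = exp(l0 - l1), bf10 = exp(l1 - l0), alpha0 = a0, beta0 = b0)
}

#' Compare posterior-only with posterior+prefrontal feature sets
#'
#' Paired t-test on per-fold accuracy differences with the repeated
#' cross-validation variance correction (fold-difference variance
#' multiplied by `1/J + n_test/n_train` over the J folds), one-sided for
#' improvement of the combined set; complemented by a beta-binomial BF01
#' on the pooled accuracies.
#'
#' @param scores_posterior,scores_combined per-fold scores (same fold
#'   structure).
#' @param n_train,n_test per-fold train/test sizes.
#' @param n_trials total test trials for the Bayes factor (optional;
#'   defaults to `n_test * J`).
#' @param null_samples optional shuffle accuracies for the BF.
#' @return list with `t`, `df`, `p` (one-sided, improvement), `mean_diff`,
#'   `correction`, and `bf01` when `null_samples` given.
#' @export
compare_roisets <- function(scores_posterior, scores_combined,
                            n_train, n_test, n_trials = NULL,
                            null_samples = NULL) {
  stopifnot(length(scores_posterior) == length(scores_combined))
  d <- scores_combined - scores_posterior
  j <- length(d)
  corr <- 1 / j + n_test / n_train
  md <- mean(d)
  v <- stats::var(d)
  if (v == 0) {
    tval <- 0; p <- 0.5
  } else {
    tval <- md / sqrt(corr * v)
    p <- stats::pt(tval, df = j - 1, lower.tail = FALSE)
  }
  out <- list(t = tval, df = j - 1, p = p, mean_diff = md,
              correction = corr)
  if (!is.null(null_samples)) {
    if (is.null(n_trials)) n_trials <- n_test * j
    k <- round(mean(scores_combined) * n_trials)
    out$bf01 <- beta_binomial_bf(k, n_trials, null_samples)$bf01
  }
  out
}
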