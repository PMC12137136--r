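## Channel-level screening: task responsiveness (signed-rank on evoked vs
## baseline AUC, FDR-corrected, with a JZS Bayes factor quantifying
## non-responsiveness) and category selectivity (d-prime with a label
## permutation test, both-task rule), plus the behavioural
## log-linear-corrected d-prime.

#' Identify task-responsive channels
#'
#' Per channel and task condition (relevant vs irrelevant non-target
#' trials; targets are excluded), the per-trial AUC of the stimulus-evoked
#' period is compared with the per-trial AUC of the baseline by a paired
#' Wilcoxon signed-rank test; p-values are Benjamini-Hochberg corrected
#' across channels within condition. A channel is flagged responsive if it
#' survives correction in at least one condition. A JZS Bayesian t-test on
#' the paired differences (all non-target trials) quantifies evidence for
#' non-responsiveness (BF01).
#'
#' @param epochs an [epoch_array()].
#' @param baseline,evoked windows in seconds (defaults -0.3-0 s and
#'   0.05-0.35 s).
#' @param q FDR level.
#' @param cauchy_r Cauchy prior scale for the Bayes factor.
#' @return data.frame, one row per channel: `channel`, `p_relevant`,
#'   `p_irrelevant`, `sig_relevant`, `sig_irrelevant`, `responsive`,
#'   `bf01_nonresponsive`.
#' @export
task_responsive <- function(epochs, baseline = c(-0.3, 0),
                            evoked = c(0.05, 0.35), q = 0.05,
                            cauchy_r = 0.707) {
  stopifnot(inherits(epochs, "epoch_array"))
  rel <- epochs$trials$relevance
  cond <- list(relevant = which(rel == "relevant_nontarget"),
               irrelevant = which(rel == "irrelevant"))
  if (!any(lengths(cond) > 0))
    stop("need non-target trials in at least one task condition")
  for (nm in names(cond))
    if (length(cond[[nm]]) > 0 && length(cond[[nm]]) < 10)
      stop("fewer than 10 trials in the ", nm, " condition")
  a_base <- window_reduce(epochs, baseline, "auc")$values
  a_evok <- window_reduce(epochs, evoked, "auc")$values
  n_ch <- ncol(a_base)
  pv <- sapply(names(cond), function(nm) {
    idx <- cond[[nm]]
    if (!length(idx)) return(rep(NA_real_, n_ch))
    vapply(seq_len(n_ch), function(ch) {
      stats::wilcox.test(a_evok[idx, ch], a_base[idx, ch],
                         paired = TRUE, exact = FALSE)$p.value
    }, numeric(1))
  })
  pv <- matrix(pv, n_ch, 2, dimnames = list(NULL, names(cond)))
  sig <- apply(pv, 2, function(p) {
    out <- rep(NA, length(p))
    ok <- !is.na(p)
    out[ok] <- fdr_bh(p[ok], q)
    out
  })
  all_idx <- sort(unlist(cond))
  bf01 <- vapply(seq_len(n_ch), function(ch) {
    d <- a_evok[all_idx, ch] - a_base[all_idx, ch]
    jzs_ttest_bf(d, cauchy_r = cauchy_r)$bf01
  }, numeric(1))
  data.frame(
    channel = epochs$channels$name,
    p_relevant = pv[, "relevant"], p_irrelevant = pv[, "irrelevant"],
    sig_relevant = as.logical(sig[, "relevant"]),
    sig_irrelevant = as.logical(sig[, "irrelevant"]),
    responsive = apply(matrix(as.logical(sig), n_ch, 2), 1,
                       function(z) any(z, na.rm = TRUE)),
    bf01_nonresponsive = bf01,
    stringsAsFactors = FALSE)
}

# d-prime of category j against the others:
# (u_j - mean_i u_i) / sqrt(0.5 * (var_j + mean_i var_i)), i != j
dprime_matrix <- function(x, labels, cats) {
  # x: trials x channels AUC matrix; returns categories x channels d-primes
  g <- matrix(0, nrow(x), length(cats))
  g[cbind(seq_len(nrow(x)), match(labels, cats))] <- 1
  n <- colSums(g)
  means <- crossprod(g, x) / n                     # cats x channels
  sq <- crossprod(g, x^2)
  vars <- (sq - n * means^2) / (n - 1)
  out <- matrix(NA_real_, length(cats), ncol(x))
  for (j in seq_along(cats)) {
    others <- setdiff(seq_along(cats), j)
    num <- means[j, ] - colMeans(means[others, , drop = FALSE])
    den <- sqrt(0.5 * (vars[j, ] + colMeans(vars[others, , drop = FALSE])))
    if (any(den == 0)) stop("zero pooled variance: d-prime undefined")
    out[j, ] <- num / den
  }
  out
}

#' Category selectivity by d-prime with a permutation test
#'
#' Per channel and category, computes a d-prime comparing the window AUC of
#' the category of interest against the mean of the other categories,
#' normalized by the pooled (averaged) variances:
#' `d' = (u_j - mean_i(u_i)) / sqrt((sigma_j^2 + mean_i(sigma_i^2)) / 2)`.
#' Significance comes from shuffling category labels within task condition
#' (one-tailed: large positive d-prime for the preferred category). The
#' test is run separately on the task-relevant and task-irrelevant trials;
#' a channel x category is selective only if significant in both
#' (and, when a `responsive` flag vector is supplied, only if responsive).
#'
#' @param epochs an [epoch_array()].
#' @param window AUC window in seconds (default 0.05-0.4 s).
#' @param n_perm number of label permutations (default 10,000).
#' @param alpha per-test significance level for the both-task rule.
#' @param responsive optional logical vector per channel.
#' @param seed integer seed (independent permutation stream per condition).
#' @return data.frame, one row per channel x category: d-primes and
#'   permutation p-values per condition, plus the `selective` flag.
#' @export
category_dprime <- function(epochs, window = c(0.05, 0.4), n_perm = 10000,
                            alpha = 0.05, responsive = NULL, seed = 1) {
  stopifnot(inherits(epochs, "epoch_array"), n_perm >= 1)
  auc <- window_reduce(epochs, window, "auc")$values
  tr <- epochs$trials
  cats <- CATEGORIES[CATEGORIES %in% unique(tr$category)]
  if (length(cats) < 2) stop("need at least 2 categories")
  conds <- list(relevant = which(tr$relevance == "relevant_nontarget"),
                irrelevant = which(tr$relevance == "irrelevant"))
  conds <- Filter(length, conds)
  set.seed(seed)
  res <- list()
  for (nm in names(conds)) {
    idx <- conds[[nm]]
    x <- auc[idx, , drop = FALSE]
    lab <- tr$category[idx]
    tab <- table(lab)
    if (any(tab[cats] < 2)) stop("need >= 2 trials per category")
    d_obs <- dprime_matrix(x, lab, cats)
    exceed <- matrix(0L, length(cats), ncol(x))
    for (p in seq_len(n_perm)) {
      d_perm <- dprime_matrix(x, sample(lab), cats)
      exceed <- exceed + (d_perm >= d_obs)
    }
    pval <- (1 + exceed) / (n_perm + 1)
    res[[nm]] <- list(d = d_obs, p = pval)
  }
  n_ch <- ncol(auc)
  grid <- expand.grid(channel = seq_len(n_ch), category = cats,
                      stringsAsFactors = FALSE)
  out <- data.frame(
    channel = epochs$channels$name[grid$channel],
    category = grid$category, stringsAsFactors = FALSE)
  for (nm in names(res)) {
    out[[paste0("dprime_", nm)]] <-
      res[[nm]]$d[cbind(match(grid$category, cats), grid$channel)]
    out[[paste0("p_", nm)]] <-
      res[[nm]]$p[cbind(match(grid$category, cats), grid$channel)]
  }
  sel <- rep(TRUE, nrow(out))
  for (nm in names(res)) sel <- sel & out[[paste0("p_", nm)]] <= alpha
  if (!is.null(responsive)) sel <- sel & responsive[grid$channel]
  out$selective <- sel
  out
}

#' Log-linear-corrected behavioural d-prime
#'
#' `d' = qnorm((H + 0.5) / (n_signal + 1)) - qnorm((FA + 0.5) /
#' (n_noise + 1))`; the 0.5/1 increments keep the estimate finite at
#' perfect performance.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative integer
#'   counts.
#' @return the corrected sensitivity index.
#' @export
loglinear_dprime <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig == 0 || n_noise == 0)
    stop("need at least one signal and one noise trial")
  stats::qnorm((hits + 0.5) / (n_sig + 1)) -
    stats::qnorm((false_alarms + 0.5) / (n_noise + 1))
}
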