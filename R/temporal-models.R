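## Duration analysis: theory-specific temporal design matrices over the
## windows of interest, per-channel OLS fits with Gaussian ML likelihood,
## BIC model comparison and delta-BIC Bayes factors, and response-profile
## classification.

WOI_WINDOWS <- list(c(0.8, 1.0), c(1.3, 1.5), c(1.8, 2.0))

MODEL_NAMES <- c("null", "duration", "woi", "duration_x_woi",
                 "iit", "gnwt", "iit_x_category", "gnwt_x_category")

#' Build per-trial x window covariates for the duration analysis
#'
#' Expands each trial into one row per window of interest and attaches the
#' theory regressors. The sustained-maintenance (IIT) regressor is 1 iff
#' the window lies within the stimulus-on period (window end <= stimulus
#' duration); the offset-ignition (GNWT) regressor is 1 iff the window is
#' exactly the 0.3-0.5-s post-offset window (`[duration + 0.3,
#' duration + 0.5]`). Category-interaction model variants multiply the
#' theory regressor by category indicators.
#'
#' @param trials a [trial_table()].
#' @param windows list of `c(t0, t1)` windows (default 0.8-1.0, 1.3-1.5,
#'   1.8-2.0 s).
#' @return data.frame with one row per trial x window: `trial`, `window`
#'   (factor), `duration` (factor), `category`, `iit`, `gnwt`.
#' @export
build_designs <- function(trials, windows = WOI_WINDOWS) {
  stopifnot(inherits(trials, "trial_table"))
  tol <- 1e-9
  offs_ok <- vapply(trials$duration_s, function(d) {
    any(vapply(windows, function(w)
      abs(w[1] - (d + 0.3)) < tol && abs(w[2] - (d + 0.5)) < tol,
      logical(1)))
  }, logical(1))
  if (!all(offs_ok))
    stop("window set does not cover the post-offset window for every duration")
  n_w <- length(windows)
  n <- nrow(trials)
  w_start <- vapply(windows, `[`, numeric(1), 1)
  w_end <- vapply(windows, `[`, numeric(1), 2)
  out <- data.frame(
    trial = rep(trials$trial_id, each = n_w),
    window = factor(rep(seq_len(n_w), times = n)),
    duration = factor(rep(trials$duration_s, each = n_w)),
    category = factor(rep(trials$category, each = n_w), levels = CATEGORIES),
    stringsAsFactors = FALSE)
  dur <- rep(trials$duration_s, each = n_w)
  ws <- rep(w_start, times = n); we <- rep(w_end, times = n)
  out$iit <- as.numeric(we <= dur + tol)
  out$gnwt <- as.numeric(abs(ws - (dur + 0.3)) < tol & abs(we - (dur + 0.5)) < tol)
  out
}

model_formula <- function(name) {
  switch(name,
    null = ~ 1,
    duration = ~ duration,
    woi = ~ window,
    duration_x_woi = ~ duration * window,
    iit = ~ iit,
    gnwt = ~ gnwt,
    iit_x_category = ~ iit:category,
    gnwt_x_category = ~ gnwt:category,
    stop("unknown model: ", name))
}

#' Fit the competing temporal models per channel
#'
#' For every channel, stacks the window-of-interest responses (one
#' observation per trial x window) and fits each model by ordinary least
#' squares with a Gaussian maximum-likelihood variance, so BIC
#' (`k ln n - 2 lnL`) is comparable across models. The winner is the
#' minimum-BIC model, except that when the top models are within
#' `tie_delta` BIC points the one with fewer parameters is preferred.
#'
#' @param values list of `window_scalar` objects (one per window, same
#'   trial set) or a numeric array `[n_trials, n_channels, n_windows]`.
#' @param designs output of [build_designs()] for the same trials/windows.
#' @param models character vector of model names (default all eight).
#' @param tie_delta BIC margin treated as a tie (default 2).
#' @return object of class `model_fit_set`: list with `bic` (channels x
#'   models), `loglik`, `k_params`, `n_obs`, `winner`, `window_means`,
#'   `window_tstats`.
#' @export
fit_models <- function(values, designs, models = MODEL_NAMES,
                       tie_delta = 2) {
  stopifnot(all(models %in% MODEL_NAMES))
  if (is.list(values) && inherits(values[[1]], "window_scalar")) {
    arr <- simplify2array(lapply(values, `[[`, "values"))  # tr x ch x w
  } else arr <- values
  stopifnot(length(dim(arr)) == 3L)
  n_tr <- dim(arr)[1]; n_ch <- dim(arr)[2]; n_w <- dim(arr)[3]
  stopifnot(nrow(designs) == n_tr * n_w)
  # response matrix: rows ordered as designs (trial-major, window-minor)
  y <- matrix(aperm(arr, c(3, 1, 2)), n_tr * n_w, n_ch)
  n <- nrow(y)
  bic <- ll <- matrix(NA_real_, n_ch, length(models),
                      dimnames = list(NULL, models))
  kp <- integer(length(models)); names(kp) <- models
  for (m in models) {
    X <- stats::model.matrix(model_formula(m), designs)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X))
      stop("rank-deficient design for model: ", m)
    res <- y - X %*% qr.coef(qr_x, y)
    rss <- colSums(res^2)
    if (any(rss <= 0)) stop("zero residual variance in model: ", m)
    loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    k <- ncol(X) + 1L  # + residual variance
    kp[m] <- k
    ll[, m] <- loglik
    bic[, m] <- k * log(n) - 2 * loglik
  }
  winner <- apply(bic, 1, function(b) {
    ord <- order(b)
    best <- ord[1]
    # prefer fewer parameters among models within tie_delta of the best
    tied <- which(b - b[best] < tie_delta)
    tied[which.min(kp[models][tied])]
  })
  winner <- models[winner]
  # per-window observed response summaries (for profile classification)
  wm <- t(apply(arr, 3, function(sl) colMeans(matrix(sl, n_tr, n_ch))))
  wse <- t(apply(arr, 3, function(sl)
    apply(matrix(sl, n_tr, n_ch), 2, stats::sd) / sqrt(n_tr)))
  structure(list(bic = bic, loglik = ll, k_params = kp, n_obs = n,
                 winner = winner, models = models,
                 window_means = t(wm), window_se = t(wse),
                 channels = if (!is.null(colnames(arr))) colnames(arr) else
                   sprintf("ch%03d", seq_len(n_ch))),
            class = "model_fit_set")
}

#' Bayes factors between two fitted models from their BIC difference
#'
#' `BF = exp((BIC_a - BIC_b) / 2)` per channel: values above 1 favour
#' model `b` over model `a`.
#'
#' @param fits a [fit_models()] result.
#' @param model_a,model_b model names present in the fit set.
#' @return numeric vector per channel.
#' @export
bf_vs_reference <- function(fits, model_a, model_b) {
  stopifnot(inherits(fits, "model_fit_set"),
            model_a %in% colnames(fits$bic), model_b %in% colnames(fits$bic))
  exp((fits$bic[, model_a] - fits$bic[, model_b]) / 2)
}

#' Classify per-channel temporal response profiles
#'
#' Crosses the winning temporal model with the selectivity and
#' responsiveness flags: an IIT-family winner gives a sustained label
#' (selective or non-selective by the category-selectivity flag); a
#' GNWT-family winner gives `onset_offset`; a theory-agnostic winner
#' (null/duration/woi families) on a task-responsive channel whose late
#' window-of-interest response is indistinguishable from zero gives
#' `onset` (response at stimulus onset only, before the windows of
#' interest); anything else is `unclassified`.
#'
#' @param fits a [fit_models()] result.
#' @param selective logical per channel (any-category selectivity flag).
#' @param responsive logical per channel.
#' @return character vector of labels per channel.
#' @export
classify_profile <- function(fits, selective = NULL, responsive = NULL) {
  stopifnot(inherits(fits, "model_fit_set"))
  n_ch <- length(fits$winner)
  if (is.null(selective)) selective <- rep(FALSE, n_ch)
  if (is.null(responsive)) responsive <- rep(TRUE, n_ch)
  last_w <- ncol(fits$window_means)
  late_null <- abs(fits$window_means[, last_w]) <=
    2 * fits$window_se[, last_w]
  vapply(seq_len(n_ch), function(ch) {
    w <- fits$winner[ch]
    if (w %in% c("iit", "iit_x_category")) {
      if (selective[ch]) "sustained_selective" else "sustained_nonselective"
    } else if (w %in% c("gnwt", "gnwt_x_category")) {
      "onset_offset"
    } else if (responsive[ch] && late_null[ch]) {
      "onset"
    } else "unclassified"
  }, character(1))
}
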