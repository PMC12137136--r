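## Cross-temporal representational similarity analysis: correlation-
## distance RDMs between stimuli at pairs of time points, within- vs
## between-class contrast, surrogate z-scoring from label shuffles,
## cluster inference, and theory-template adjudication over the four test
## windows.

#' Cross-temporal representational dissimilarity tensor
#'
#' Computes `1 - Pearson r` between the feature pattern of stimulus `a` at
#' time `t1` and stimulus `b` at time `t2`, for all stimulus pairs and all
#' (t1, t2) pairs of the supplied time grid. Patterns with zero variance
#' produce masked (NA) cells with a warning.
#'
#' @param patterns numeric array `[n_stimuli, n_features, n_times]` (e.g.
#'   trial-averaged channel patterns on a binned time grid).
#' @param times optional time axis (stored alongside).
#' @return object of class `cross_temporal_rdm`: list with `dissimilarity`
#'   `[n_stim, n_stim, n_t, n_t]` and `times`.
#' @export
compute_rdm <- function(patterns, times = NULL) {
  stopifnot(length(dim(patterns)) == 3L)
  n_s <- dim(patterns)[1]; n_f <- dim(patterns)[2]; n_t <- dim(patterns)[3]
  if (n_f < 2) stop("need at least 2 features")
  if (n_s < 2) stop("need at least 2 stimuli")
  d <- array(NA_real_, dim = c(n_s, n_s, n_t, n_t))
  warned <- FALSE
  for (t1 in seq_len(n_t)) {
    x1 <- t(matrix(patterns[, , t1], n_s, n_f))  # features x stimuli
    sd1 <- apply(x1, 2, stats::sd)
    for (t2 in seq_len(n_t)) {
      x2 <- t(matrix(patterns[, , t2], n_s, n_f))
      sd2 <- apply(x2, 2, stats::sd)
      ok1 <- sd1 > 0; ok2 <- sd2 > 0
      if (!all(ok1) || !all(ok2)) warned <- TRUE
      cc <- matrix(NA_real_, n_s, n_s)
      if (any(ok1) && any(ok2))
        cc[ok1, ok2] <- stats::cor(x1[, ok1, drop = FALSE],
                                   x2[, ok2, drop = FALSE])
      d[, , t1, t2] <- 1 - cc
    }
  }
  if (warned) warning("zero-variance pattern(s): dissimilarity masked (NA)")
  structure(list(dissimilarity = d, times = times),
            class = "cross_temporal_rdm")
}

#' Within- vs between-class contrast of a cross-temporal RDM
#'
#' `obs[t1, t2]` = mean between-class dissimilarity minus mean
#' within-class dissimilarity at that time-point pair (self-pairs
#' excluded); positive values indicate class information.
#'
#' @param rdm a [compute_rdm()] result (or a bare 4D dissimilarity array).
#' @param classes class label per stimulus.
#' @return numeric matrix `[n_t, n_t]`.
#' @export
class_contrast <- function(rdm, classes) {
  d <- if (inherits(rdm, "cross_temporal_rdm")) rdm$dissimilarity else rdm
  n_s <- dim(d)[1]
  stopifnot(length(classes) == n_s)
  if (any(table(classes) < 2)) stop("every class needs >= 2 stimuli")
  same <- outer(classes, classes, `==`)
  diag(same) <- NA  # exclude self-pairs
  within <- which(same)          # off-diagonal, same class
  between <- which(!same)
  n_t <- dim(d)[3]
  obs <- matrix(NA_real_, n_t, n_t)
  for (t1 in seq_len(n_t)) for (t2 in seq_len(n_t)) {
    sl <- d[, , t1, t2]
    obs[t1, t2] <- mean(sl[between], na.rm = TRUE) -
      mean(sl[within], na.rm = TRUE)
  }
  obs
}

#' Surrogate-null z-scoring of the class contrast
#'
#' Re-runs the RSA pipeline `n_surr` times with randomly shuffled labels
#' and z-scores the observed within/between class contrast cellwise:
#' `z[i,j] = (obs[i,j] - mu_surr[i,j]) / sigma_surr[i,j]`.
#'
#' When `x` is a trial-level pattern array and `stimulus` gives the
#' trial-to-stimulus assignment, each surrogate shuffles the trial labels
#' (which stimulus each trial is attributed to, with the stimulus-to-class
#' map held fixed), re-averages trials into stimulus patterns, recomputes
#' the dissimilarity tensor and re-runs the contrast — the full pipeline
#' per shuffle, with a zero-mean null by construction. When `x` is an
#' already computed [compute_rdm()] tensor, the stimulus-level class
#' labels are shuffled instead (a weaker null that leaves the pattern
#' structure in place); the trial-level form is preferred.
#'
#' @param x numeric array `[n_trials, n_features, n_times]`, or a
#'   [compute_rdm()] result.
#' @param classes class label per trial (trial-level form) or per
#'   stimulus (RDM form).
#' @param stimulus trial-to-stimulus grouping (trial-level form only).
#' @param n_surr number of label shuffles (default 1,024; minimum 100).
#' @param seed integer seed.
#' @return object of class `surrogate_null`: list with `obs`, `z`,
#'   `mu_surr`, `sigma_surr`, and `surrogates` (array
#'   `[n_surr, n_t, n_t]`).
#' @export
surrogate_z <- function(x, classes, stimulus = NULL, n_surr = 1024,
                        seed = 1) {
  stopifnot(n_surr >= 100)
  set.seed(seed)
  if (inherits(x, "cross_temporal_rdm")) {
    obs <- class_contrast(x, classes)
    n_t <- nrow(obs)
    surr <- array(NA_real_, dim = c(n_surr, n_t, n_t))
    for (s in seq_len(n_surr))
      surr[s, , ] <- class_contrast(x, sample(classes))
  } else {
    stopifnot(length(dim(x)) == 3L, !is.null(stimulus),
              length(classes) == dim(x)[1],
              length(stimulus) == dim(x)[1])
    # stimulus-to-class map (must be constant within stimulus)
    stim_chr <- as.character(stimulus)
    cls_map <- tapply(as.character(classes), stim_chr,
                      function(v) {
                        u <- unique(v)
                        stopifnot(length(u) == 1L)
                        u
                      })
    pipeline <- function(stim) {
      avg <- average_by_stimulus(x, stim)
      class_contrast(compute_rdm(avg$patterns),
                     as.character(cls_map[avg$levels]))
    }
    obs <- pipeline(stim_chr)
    n_t <- nrow(obs)
    surr <- array(NA_real_, dim = c(n_surr, n_t, n_t))
    n_trials <- dim(x)[1]
    for (s in seq_len(n_surr))
      surr[s, , ] <- pipeline(stim_chr[sample(n_trials)])
  }
  mu <- apply(surr, c(2, 3), mean)
  sg <- apply(surr, c(2, 3), stats::sd)
  if (any(sg == 0, na.rm = TRUE)) {
    warning("zero surrogate s.d. at some cells: z masked (NA)")
    sg[sg == 0] <- NA
  }
  structure(list(obs = obs, z = (obs - mu) / sg, mu_surr = mu,
                 sigma_surr = sg, surrogates = surr, n_surr = n_surr),
            class = "surrogate_null")
}

# average a trial-level pattern array into per-stimulus patterns
average_by_stimulus <- function(x, stimulus) {
  g <- as.character(stimulus)
  ug <- unique(g)
  counts <- as.integer(table(factor(g, levels = ug)))
  n_f <- dim(x)[2]; n_t <- dim(x)[3]
  flat <- matrix(x, dim(x)[1], n_f * n_t)
  sums <- rowsum(flat, factor(g, levels = ug))
  pat <- array(sums / counts, dim = c(length(ug), n_f, n_t))
  list(patterns = pat, levels = ug)
}

#' Cluster significance of a z-scored cross-temporal matrix
#'
#' Thresholds the observed z matrix at `threshold` (default 1.5, upper
#' tail), and scores 2D connected clusters by mass against the max-mass
#' distribution of the z-scored surrogates (each surrogate z-scored
#' against the surrogate ensemble).
#'
#' @param null a [surrogate_z()] result.
#' @param threshold cluster-forming z threshold (default 1.5).
#' @param connectivity 4 or 8.
#' @return a `cluster_result` (see [cluster_permutation()]).
#' @export
cluster_significance <- function(null, threshold = 1.5, connectivity = 4) {
  stopifnot(inherits(null, "surrogate_null"))
  z_surr <- lapply(seq_len(null$n_surr), function(s)
    (null$surrogates[s, , ] - null$mu_surr) / null$sigma_surr)
  cluster_permutation(null$z, z_surr, threshold = threshold,
                      tail = "upper", connectivity = connectivity)
}

#' Theory template matrices over the four test windows
#'
#' Binary 4x4 matrices over the test windows (0.3-0.5, 0.8-1.0, 1.3-1.5,
#' 1.8-2.0 s for a 1.5-s stimulus). The sustained-maintenance (`iit`)
#' template is 1 where both windows precede stimulus offset; the
#' onset/offset-ignition (`gnwt`) template is 1 where both windows are the
#' onset window or the post-offset window, including by default the cross
#' cells (re-ignition of the same content at offset).
#'
#' @param kind `"iit"` or `"gnwt"`.
#' @param stimulus_duration stimulus duration in seconds (default 1.5).
#' @param windows list of the four test windows.
#' @param gnwt_cross include the onset x offset cross cells in the gnwt
#'   template (default TRUE).
#' @return binary matrix `[4, 4]`.
#' @export
theory_template <- function(kind = c("iit", "gnwt"),
                            stimulus_duration = 1.5,
                            windows = list(c(0.3, 0.5), c(0.8, 1.0),
                                           c(1.3, 1.5), c(1.8, 2.0)),
                            gnwt_cross = TRUE) {
  kind <- match.arg(kind)
  n_w <- length(windows)
  w_end <- vapply(windows, `[`, numeric(1), 2)
  w_start <- vapply(windows, `[`, numeric(1), 1)
  tol <- 1e-9
  if (kind == "iit") {
    on <- w_end <= stimulus_duration + tol
    tmpl <- outer(on, on, `&`)
  } else {
    onset <- seq_len(n_w) == 1L
    offset <- abs(w_start - (stimulus_duration + 0.3)) < tol &
      abs(w_end - (stimulus_duration + 0.5)) < tol
    key <- onset | offset
    tmpl <- outer(key, key, `&`)
    if (!gnwt_cross) tmpl <- tmpl & !outer(onset, offset, `&`) &
        !outer(offset, onset, `&`)
  }
  tmpl * 1
}

#' Average a cross-temporal matrix over window-pair blocks
#'
#' @param obs matrix over a fine time grid.
#' @param times time axis matching the rows/columns of `obs`.
#' @param windows list of test windows.
#' @return matrix `[n_windows, n_windows]` of block means.
#' @export
window_subsample <- function(obs, times,
                             windows = list(c(0.3, 0.5), c(0.8, 1.0),
                                            c(1.3, 1.5), c(1.8, 2.0))) {
  tol <- 1e-9
  idx <- lapply(windows, function(w)
    which(times >= w[1] - tol & times <= w[2] + tol))
  if (any(lengths(idx) == 0)) stop("a test window contains no time points")
  n_w <- length(windows)
  out <- matrix(NA_real_, n_w, n_w)
  for (i in seq_len(n_w)) for (j in seq_len(n_w))
    out[i, j] <- mean(obs[idx[[i]], idx[[j]]], na.rm = TRUE)
  out
}

#' Template adjudication between the two theories
#'
#' Correlates the window-subsampled observed matrix (z-scored against the
#' surrogate null, like the matrices the clusters are formed on) with each
#' theory template using Kendall's tau; p-values locate the observed tau
#' in the tau distribution of the label-shuffle surrogates, each surrogate
#' z-scored against the same null (upper tail).
#' If either correlation is significant, the difference of transformed
#' correlations `(tau + 1) / 2` between theories is tested against the
#' surrogate difference null (two-sided). All p-values are
#' Benjamini-Hochberg corrected together.
#'
#' @param null a [surrogate_z()] result computed on the fine time grid.
#' @param times time axis of the contrast matrices.
#' @param windows list of the four test windows.
#' @param stimulus_duration stimulus duration in seconds.
#' @param alpha significance level used for the gating of the difference
#'   test.
#' @param gnwt_cross see [theory_template()].
#' @return data.frame with one row per test (`iit`, `gnwt`, and
#'   `difference` when gated in): `tau` (or tau difference on the
#'   transformed scale), `p`, `p_fdr`, `significant`.
#' @export
template_test <- function(null, times,
                          windows = list(c(0.3, 0.5), c(0.8, 1.0),
                                         c(1.3, 1.5), c(1.8, 2.0)),
                          stimulus_duration = 1.5, alpha = 0.05,
                          gnwt_cross = TRUE) {
  stopifnot(inherits(null, "surrogate_null"))
  obs_w <- window_subsample(null$z, times, windows)
  tmpl <- list(iit = theory_template("iit", stimulus_duration, windows),
               gnwt = theory_template("gnwt", stimulus_duration, windows,
                                      gnwt_cross = gnwt_cross))
  for (k in names(tmpl))
    if (stats::sd(tmpl[[k]]) == 0)
      stop("constant template: tau undefined")
  if (stats::sd(obs_w) == 0)
    stop("constant observed matrix: tau undefined")
  surr_w <- lapply(seq_len(null$n_surr), function(s)
    window_subsample((null$surrogates[s, , ] - null$mu_surr) /
                       null$sigma_surr, times, windows))
  tau_obs <- vapply(tmpl, function(tm)
    stats::cor(as.vector(obs_w), as.vector(tm), method = "kendall"),
    numeric(1))
  tau_surr <- sapply(names(tmpl), function(k)
    vapply(surr_w, function(sw) {
      if (stats::sd(sw) == 0) return(0)
      stats::cor(as.vector(sw), as.vector(tmpl[[k]]), method = "kendall")
    }, numeric(1)))
  n_s <- null$n_surr
  p_theory <- vapply(names(tmpl), function(k)
    (1 + sum(tau_surr[, k] >= tau_obs[k])) / (n_s + 1), numeric(1))
  out <- data.frame(test = names(tmpl), tau = tau_obs, p = p_theory,
                    stringsAsFactors = FALSE)
  if (any(p_theory <= alpha)) {
    tr <- function(x) (x + 1) / 2
    d_obs <- tr(tau_obs["iit"]) - tr(tau_obs["gnwt"])
    d_surr <- tr(tau_surr[, "iit"]) - tr(tau_surr[, "gnwt"])
    p_diff <- (1 + sum(abs(d_surr - mean(d_surr)) >=
                         abs(d_obs - mean(d_surr)))) / (n_s + 1)
    out <- rbind(out, data.frame(test = "difference", tau = d_obs,
                                 p = p_diff, stringsAsFactors = FALSE))
  }
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr <= alpha
  rownames(out) <- NULL
  out
}

#' Subsample-and-average RDM for unequal trial counts
#'
#' Where stimulus groups have unequal trial counts, subsamples every group
#' to the minimum count, computes the cross-temporal RDM, and repeats
#' `n_rep` times. Correlations are averaged across repetitions on the
#' Fisher z scale (the "Fisher corrected" distance): the returned
#' dissimilarity is `1 - tanh(mean(atanh(r)))`.
#'
#' @param epochs an [epoch_array()].
#' @param groups stimulus grouping per trial.
#' @param classes class label per trial.
#' @param n_rep number of subsample repetitions (default 100).
#' @param bin_s optional bin width passed to [stimulus_patterns()].
#' @param seed integer seed.
#' @return a `cross_temporal_rdm` with the Fisher-averaged dissimilarity,
#'   plus `classes` per stimulus.
#' @export
rdm_subsample_average <- function(epochs, groups, classes, n_rep = 100,
                                  bin_s = NULL, seed = 1) {
  stopifnot(inherits(epochs, "epoch_array"))
  set.seed(seed)
  g <- as.character(groups)
  n_min <- min(table(g))
  acc <- NULL
  cls <- NULL
  tms <- NULL
  for (rep_i in seq_len(n_rep)) {
    keep <- unlist(lapply(split(seq_along(g), g), function(ix)
      if (length(ix) > n_min) sample(ix, n_min) else ix), use.names = FALSE)
    keep <- sort(keep)
    sub <- epoch_subset(epochs, trials = keep)
    sp <- stimulus_patterns(sub, g[keep], as.character(classes)[keep], bin_s)
    rdm <- compute_rdm(sp$patterns, sp$times)
    zr <- atanh(pmin(pmax(1 - rdm$dissimilarity, -0.999999), 0.999999))
    acc <- if (is.null(acc)) zr else acc + zr
    cls <- sp$classes
    tms <- sp$times
  }
  d <- 1 - tanh(acc / n_rep)
  structure(list(dissimilarity = d, times = tms, classes = cls),
            class = "cross_temporal_rdm")
}

#' Trial-averaged stimulus patterns on a binned time grid
#'
#' Convenience builder for RSA inputs: averages an epoch array's trials by
#' stimulus grouping (e.g. category x identity x orientation) after
#' binning, returning the `[stimuli, features, times]` pattern array plus
#' per-stimulus class labels.
#'
#' @param epochs an [epoch_array()].
#' @param groups factor-like vector per trial identifying the stimulus.
#' @param classes class label per trial (constant within stimulus group).
#' @param bin_s bin width for [bin_decimate()] (NULL to skip binning).
#' @return list with `patterns`, `classes` (per stimulus), `times`.
#' @export
stimulus_patterns <- function(epochs, groups, classes, bin_s = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (!is.null(bin_s)) epochs <- bin_decimate(epochs, bin_s)
  g <- as.character(groups)
  ug <- unique(g)
  n_f <- dim(epochs$data)[2]; n_t <- dim(epochs$data)[3]
  pat <- array(NA_real_, dim = c(length(ug), n_f, n_t))
  cls <- character(length(ug))
  for (i in seq_along(ug)) {
    sel <- which(g == ug[i])
    sl <- epochs$data[sel, , , drop = FALSE]
    pat[i, , ] <- apply(sl, c(2, 3), mean)
    cl <- unique(as.character(classes)[sel])
    stopifnot(length(cl) == 1L)
    cls[i] <- cl
  }
  list(patterns = pat, classes = cls, times = epochs$times)
}
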