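## Time-frequency estimation (complex Morlet wavelets), pairwise phase
## consistency, content-selective synchrony contrasts, and generalized-
## eigendecomposition spatial filters.

#' Complex Morlet time-frequency decomposition
#'
#' Convolves each trial and channel with analytic Morlet wavelets
#' (Gaussian-windowed complex exponentials, `sigma_t = n_cycles /
#' (2 pi f)`), via FFT. Returns complex coefficients per trial, channel,
#' frequency and time; samples within one wavelet half-width of either
#' epoch edge are flagged in the `edge_mask` attribute (TRUE = valid).
#'
#' @param epochs an [epoch_array()].
#' @param freqs frequency grid in Hz (all below Nyquist).
#' @param n_cycles cycles per wavelet: scalar, vector parallel to
#'   `freqs`, or function of frequency (e.g. `function(f) f / 4`).
#' @return object of class `spectral_estimate`: list with `coef` (complex
#'   array `[trials, channels, freqs, times]`), `freqs`, `times`, `sfreq`,
#'   `edge_mask` (`[freqs, times]` logical).
#' @export
morlet_tfr <- function(epochs, freqs, n_cycles = 4) {
  stopifnot(inherits(epochs, "epoch_array"))
  sfreq <- epochs$sfreq
  if (any(freqs >= sfreq / 2)) stop("frequency at or above Nyquist (sfreq/2)")
  cyc <- if (is.function(n_cycles)) vapply(freqs, n_cycles, numeric(1))
         else rep_len(n_cycles, length(freqs))
  n_tr <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  n_t <- dim(epochs$data)[3]
  # flatten trials x channels into columns for a single batched FFT per freq
  xmat <- matrix(aperm(epochs$data, c(3, 1, 2)), n_t, n_tr * n_ch)
  out <- array(complex(real = NA), dim = c(n_tr, n_ch, length(freqs), n_t))
  edge <- matrix(TRUE, length(freqs), n_t)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_t <- cyc[fi] / (2 * pi * f)
    half <- ceiling(5 * sigma_t * sfreq)           # +- 5 sd support
    tw <- seq(-half, half) / sfreq
    w <- exp(2i * pi * f * tw) * exp(-tw^2 / (2 * sigma_t^2))
    w <- w / sum(abs(w))                           # unit l1 gain
    nw <- length(w)
    nfft <- stats::nextn(n_t + nw - 1L, 2)
    wf <- stats::fft(c(w, rep(0, nfft - nw)))
    xf <- stats::mvfft(rbind(xmat, matrix(0, nfft - n_t, ncol(xmat))))
    conv <- stats::mvfft(xf * wf, inverse = TRUE) / nfft
    centre <- conv[half + seq_len(n_t), , drop = FALSE]
    out[, , fi, ] <- array(t(centre), c(n_tr, n_ch, n_t))
    hw <- half
    valid <- rep(TRUE, n_t)
    if (hw >= 1) {
      valid[seq_len(min(hw, n_t))] <- FALSE
      valid[seq.int(max(1L, n_t - hw + 1L), n_t)] <- FALSE
    }
    edge[fi, ] <- valid
  }
  structure(list(coef = out, freqs = freqs, times = epochs$times,
                 sfreq = sfreq, edge_mask = edge,
                 trials = epochs$trials, channels = epochs$channels),
            class = "spectral_estimate")
}

#' Pairwise phase consistency between two channels
#'
#' For each frequency and time, takes the per-trial phase difference
#' between the two channels and computes the bias-free pairwise phase
#' consistency over all trial pairs:
#' `PPC = 2 / (N (N-1)) * sum_{j<k} cos(dtheta_j - dtheta_k)`,
#' evaluated through the equivalent resultant-vector identity
#' `(|sum_j exp(i dtheta_j)|^2 - N) / (N (N - 1))`.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param chan_a,chan_b channel indices.
#' @param trials optional trial subset (indices); default all.
#' @return matrix `[n_freqs, n_times]` of PPC values in \[-1, 1\].
#' @export
ppc <- function(tfr, chan_a, chan_b, trials = NULL) {
  stopifnot(inherits(tfr, "spectral_estimate"))
  if (is.null(trials)) trials <- seq_len(dim(tfr$coef)[1])
  n <- length(trials)
  if (n < 2) stop("PPC needs at least 2 trials")
  n_f <- dim(tfr$coef)[3]; n_t <- dim(tfr$coef)[4]
  pa <- matrix(tfr$coef[trials, chan_a, , ], n, n_f * n_t)
  pb <- matrix(tfr$coef[trials, chan_b, , ], n, n_f * n_t)
  e <- exp(1i * (Arg(pa) - Arg(pb)))
  s <- colSums(e)
  matrix((Mod(s)^2 - n) / (n * (n - 1)), n_f, n_t)
}

#' Content-selective synchrony contrast with cluster inference
#'
#' Computes the within-category minus across-category PPC contrast for a
#' channel pair (trial counts equated by subsampling the larger set,
#' averaged over `n_equate` repetitions) and assesses significance by
#' permuting the category assignment of trials.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param chan_a,chan_b channel indices of the pair.
#' @param categories category label per trial.
#' @param within_category the pair's preferred category; within-category
#'   trials are those of this category, across-category all others.
#' @param n_perm number of category-shuffle permutations.
#' @param n_equate subsample repetitions for trial-count equating.
#' @param tail passed to [cluster_permutation()] (default `"two"`).
#' @param seed integer seed.
#' @return list with `contrast` (`[n_freqs, n_times]`), `clusters`
#'   (a `cluster_result`), `n_within`, `n_across`.
#' @export
content_selective_sync <- function(tfr, chan_a, chan_b, categories,
                                   within_category, n_perm = 200,
                                   n_equate = 20, tail = "two", seed = 1) {
  stopifnot(inherits(tfr, "spectral_estimate"))
  categories <- as.character(categories)
  idx_w <- which(categories == within_category)
  idx_a <- which(categories != within_category)
  if (length(idx_w) < 2 || length(idx_a) < 2)
    stop("need >= 2 trials in both the within and across condition")
  set.seed(seed)
  contrast_of <- function(iw, ia) {
    n_eq <- min(length(iw), length(ia))
    reps <- if (length(iw) == n_eq && length(ia) == n_eq) 1L else n_equate
    acc <- 0
    for (r in seq_len(reps)) {
      sw <- if (length(iw) > n_eq) sample(iw, n_eq) else iw
      sa <- if (length(ia) > n_eq) sample(ia, n_eq) else ia
      acc <- acc + (ppc(tfr, chan_a, chan_b, sw) -
                      ppc(tfr, chan_a, chan_b, sa))
    }
    acc / reps
  }
  obs <- contrast_of(idx_w, idx_a)
  all_idx <- c(idx_w, idx_a)
  n_w <- length(idx_w)
  nulls <- lapply(seq_len(n_perm), function(p) {
    shuf <- sample(all_idx)
    contrast_of(shuf[seq_len(n_w)], shuf[-seq_len(n_w)])
  })
  clusters <- cluster_permutation(obs, nulls, threshold = NULL, tail = tail)
  list(contrast = obs, clusters = clusters,
       n_within = length(idx_w), n_across = length(idx_a))
}

#' Generalized-eigendecomposition spatial filter
#'
#' Contrasts the channel covariance of a signal condition against a
#' reference condition: per-trial covariances are computed over the given
#' window, trials whose Euclidean distance from the mean covariance
#' exceeds `z_reject` z-scores are excluded (per condition), the reference
#' covariance is shrunk towards its diagonal
#' (`R <- (1 - gamma) R + gamma * mean(diag(R)) * I`), and the
#' generalized eigenproblem `S w = lambda R w` is solved via Cholesky
#' whitening. The eigenvector with the largest eigenvalue is the spatial
#' filter; applying it to the data yields the component time series.
#'
#' @param epochs an [epoch_array()].
#' @param signal_trials,reference_trials trial indices of the two
#'   conditions.
#' @param window covariance window `c(t0, t1)` in seconds (default the
#'   whole epoch).
#' @param gamma diagonal shrinkage weight for the reference covariance
#'   (default 0.01).
#' @param z_reject covariance-distance rejection threshold in z-scores.
#' @return object of class `ged_filter`: list with `filter` (unit-norm
#'   weights), `eigenvalues`, `component` (`[n_trials, n_times]` time
#'   series for all trials), `kept_signal`, `kept_reference`.
#' @export
ged_filter <- function(epochs, signal_trials, reference_trials,
                       window = NULL, gamma = 0.01, z_reject = 3) {
  stopifnot(inherits(epochs, "epoch_array"),
            length(signal_trials) > 0, length(reference_trials) > 0)
  n_ch <- dim(epochs$data)[2]
  if (n_ch < 2) stop("need at least 2 channels")
  tol <- 1e-9
  tsel <- if (is.null(window)) seq_along(epochs$times) else
    which(epochs$times >= window[1] - tol & epochs$times <= window[2] + tol)
  trial_cov <- function(e) {
    x <- matrix(epochs$data[e, , tsel], n_ch, length(tsel))
    x <- x - rowMeans(x)
    tcrossprod(x) / (length(tsel) - 1)
  }
  covs_of <- function(idx) lapply(idx, trial_cov)
  reject <- function(covs) {
    if (length(covs) < 3) return(seq_along(covs))
    m <- Reduce(`+`, covs) / length(covs)
    d <- vapply(covs, function(cv) sqrt(sum((cv - m)^2)), numeric(1))
    z <- (d - mean(d)) / stats::sd(d)
    which(abs(z) <= z_reject)
  }
  cs <- covs_of(signal_trials); cr <- covs_of(reference_trials)
  ks <- reject(cs); kr <- reject(cr)
  s_mat <- Reduce(`+`, cs[ks]) / length(ks)
  r_mat <- Reduce(`+`, cr[kr]) / length(kr)
  r_reg <- (1 - gamma) * r_mat + gamma * mean(diag(r_mat)) * diag(n_ch)
  ch <- tryCatch(chol(r_reg), error = function(e)
    stop("reference covariance is singular; increase gamma"))
  li <- backsolve(ch, diag(n_ch), transpose = TRUE)  # inv(t(chol))
  m <- li %*% s_mat %*% t(li)
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  w <- t(li) %*% eg$vectors[, 1]
  w <- w / sqrt(sum(w^2))
  comp <- apply(epochs$data, c(1, 3), function(v) sum(v * w))
  structure(list(filter = as.numeric(w), eigenvalues = eg$values,
                 component = comp, kept_signal = signal_trials[ks],
                 kept_reference = reference_trials[kr], gamma = gamma),
            class = "ged_filter")
}
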