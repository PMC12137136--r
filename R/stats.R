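## Shared statistical engine: cluster-based permutation inference,
## FDR control, and Bayes-factor utilities used by all analysis stages.

#' Label connected components of a suprathreshold mask
#'
#' Internal flood-fill labelling over a logical vector (1D, runs) or matrix
#' (2D, 4- or 8-neighbour connectivity).
#'
#' @param mask logical vector or matrix.
#' @param connectivity 4 or 8 (2D only).
#' @return integer array of the same shape; 0 marks background, clusters are
#'   numbered from 1.
#' @keywords internal
label_components <- function(mask, connectivity = 4) {
  if (anyNA(mask)) mask[is.na(mask)] <- FALSE
  if (is.null(dim(mask)) || length(dim(mask)) == 1L) {
    lab <- integer(length(mask))
    if (!any(mask)) return(lab)
    r <- rle(as.logical(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    id <- 0L
    for (i in seq_along(r$values)) {
      if (r$values[i]) {
        id <- id + 1L
        lab[starts[i]:ends[i]] <- id
      }
    }
    return(lab)
  }
  stopifnot(length(dim(mask)) == 2L, connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3L); dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(dr == 0L & dc == 0L); dr <- dr[keep]; dc <- dc[keep]
  }
  id <- 0L
  todo <- which(mask)
  for (cell in todo) {
    if (lab[cell] != 0L) next
    id <- id + 1L
    stack <- cell
    lab[cell] <- id
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- (cur - 1L) %% nr + 1L
      c0 <- (cur - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        r1 <- r0 + dr[k]; c1 <- c0 + dc[k]
        if (r1 >= 1L && r1 <= nr && c1 >= 1L && c1 <= nc) {
          idx <- (c1 - 1L) * nr + r1
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- id
            stack <- c(stack, idx)
          }
        }
      }
    }
  }
  lab
}

#' Cluster-based permutation test
#'
#' Finds connected components of a statistic map exceeding a cluster-forming
#' threshold, scores each by its mass (sum of the statistic over the
#' cluster), and assigns corrected p-values by ranking the observed masses in
#' the distribution of maximal cluster masses obtained from permutation (or
#' surrogate) statistic maps. Two-sided inference runs two one-sided passes,
#' one per tail, each at half the nominal level (cluster p-values are
#' doubled so that `p <= alpha` keeps the family-wise level at `alpha`).
#'
#' @param observed numeric vector (1D) or matrix (2D) of statistics.
#' @param null_samples list of arrays (same shape as `observed`), or an array
#'   with the permutation index as its first dimension, holding the
#'   permutation/surrogate statistic maps.
#' @param threshold cluster-forming threshold: a scalar, an array of
#'   pointwise thresholds, or `NULL` to derive pointwise thresholds from the
#'   `1 - alpha` (per tail) quantile of `null_samples`.
#' @param tail `"upper"`, `"lower"` or `"two"`.
#' @param connectivity 4 (default) or 8 neighbourhood for 2D maps.
#' @param alpha forming-level used when `threshold` is derived from the null
#'   samples.
#' @return an object of class `cluster_result`: list with `clusters` (each a
#'   list with `mask`, `mass`, `p`, `tail`), `threshold`, `n_perm`, and the
#'   max-mass null distribution(s).
#' @examples
#' set.seed(1)
#' obs <- matrix(rnorm(25), 5, 5); obs[2:3, 2:3] <- 6
#' nulls <- lapply(1:200, function(i) matrix(rnorm(25), 5, 5))
#' res <- cluster_permutation(obs, nulls, threshold = 2, tail = "upper")
#' @export
cluster_permutation <- function(observed, null_samples, threshold = NULL,
                                tail = c("upper", "two", "lower"),
                                connectivity = 4, alpha = 0.05) {
  tail <- match.arg(tail)
  if (is.array(null_samples) && !is.list(null_samples)) {
    null_samples <- lapply(seq_len(dim(null_samples)[1]), function(i) {
      if (length(dim(null_samples)) == 3L) null_samples[i, , ] else null_samples[i, ]
    })
  }
  n_perm <- length(null_samples)
  stopifnot(n_perm >= 1L, all(is.finite(observed[!is.na(observed)])))
  dims <- dim(observed)

  per_tail_alpha <- if (tail == "two") alpha / 2 else alpha
  derive_thr <- function(upper) {
    if (!is.null(threshold)) return(threshold)
    flat <- vapply(null_samples, as.vector, numeric(length(observed)))
    q <- apply(flat, 1L, stats::quantile,
               probs = if (upper) 1 - per_tail_alpha else per_tail_alpha,
               names = FALSE)
    out <- q
    if (!is.null(dims)) dim(out) <- dims
    out
  }

  run_pass <- function(negative) {
    thr <- derive_thr(upper = !negative)
    s <- if (negative) -observed else observed
    th <- if (negative && is.null(threshold)) -thr else thr
    mask <- s > th
    lab <- label_components(mask, connectivity)
    null_max <- vapply(null_samples, function(m) {
      sn <- if (negative) -m else m
      msk <- sn > th
      lb <- label_components(msk, connectivity)
      if (!any(lb > 0L)) 0 else
        max(vapply(seq_len(max(lb)), function(i) sum(sn[lb == i]), numeric(1)))
    }, numeric(1))
    clusters <- list()
    if (any(lab > 0L)) {
      for (i in seq_len(max(lab))) {
        mass <- sum(s[lab == i])
        p <- (1 + sum(null_max >= mass)) / (n_perm + 1)
        # two one-sided passes at alpha/2 each: report the Bonferroni-
        # doubled p so "p <= alpha" keeps the family-wise level at alpha
        if (tail == "two") p <- min(1, 2 * p)
        clusters[[length(clusters) + 1L]] <- list(
          mask = lab == i,
          mass = if (negative) -mass else mass,
          p = p,
          tail = if (negative) "lower" else "upper")
      }
    }
    list(clusters = clusters, null_max = null_max, threshold = thr)
  }

  passes <- switch(tail,
    upper = list(run_pass(FALSE)),
    lower = list(run_pass(TRUE)),
    two   = list(run_pass(FALSE), run_pass(TRUE)))
  out <- list(
    clusters = do.call(c, lapply(passes, `[[`, "clusters")),
    threshold = passes[[1]]$threshold,
    n_perm = n_perm,
    null_max = lapply(passes, `[[`, "null_max"),
    tail = tail, alpha = alpha)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation result (%s tail, %d permutations)\n",
              x$tail, x$n_perm))
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d [%s]: size %d, mass %.3f, p = %.4g\n",
                  i, cl$tail, sum(cl$mask), cl$mass, cl$p))
    }
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control at level `q`; returns the logical
#' rejection mask (wrapper around [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Bayes factor from a BIC difference
#'
#' `BF = exp((bic_0 - bic_1) / 2)`: the evidence for model 1 over model 0
#' under the unit-information-prior approximation.
#'
#' @param bic_0,bic_1 finite BIC values.
#' @export
bf_from_bic <- function(bic_0, bic_1) {
  stopifnot(is.finite(bic_0), is.finite(bic_1))
  exp((bic_0 - bic_1) / 2)
}

#' JZS Bayes factor for a t-test
#'
#' Default-prior Bayes factor for the point null against a Cauchy(0, r)
#' effect-size alternative (Jeffreys-Zellner-Siow), computed by
#' one-dimensional numerical integration over the g-prior mixing variable.
#' Returns BF01 (evidence for the null).
#'
#' @param x numeric vector: one sample, paired differences, or first group.
#' @param y optional second group for the two-sample test.
#' @param paired if `TRUE` with `y`, test `x - y`.
#' @param cauchy_r Cauchy prior scale (default 0.707).
#' @return named list with `bf01`, `bf10`, `t`, `df`.
#' @export
jzs_ttest_bf <- function(x, y = NULL, paired = FALSE, cauchy_r = 0.707) {
  if (!is.null(y) && paired) {
    stopifnot(length(x) == length(y))
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    stopifnot(n >= 3)
    if (stats::sd(x) == 0) stop("zero variance: JZS Bayes factor undefined")
    tval <- mean(x) / (stats::sd(x) / sqrt(n))
    neff <- n
    df <- n - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    stopifnot(n1 >= 2, n2 >= 2, n1 + n2 >= 5)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) stop("zero variance: JZS Bayes factor undefined")
    tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    neff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  r2 <- cauchy_r^2
  # delta ~ Cauchy(0, r)  <=>  g ~ InverseGamma(1/2, r^2/2)
  log_m0 <- -(df + 1) / 2 * log1p(tval^2 / df)
  integrand <- function(g) {
    a <- 1 + neff * g
    exp(-0.5 * log(a) - (df + 1) / 2 * log1p(tval^2 / (a * df)) +
          0.5 * log(r2 / 2) - lgamma(0.5) - 1.5 * log(g) - r2 / (2 * g))
  }
  m1 <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                         subdivisions = 500L)$value
  bf10 <- m1 / exp(log_m0)
  list(bf01 = 1 / bf10, bf10 = bf10, t = tval, df = df)
}
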