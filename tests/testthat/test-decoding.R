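test_that("pseudotrials preserve class means and shrink noise", {
  set.seed(2)
  x <- matrix(rnorm(1000 * 4), 1000, 4)
  y <- rep(c("a", "b"), each = 500)
  x[y == "b", ] <- x[y == "b", ] + 2
  pt <- make_pseudotrials(x, y, k = 5, seed = 3)
  expect_equal(nrow(pt$x), 200)
  # class means preserved exactly (all trials used: 500 divisible by 5)
  for (cl in c("a", "b"))
    expect_equal(colMeans(pt$x[pt$y == cl, ]), colMeans(x[y == cl, ]),
                 tolerance = 1e-12)
  # noise variance shrinks ~ 1/k
  v_ratio <- mean(apply(pt$x[pt$y == "a", ], 2, var) /
                    apply(x[y == "a", ], 2, var))
  expect_equal(v_ratio, 1 / 5, tolerance = 0.35)
  # k = 1 is the identity up to trial order
  p1 <- make_pseudotrials(x, y, k = 1, seed = 4)
  expect_equal(dim(p1$x), dim(x))
  expect_equal(sort(p1$x[, 1]), sort(x[, 1]))
  expect_error(make_pseudotrials(x[1:6, ], y[c(1:3, 501:503)], k = 4),
               "smaller than k")
})

test_that("F-ranking matches the between/within variance ratio and finds signal", {
  # 3-group toy against a hand-coded F
  set.seed(5)
  y <- rep(c("a", "b", "c"), times = c(5, 6, 7))
  x <- matrix(rnorm(18 * 3), 18, 3)
  idx <- rank_features(x, y, 3)
  f_hand <- apply(x, 2, function(v) {
    gm <- tapply(v, y, mean); ng <- tapply(v, y, length)
    ssb <- sum(ng * (gm - mean(v))^2)
    ssw <- sum((v - gm[y])^2)
    (ssb / 2) / (ssw / 15)
  })
  expect_equal(idx, order(-f_hand, seq_along(f_hand)))
  f_aov <- summary(aov(x[, 1] ~ y))[[1]]$`F value`[1]
  expect_equal(f_hand[1], f_aov, tolerance = 1e-9)
  # one informative feature among 50 noise features ranks first
  set.seed(6)
  y2 <- rep(c("a", "b"), each = 40)
  x2 <- matrix(rnorm(80 * 51), 80, 51)
  x2[y2 == "b", 17] <- x2[y2 == "b", 17] + 3
  expect_equal(rank_features(x2, y2, 1), 17)
  # k >= n_features returns everything
  expect_length(rank_features(x2, y2, 100), 51)
  # constant feature ranks last
  x3 <- cbind(x2[, 1:3], 5)
  expect_equal(rank_features(x3, y2, 4)[4], 4)
})

test_that("balanced accuracy equals the per-class sensitivity mean", {
  expect_equal(balanced_accuracy(c("a", "b"), c("a", "b")), 1)
  # constant 'front' predictor on 160/80/80 -> 1/3
  y <- rep(c("front", "left", "right"), times = c(160, 80, 80))
  expect_equal(balanced_accuracy(y, rep("front", 320)), 1 / 3)
  # random confusion table against a brute-force oracle
  set.seed(7)
  yt <- sample(c("x", "y", "z"), 200, replace = TRUE)
  yp <- sample(c("x", "y", "z"), 200, replace = TRUE)
  ref <- mean(vapply(unique(yt), function(cl)
    sum(yt == cl & yp == cl) / sum(yt == cl), numeric(1)))
  expect_equal(balanced_accuracy(yt, yp), ref, tolerance = 1e-12)
  # equals plain accuracy for balanced classes
  yb <- rep(c("x", "y"), each = 50)
  pb <- sample(c("x", "y"), 100, replace = TRUE)
  expect_equal(balanced_accuracy(yb, pb), mean(yb == pb), tolerance = 1e-12)
  expect_error(balanced_accuracy(character(0), character(0)))
})

test_that("planted signals decode near ceiling inside their window only", {
  set.seed(8)
  n <- 60
  y <- rep(c("face", "object"), each = n / 2)
  # 6 time points; separable signal at times 2-4 only
  x <- array(rnorm(n * 8 * 6), c(n, 8, 6))
  for (t in 2:4) x[y == "object", 1:3, t] <- x[y == "object", 1:3, t] + 5
  res <- decode_timecourse(x, y, "within_cv", n_folds = 5, n_repeats = 1,
                           seed = 9)
  expect_gte(min(res$accuracy[2:4]), 0.95)
  expect_lt(max(abs(res$accuracy[c(1, 5, 6)] - 0.5)), 0.25)
  expect_equal(res$chance, 0.5)
})

test_that("cross-task decoding generalizes shared geometry", {
  set.seed(10)
  n <- 80
  task <- rep(c("relevant", "irrelevant"), each = n / 2)
  y <- rep(rep(c("face", "object"), each = n / 4), 2)
  x <- array(rnorm(n * 6 * 2), c(n, 6, 2))
  x[y == "object", 1:2, 1] <- x[y == "object", 1:2, 1] + 4  # time 1 only
  res <- decode_timecourse(x, y, "cross_task", task = task,
                           train_task = "relevant", n_folds = 5,
                           n_repeats = 1, seed = 11)
  expect_gt(res$accuracy[1], 0.9)
  expect_lt(abs(res$accuracy[2] - 0.5), 0.3)
})

test_that("temporal generalization distinguishes static from transient codes", {
  set.seed(12)
  n <- 48
  y <- rep(c("a", "b"), each = n / 2)
  # static sustained code: same pattern at times 1-3, nothing at 4-5
  xs <- array(rnorm(n * 5 * 5), c(n, 5, 5))
  for (t in 1:3) xs[y == "b", 1:2, t] <- xs[y == "b", 1:2, t] + 4
  tg <- temporal_generalization(xs, y, n_folds = 4, n_repeats = 1, seed = 13)
  expect_gte(min(tg$accuracy[1:3, 1:3]), 0.85)   # square above-chance region
  expect_lt(mean(tg$accuracy[4:5, 4:5]), 0.7)
  # transient code at time 1 only: off-diagonal train-1/test-3 is chance-ish
  xt <- array(rnorm(n * 5 * 5), c(n, 5, 5))
  xt[y == "b", 1:2, 1] <- xt[y == "b", 1:2, 1] + 4
  tg2 <- temporal_generalization(xt, y, n_folds = 4, n_repeats = 1, seed = 14)
  expect_gt(tg2$accuracy[1, 1], 0.85)
  expect_lt(mean(tg2$accuracy[1, 3:5]), 0.7)
  expect_lt(mean(tg2$accuracy[3:5, 3:5]), 0.7)
})

test_that("no information leaks from test folds into training", {
  # leakage canary: a feature equal to the label on test folds only must
  # not raise accuracy above chance
  set.seed(15)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- array(rnorm(n * 4 * 2), c(n, 4, 2))
  accs <- c()
  for (r in 1:10) {
    canary <- as.numeric(y == "b")
    x2 <- x
    # plant the canary then corrupt it on a random "training-like" half;
    # a leak-free harness cannot benefit because ranking/fitting uses
    # training rows only, where the canary is noise
    train_half <- sample(n, n / 2)
    canary[train_half] <- rnorm(n / 2)
    x2[, 4, ] <- canary
    res <- decode_timecourse(x2, y, "within_cv", n_folds = 2, n_repeats = 1,
                             n_features = 2, seed = 20 + r)
    accs <- c(accs, mean(res$accuracy))
  }
  expect_lt(mean(accs), 0.75)
})

test_that("label-shuffled data decode at chance", {
  set.seed(16)
  accs2 <- accs3 <- c()
  for (r in 1:10) {
    x <- array(rnorm(120 * 6), c(120, 6, 1))
    y2 <- sample(rep(c("a", "b"), each = 60))
    accs2 <- c(accs2, decode_timecourse(x, y2, n_repeats = 1,
                                        seed = 30 + r)$accuracy)
    y3 <- sample(rep(c("f", "l", "r"), times = c(60, 30, 30)))
    accs3 <- c(accs3, decode_timecourse(x, y3, n_repeats = 1,
                                        metric = "balanced_accuracy",
                                        seed = 40 + r)$accuracy)
  }
  expect_equal(mean(accs2), 0.5, tolerance = 0.1)
  expect_equal(mean(accs3), 1 / 3, tolerance = 0.15)
})

test_that("cluster-mass permutation flags a strong sustained effect", {
  set.seed(17)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- array(rnorm(n * 4 * 5), c(n, 4, 5))
  for (t in 2:4) x[y == "b", 1:2, t] <- x[y == "b", 1:2, t] + 5
  res <- permutation_cluster_test(x, y, n_folds = 3, n_repeats = 1,
                                  n_perm = 99, seed = 18)
  ps <- vapply(res$clusters$clusters, `[[`, numeric(1), "p")
  expect_true(any(ps <= 0.05))
  expect_equal(min(ps), 2 / 100)  # two-sided permutation floor (2x one-sided)
})

test_that("roi-set comparison applies the repeated-CV variance correction", {
  # correction factor: J = 15 folds, 80/20 split -> 1/15 + 0.25
  res0 <- compare_roisets(rep(0.7, 15), rep(0.7, 15), n_train = 80,
                          n_test = 20)
  expect_equal(res0$correction, 1 / 15 + 0.25, tolerance = 1e-12)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)
  # hand arithmetic on a non-trivial difference vector
  set.seed(19)
  d <- rnorm(15, 0.05, 0.02)
  sp <- rep(0.7, 15); sc <- sp + d
  res <- compare_roisets(sp, sc, n_train = 80, n_test = 20)
  expect_equal(res$t, mean(d) / sqrt((1 / 15 + 0.25) * var(d)),
               tolerance = 1e-12)
  expect_equal(res$p, pt(res$t, 14, lower.tail = FALSE), tolerance = 1e-12)
  # a genuinely better combined set is detected
  expect_lt(res$p, 0.05)
})
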