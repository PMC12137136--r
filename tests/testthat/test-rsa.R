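test_that("correlation distances match a brute-force loop and its bounds", {
  set.seed(4)
  pat <- array(rnorm(10 * 5 * 3), c(10, 5, 3))
  rdm <- compute_rdm(pat)
  d <- rdm$dissimilarity
  for (rep_i in 1:20) {
    a <- sample(10, 1); b <- sample(10, 1)
    t1 <- sample(3, 1); t2 <- sample(3, 1)
    expect_equal(d[a, b, t1, t2],
                 1 - cor(pat[a, , t1], pat[b, , t2]), tolerance = 1e-12)
  }
  # self-dissimilarity 0 at equal times; symmetric slice; range [0, 2]
  for (t1 in 1:3) {
    expect_true(all(abs(diag(d[, , t1, t1])) < 1e-12))
    expect_equal(d[, , t1, t1], t(d[, , t1, t1]), tolerance = 1e-12)
  }
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
  # identical patterns -> 0; sign-flipped -> 2
  p2 <- array(0, c(2, 4, 1))
  p2[1, , 1] <- c(1, 2, 3, 4); p2[2, , 1] <- -c(1, 2, 3, 4)
  d2 <- compute_rdm(p2)$dissimilarity
  expect_equal(d2[1, 2, 1, 1], 2, tolerance = 1e-12)
  p3 <- p2; p3[2, , 1] <- p3[1, , 1]
  expect_equal(compute_rdm(p3)$dissimilarity[1, 2, 1, 1], 0, tolerance = 1e-12)
})

test_that("dissimilarities are invariant to per-pattern affine rescaling", {
  set.seed(6)
  pat <- array(rnorm(8 * 6 * 2), c(8, 6, 2))
  pat2 <- pat
  for (i in 1:8) for (t in 1:2)
    pat2[i, , t] <- pat[i, , t] * runif(1, 0.5, 3) + rnorm(1)
  expect_equal(compute_rdm(pat)$dissimilarity,
               compute_rdm(pat2)$dissimilarity, tolerance = 1e-10)
})

test_that("class contrast separates planted clusters and is null otherwise", {
  set.seed(9)
  n_s <- 12; n_f <- 6
  cls <- rep(c("a", "b"), each = 6)
  proto <- matrix(rnorm(2 * n_f), 2, n_f)
  pat <- array(rnorm(n_s * n_f * 2, sd = 0.01), c(n_s, n_f, 2))
  for (i in 1:n_s) for (t in 1:2)
    pat[i, , t] <- pat[i, , t] + proto[(cls[i] == "b") + 1, ]
  obs <- class_contrast(compute_rdm(pat), cls)
  expect_true(all(obs > 0))
  # all stimuli identical -> contrast 0 everywhere
  pid <- array(rep(rnorm(n_f), each = n_s), c(n_s, n_f, 1)) +
    array(rnorm(n_s * n_f, sd = 1e-8), c(n_s, n_f, 1))
  obs0 <- class_contrast(compute_rdm(pid), cls)
  expect_lt(max(abs(obs0)), 1e-3)
  # randomly permuted labels have expectation 0
  set.seed(10)
  pats <- array(rnorm(n_s * n_f * 1), c(n_s, n_f, 1))
  vals <- replicate(200, class_contrast(compute_rdm(pats), sample(cls))[1, 1])
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(200) + 1e-3)
  expect_error(class_contrast(compute_rdm(pat), c(rep("a", 11), "b")),
               ">= 2 stimuli")
})

test_that("surrogate z-scoring is exact on a toy and calibrated on null data", {
  # hand-computed z on a toy: obs equal to the surrogate mean gives z = 0
  ps <- rsa_patterns("null", n_stim = 8, n_feat = 5, k_trials = 10, seed = 2)
  null <- surrogate_z(ps$x, ps$classes, ps$stimulus, n_surr = 100, seed = 3)
  expect_equal(null$z, (null$obs - null$mu_surr) / null$sigma_surr,
               tolerance = 1e-12)
  z2 <- (null$obs[2, 2] - mean(null$surrogates[, 2, 2])) /
    sd(null$surrogates[, 2, 2])
  expect_equal(null$z[2, 2], z2, tolerance = 1e-12)
  # null data: z approximately standard normal across cells and replicates
  zs <- c()
  for (r in 1:12) {
    ps <- rsa_patterns("null", n_stim = 8, n_feat = 5, k_trials = 10,
                       seed = 20 + r)
    nl <- surrogate_z(ps$x, ps$classes, ps$stimulus, n_surr = 100,
                      seed = 30 + r)
    zs <- c(zs, as.vector(nl$z))
  }
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.85); expect_lt(sd(zs), 1.15)
})

test_that("theory templates encode the predicted window structure", {
  ti <- theory_template("iit")
  expect_equal(ti, outer(c(1, 1, 1, 0), c(1, 1, 1, 0)))
  tg <- theory_template("gnwt")
  expect_equal(tg, outer(c(1, 0, 0, 1), c(1, 0, 0, 1)))
  tg0 <- theory_template("gnwt", gnwt_cross = FALSE)
  expect_equal(tg0, diag(c(1, 0, 0, 1)))
})

test_that("planted geometries select the matching theory template", {
  # sustained -> iit template wins with a significant difference
  ps <- rsa_patterns("sustained", seed = 45)
  null <- surrogate_z(ps$x, ps$classes, ps$stimulus, n_surr = 200, seed = 46)
  tt <- template_test(null, ps$times)
  expect_gt(tt$tau[tt$test == "iit"], tt$tau[tt$test == "gnwt"])
  expect_true(tt$significant[tt$test == "iit"])
  expect_true("difference" %in% tt$test &&
                tt$significant[tt$test == "difference"])
  # onset+offset -> gnwt template wins
  ps2 <- rsa_patterns("onset_offset", seed = 43)
  null2 <- surrogate_z(ps2$x, ps2$classes, ps2$stimulus, n_surr = 200,
                       seed = 44)
  tt2 <- template_test(null2, ps2$times)
  expect_gt(tt2$tau[tt2$test == "gnwt"], tt2$tau[tt2$test == "iit"])
  # identical matrices: obs equal to the iit template correlates perfectly
  expect_equal(cor(as.vector(theory_template("iit")),
                   as.vector(theory_template("iit")), method = "kendall"), 1)
})

test_that("cluster inference flags planted blocks and nothing on empty fields", {
  ps <- rsa_patterns("sustained", seed = 51)
  null <- surrogate_z(ps$x, ps$classes, ps$stimulus, n_surr = 150, seed = 52)
  cs <- cluster_significance(null, threshold = 1.5)
  sig <- Filter(function(cl) cl$p <= 0.05, cs$clusters)
  expect_gte(length(sig), 1)
  # the significant cluster covers the sustained (3x3 window) block
  big <- sig[[which.max(vapply(sig, `[[`, numeric(1), "mass"))]]
  expect_true(all(big$mask[1:3, 1:3]))
  expect_false(any(big$mask[4, 4]))
  # pure-noise field: no clusters below the floor
  ps0 <- rsa_patterns("null", n_stim = 8, n_feat = 5, k_trials = 10, seed = 53)
  null0 <- surrogate_z(ps0$x, ps0$classes, ps0$stimulus, n_surr = 150,
                       seed = 54)
  cs0 <- cluster_significance(null0, threshold = 1.5)
  ps_vals <- vapply(cs0$clusters, `[[`, numeric(1), "p")
  if (length(ps_vals)) expect_gte(min(ps_vals), 1 / 151)
})

test_that("subsample-averaged RDMs agree with direct RDMs on balanced data", {
  set.seed(61)
  tt <- tiny_trials(24, duration = 1.5)
  ep <- noise_epochs(tt, n_channels = 5, sfreq = 50, seed = 62)
  groups <- rep(1:6, each = 4)
  classes <- rep(c("a", "b"), each = 12)
  r1 <- rdm_subsample_average(ep, groups, classes, n_rep = 3, seed = 63)
  sp <- stimulus_patterns(ep, groups, classes)
  r2 <- compute_rdm(sp$patterns)
  # balanced counts: no subsampling happens, Fisher average = single RDM
  expect_equal(r1$dissimilarity, r2$dissimilarity, tolerance = 1e-6)
})
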