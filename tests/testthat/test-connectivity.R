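test_that("Morlet decomposition localizes frequency and scales linearly", {
  tt <- tiny_trials(3, duration = 1.0)
  sfreq <- 200
  times_c <- (0:4000) / sfreq
  sig <- rbind(sin(2 * pi * 10 * times_c), 2 * sin(2 * pi * 10 * times_c))
  ep <- epoch(sig, sfreq, tt, tmin = -0.5, tmax = 1.5)
  tfr <- morlet_tfr(ep, freqs = seq(4, 20, 2), n_cycles = 4)
  expect_equal(length(tfr$freqs), 9)
  mid <- tfr$times > 0 & tfr$times < 1
  pw <- apply(Mod(tfr$coef[1, 1, , mid])^2, 1, mean)
  expect_equal(tfr$freqs[which.max(pw)], 10)
  # doubling amplitude quadruples power, leaves phase unchanged
  p1 <- Mod(tfr$coef[1, 1, 4, mid])^2
  p2 <- Mod(tfr$coef[1, 2, 4, mid])^2
  expect_equal(p2 / p1, rep(4, sum(mid)), tolerance = 1e-6)
  ph_diff <- Arg(tfr$coef[1, 2, 4, mid]) - Arg(tfr$coef[1, 1, 4, mid])
  expect_lt(max(abs(ph_diff)), 1e-6)
  # 2-30 Hz at 1-Hz steps is 29 bins; Nyquist guard
  expect_length(morlet_tfr(ep, 2:30, 4)$freqs, 29)
  expect_error(morlet_tfr(ep, c(10, 100), 4), "Nyquist")
})

test_that("PPC matches the brute-force pairwise loop and its exact cases", {
  tt <- tiny_trials(6, duration = 1.0)
  ep <- simulate_oscillations(tt, channel_info(c("a", "b")),
                              carrier_freq_hz = 8, noise_sd = 0.3,
                              sfreq = 100, seed = 5)
  tfr <- morlet_tfr(ep, freqs = c(6, 8, 10), n_cycles = 4)
  got <- ppc(tfr, 1, 2)
  # brute-force double loop at machine precision
  for (fi in 1:3) for (ti in seq(10, 300, by = 97)) {
    dphi <- Arg(tfr$coef[, 1, fi, ti]) - Arg(tfr$coef[, 2, fi, ti])
    acc <- 0
    for (j in 1:5) for (k in (j + 1):6) acc <- acc + cos(dphi[j] - dphi[k])
    expect_equal(got[fi, ti], 2 / (6 * 5) * acc, tolerance = 1e-10)
  }
  # N = 2 gives exactly cos(dphi1 - dphi2)
  g2 <- ppc(tfr, 1, 2, trials = c(1, 2))
  dphi12 <- (Arg(tfr$coef[1, 1, 2, 50]) - Arg(tfr$coef[1, 2, 2, 50])) -
    (Arg(tfr$coef[2, 1, 2, 50]) - Arg(tfr$coef[2, 2, 2, 50]))
  expect_equal(g2[2, 50], cos(dphi12), tolerance = 1e-10)
  expect_error(ppc(tfr, 1, 2, trials = 1), "at least 2")
})

test_that("PPC is phase-offset invariant, 1 for locked phases, ~0 for independent", {
  # identical phase differences across trials give exactly 1
  tt <- tiny_trials(20, duration = 1.5)
  ep <- simulate_oscillations(tt, channel_info(c("a", "b")),
    carrier_freq_hz = 10,
    coupling = list(coupling_spec(c(1, 2), 10, kappa = 1, phase_lag = 1)),
    noise_sd = 0, sfreq = 100, seed = 6)
  tfr <- morlet_tfr(ep, freqs = 10, n_cycles = 4)
  mid <- which(tfr$times > 0.3 & tfr$times < 1.0)
  expect_true(all(ppc(tfr, 1, 2)[1, mid] > 0.999))
  # independent uniform phases: E[PPC] -> 0 at N = 200
  tt2 <- tiny_trials(200, seed = 3)
  ep2 <- simulate_oscillations(tt2, channel_info(c("a", "b")),
                               carrier_freq_hz = 10, noise_sd = 0,
                               sfreq = 100, seed = 7)
  tfr2 <- morlet_tfr(ep2, freqs = 10, n_cycles = 4)
  expect_lt(max(abs(ppc(tfr2, 1, 2)[1, mid])), 0.02 + 3 / 200)
  # common phase offset on one channel leaves PPC unchanged
  tfr3 <- tfr2
  tfr3$coef[, 2, , ] <- tfr3$coef[, 2, , ] * exp(1i * 0.8)
  expect_equal(ppc(tfr3, 1, 2), ppc(tfr2, 1, 2), tolerance = 1e-9)
})

test_that("content-selective synchrony flags planted coupling in band and window", {
  sch <- nontargets(generate_schedule(design_spec("ieeg"), seed = 61))
  sch <- trial_table(sch[sch$category %in% c("face", "object"), ][1:120, ])
  ep <- simulate_oscillations(sch, channel_info(c("v1", "fus")),
    carrier_freq_hz = 40,
    coupling = list(coupling_spec(c(1, 2), 40, kappa = 0.8,
                                  category = "face", window = c(0.3, 1.0))),
    noise_sd = 0.3, sfreq = 128, tmin = -0.25, tmax = 1.25, seed = 62)
  tfr <- morlet_tfr(ep, freqs = seq(32, 48, 4), n_cycles = function(f) f / 4)
  res <- content_selective_sync(tfr, 1, 2, sch$category, "face",
                                n_perm = 99, seed = 63)
  sig <- Filter(function(cl) cl$p <= 0.05 && cl$tail == "upper",
                res$clusters$clusters)
  expect_gte(length(sig), 1)
  big <- sig[[which.max(vapply(sig, `[[`, numeric(1), "mass"))]]
  # the planted 40-Hz bin inside the coupling window is covered
  f40 <- which(tfr$freqs == 40)
  in_win <- tfr$times > 0.4 & tfr$times < 0.9
  expect_gt(mean(big$mask[f40, in_win]), 0.5)
})

test_that("equal coupling for both categories yields no reliable contrast", {
  n_sig <- 0
  for (r in 1:5) {
    sch <- nontargets(generate_schedule(design_spec("ieeg"), seed = 70 + r))
    sch <- trial_table(sch[sch$category %in% c("face", "object"), ][1:80, ])
    ep <- simulate_oscillations(sch, channel_info(c("v1", "fus")),
      carrier_freq_hz = 40,
      coupling = list(coupling_spec(c(1, 2), 40, kappa = 0.8,
                                    window = c(0.3, 1.0))),  # all categories
      noise_sd = 0.3, sfreq = 128, tmin = -0.25, tmax = 1.25, seed = 80 + r)
    tfr <- morlet_tfr(ep, freqs = c(36, 40, 44), n_cycles = function(f) f / 4)
    res <- content_selective_sync(tfr, 1, 2, sch$category, "face",
                                  n_perm = 60, seed = 90 + r)
    ps <- vapply(res$clusters$clusters, `[[`, numeric(1), "p")
    if (length(ps) && any(ps <= 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1)
})

test_that("GED filters recover a planted spatial pattern", {
  sch <- nontargets(generate_schedule(design_spec("ieeg"), seed = 91))
  sch <- trial_table(sch[1:200, ])
  n_ch <- 5
  pattern <- c(3, 2, 1, 0, 0)
  ch <- channel_info(sprintf("g%d", 1:n_ch))
  profs <- lapply(pattern, function(a)
    response_profile(if (a > 0) "sustained" else "none", amplitude = a,
                     selectivity = c(face = 1)))
  ep <- simulate_highgamma(sch, ch, profs, noise_sd = 1, sfreq = 64, seed = 92)
  sig <- which(sch$category == "face")
  ref <- which(sch$category != "face")
  g <- ged_filter(ep, sig, ref, window = c(0.3, 1.0))
  cosine <- abs(sum(g$filter * pattern / sqrt(sum(pattern^2))))
  expect_gt(cosine, 0.9)
  # component variance ratio equals the top generalized eigenvalue
  # (up to the shrinkage regularization on the training covariances)
  expect_gt(g$eigenvalues[1], 1)
  # identical conditions: all generalized eigenvalues ~ 1
  g0 <- ged_filter(ep, sig, sig, window = c(0.3, 1.0), gamma = 0)
  expect_equal(g0$eigenvalues, rep(1, n_ch), tolerance = 1e-6)
})

test_that("GED with gamma = 0 matches a dense generalized-eigensolver oracle", {
  sch <- nontargets(generate_schedule(design_spec("ieeg"), seed = 93))
  sch <- trial_table(sch[1:60, ])
  ep <- noise_epochs(sch, n_channels = 4, sfreq = 50, seed = 94)
  sig <- 1:30; ref <- 31:60
  g <- ged_filter(ep, sig, ref, window = c(0, 1), gamma = 0, z_reject = Inf)
  # oracle: solve(R) %*% S on the same covariances
  covs <- function(idx) {
    tsel <- which(ep$times >= 0 & ep$times <= 1)
    Reduce(`+`, lapply(idx, function(e) {
      x <- matrix(ep$data[e, , tsel], 4, length(tsel))
      x <- x - rowMeans(x)
      tcrossprod(x) / (length(tsel) - 1)
    })) / length(idx)
  }
  s_m <- covs(sig); r_m <- covs(ref)
  eg <- eigen(solve(r_m, s_m))
  expect_equal(sort(g$eigenvalues), sort(Re(eg$values)), tolerance = 1e-8)
  v1 <- Re(eg$vectors[, which.max(Re(eg$values))])
  v1 <- v1 / sqrt(sum(v1^2))
  expect_equal(abs(sum(v1 * g$filter)), 1, tolerance = 1e-8)
})

test_that("trial rejection excludes covariance outliers", {
  sch <- nontargets(generate_schedule(design_spec("ieeg"), seed = 95))
  sch <- trial_table(sch[1:60, ])
  ep <- noise_epochs(sch, n_channels = 3, sfreq = 50, seed = 96)
  ep$data[5, , ] <- ep$data[5, , ] * 50   # artifact trial
  g <- ged_filter(ep, 1:30, 31:60, window = c(0, 1))
  expect_false(5 %in% g$kept_signal)
  expect_gt(length(g$kept_signal), 25)
})
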