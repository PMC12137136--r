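# Shared fixture builders (all fixtures are generated in code).

# a minimal valid trial table with n trials, one pictorial block
tiny_trials <- function(n = 8, duration = NULL, seed = 1) {
  set.seed(seed)
  dur <- if (is.null(duration)) sample(c(0.5, 1.0, 1.5), n, replace = TRUE)
         else rep_len(duration, n)
  trial_table(data.frame(
    trial_id = seq_len(n),
    onset_s = seq_len(n) * 3,
    category = rep_len(c("face", "object"), n),
    identity = rep_len(1:4, n),
    orientation = rep_len(c("front", "left", "right"), n),
    duration_s = dur,
    relevance = "relevant_nontarget",
    block = 1L, run = 1L))
}

# drop targets from a schedule, preserving the trial_table class
nontargets <- function(schedule) {
  out <- schedule[schedule$relevance != "target", ]
  class(out) <- c("trial_table", "data.frame")
  out
}

# epoched pure-noise data for a schedule
noise_epochs <- function(schedule, n_channels = 2, sfreq = 64, noise_sd = 1,
                         seed = 1) {
  ch <- channel_info(sprintf("n%02d", seq_len(n_channels)))
  profs <- replicate(n_channels, response_profile("none"), simplify = FALSE)
  simulate_highgamma(schedule, ch, profs, noise_sd = noise_sd,
                     sfreq = sfreq, seed = seed)
}

# trial-level RSA pattern set with a planted class geometry
rsa_patterns <- function(kind = c("sustained", "onset_offset", "null"),
                         n_stim = 16, n_feat = 10, k_trials = 100,
                         delta = 0.3, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  cls_s <- rep(c("face", "object"), each = n_stim / 2)
  stim <- rep(seq_len(n_stim), each = k_trials)
  cls <- cls_s[stim]
  times <- c(0.4, 0.9, 1.4, 1.9)  # centres of the four test windows
  x <- array(rnorm(n_stim * k_trials * n_feat * 4),
             c(n_stim * k_trials, n_feat, 4))
  if (kind != "null") {
    proto <- matrix(rnorm(2 * n_feat), 2, n_feat)
    wins <- if (kind == "sustained") 1:3 else c(1, 4)
    for (t in wins)
      x[, , t] <- x[, , t] + delta * proto[(cls == "object") + 1, ]
  }
  list(x = x, stimulus = stim, classes = cls, times = times)
}
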