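## Signal simulators with planted, recoverable structure: high-gamma
## envelope profiles (sustained / onset-transient / onset+offset) and
## narrowband oscillations with category-specific cross-channel phase
## coupling.

#' Response profile for a simulated channel
#'
#' The three temporal families mirror the competing theoretical
#' predictions: `sustained` holds a boxcar from `latency_s` to stimulus
#' offset (content maintained for the experienced duration);
#' `onset_transient` is a single pulse of `transient_width_s` after
#' `latency_s`; `onset_offset` adds an ignition-like pulse in the
#' 0.3-0.5-s window after stimulus offset; `none` is pure noise.
#'
#' @param kind `"sustained"`, `"onset_transient"`, `"onset_offset"` or
#'   `"none"`.
#' @param amplitude response amplitude (signal units), >= 0.
#' @param latency_s response latency (default 0.3 s).
#' @param transient_width_s transient pulse width (default 0.2 s, the
#'   geometry of the 0.3-0.5-s ignition window).
#' @param selectivity named numeric vector of per-category gains; `NULL`
#'   (default) means gain 1 for every category, while a supplied map gives
#'   gain 0 to categories it omits.
#' @param identity_gain,orientation_gain modulation depths for identity
#'   (linear in exemplar index, centred) and orientation (side view vs
#'   front).
#' @return list of class `response_profile`.
#' @export
response_profile <- function(kind = c("sustained", "onset_transient",
                                      "onset_offset", "none"),
                             amplitude = 1, latency_s = 0.3,
                             transient_width_s = 0.2,
                             selectivity = NULL,
                             identity_gain = 0, orientation_gain = 0) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0)
  structure(list(kind = kind, amplitude = amplitude, latency_s = latency_s,
                 transient_width_s = transient_width_s,
                 selectivity = selectivity, identity_gain = identity_gain,
                 orientation_gain = orientation_gain),
            class = "response_profile")
}

profile_gain <- function(profile, category, identity, orientation) {
  # a selectivity map gives explicit gains; categories it omits get 0
  g <- if (is.null(profile$selectivity)) 1
       else if (category %in% names(profile$selectivity))
         profile$selectivity[[category]]
       else 0
  g <- g * (1 + profile$identity_gain * (identity - 10.5) / 9.5)
  g * (1 + profile$orientation_gain * as.numeric(orientation != "front"))
}

profile_timecourse <- function(profile, times, duration, gain) {
  amp <- profile$amplitude * gain
  lat <- profile$latency_s
  w <- profile$transient_width_s
  y <- numeric(length(times))
  switch(profile$kind,
    none = y,
    sustained = {
      y[times >= lat & times <= duration] <- amp
      y
    },
    onset_transient = {
      y[times >= lat & times <= lat + w] <- amp
      y
    },
    onset_offset = {
      y[times >= lat & times <= lat + w] <- amp
      y[times >= duration + 0.3 & times <= duration + 0.5] <- amp
      y
    },
    stop("unknown profile kind: ", profile$kind))
}

#' Simulate epoched high-gamma envelopes with planted response profiles
#'
#' Builds an [epoch_array()] directly in epoch space (window `[tmin, tmax]`
#' around stimulus onset): each channel's deterministic response follows
#' its [response_profile()] scaled by its category/identity/orientation
#' gains and the trial's duration, plus additive Gaussian noise. The same
#' seed reproduces the tensor bit-exactly.
#'
#' @param schedule a [trial_table()].
#' @param channels list of `list(info = <1-row channel_info or name>,
#'   profile = <response_profile>)`, or a [channel_info()] whose
#'   `ground_truth_profile` names a kind with a shared `profiles` list.
#' @param profiles list of [response_profile()], one per channel (parallel
#'   to `channels` when `channels` is a [channel_info()]).
#' @param noise_sd Gaussian noise standard deviation.
#' @param sfreq sampling rate in Hz (>= 50).
#' @param tmin,tmax epoch window in seconds.
#' @param seed integer seed.
#' @return an [epoch_array()].
#' @export
simulate_highgamma <- function(schedule, channels, profiles, noise_sd = 1,
                               sfreq = 100, tmin = -1.0, tmax = 2.5,
                               seed = 1) {
  stopifnot(inherits(schedule, "trial_table"), sfreq >= 50,
            inherits(channels, "channel_info"),
            length(profiles) == nrow(channels))
  for (p in profiles) stopifnot(inherits(p, "response_profile"))
  set.seed(seed)
  times <- seq(round(tmin * sfreq), round(tmax * sfreq)) / sfreq
  n_tr <- nrow(schedule); n_ch <- nrow(channels); n_t <- length(times)
  dat <- array(stats::rnorm(n_tr * n_ch * n_t, sd = noise_sd),
               dim = c(n_tr, n_ch, n_t))
  for (ch in seq_len(n_ch)) {
    pr <- profiles[[ch]]
    if (pr$kind == "none") next
    for (e in seq_len(n_tr)) {
      g <- profile_gain(pr, schedule$category[e], schedule$identity[e],
                        schedule$orientation[e])
      dat[e, ch, ] <- dat[e, ch, ] +
        profile_timecourse(pr, times, schedule$duration_s[e], g)
    }
  }
  epoch_array(dat, sfreq, times, schedule, channels)
}

#' Cross-channel phase-coupling specification
#'
#' Ground truth for phase-consistency analyses: within the active window,
#' on trials of the restricted category, the target channel's oscillatory
#' phase equals the source channel's phase plus `phase_lag`, jittered by a
#' von Mises deviate whose mean resultant length equals `kappa` (so
#' `kappa = 1` is a deterministic phase relation and `kappa = 0`
#' independent phases, with expected pairwise phase consistency about
#' `kappa^2`).
#'
#' @param pair integer `c(source, target)` channel indices.
#' @param carrier_freq_hz carrier frequency (must be below Nyquist).
#' @param kappa coupling strength in \[0, 1\].
#' @param category category whose trials are coupled (`NULL` = all).
#' @param window active window `c(t0, t1)` in seconds (`NULL` = whole
#'   epoch).
#' @param phase_lag phase lag in radians.
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(pair, carrier_freq_hz, kappa = 1,
                          category = NULL, window = NULL, phase_lag = 0) {
  stopifnot(length(pair) == 2L, kappa >= 0, kappa <= 1)
  structure(list(pair = as.integer(pair), carrier_freq_hz = carrier_freq_hz,
                 kappa = kappa, category = category, window = window,
                 phase_lag = phase_lag),
            class = "coupling_spec")
}

# concentration of a von Mises distribution with mean resultant length rho
# (A(k) = I1(k)/I0(k) inverted numerically)
vonmises_concentration <- function(rho) {
  if (rho <= 0) return(0)
  if (rho >= 1) return(Inf)
  a <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) a(k) - rho, lower = 1e-8, upper = 1e4,
                 tol = 1e-10)$root
}

# Best-Fisher rejection sampler for von Mises(0, kappa)
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa)) return(numeric(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Simulate epoched narrowband oscillations with planted phase coupling
#'
#' Each channel is a unit sinusoid at its carrier frequency with an
#' independent uniform phase per trial, plus Gaussian noise. For every
#' [coupling_spec()], on trials of the restricted category the target
#' channel's phase within the active window is replaced by the source's
#' phase plus the specified lag and von Mises jitter.
#'
#' @param schedule a [trial_table()].
#' @param channels a [channel_info()].
#' @param carrier_freq_hz per-channel carrier frequencies (recycled).
#' @param coupling list of [coupling_spec()] (may be empty).
#' @param noise_sd Gaussian noise standard deviation.
#' @param sfreq sampling rate in Hz.
#' @param tmin,tmax epoch window in seconds.
#' @param seed integer seed.
#' @return an [epoch_array()] with attribute `"phases"`: the per-trial,
#'   per-channel ground-truth phase matrix (phase of the coupled window
#'   where a coupling applies, base phase otherwise).
#' @export
simulate_oscillations <- function(schedule, channels, carrier_freq_hz = 10,
                                  coupling = list(), noise_sd = 0.1,
                                  sfreq = 200, tmin = -1.0, tmax = 2.5,
                                  seed = 1) {
  stopifnot(inherits(schedule, "trial_table"),
            inherits(channels, "channel_info"))
  n_ch <- nrow(channels)
  carriers <- rep_len(carrier_freq_hz, n_ch)
  if (any(carriers >= sfreq / 2))
    stop("carrier frequency at or above Nyquist (sfreq/2)")
  for (cp in coupling) {
    stopifnot(inherits(cp, "coupling_spec"))
    if (cp$carrier_freq_hz >= sfreq / 2)
      stop("coupling carrier frequency at or above Nyquist")
  }
  set.seed(seed)
  times <- seq(round(tmin * sfreq), round(tmax * sfreq)) / sfreq
  n_tr <- nrow(schedule); n_t <- length(times)
  base_phase <- matrix(stats::runif(n_tr * n_ch, -pi, pi), n_tr, n_ch)
  phase <- base_phase
  dat <- array(stats::rnorm(n_tr * n_ch * n_t, sd = noise_sd),
               dim = c(n_tr, n_ch, n_t))
  # phase field per trial x channel x time; start from base phase
  for (ch in seq_len(n_ch)) {
    osc <- outer(base_phase[, ch], 2 * pi * carriers[ch] * times, `+`)
    dat[, ch, ] <- dat[, ch, ] + sin(osc)
  }
  for (cp in coupling) {
    src <- cp$pair[1]; tgt <- cp$pair[2]
    sel <- rep(TRUE, n_tr)
    if (!is.null(cp$category)) sel <- schedule$category == cp$category
    idx <- which(sel)
    if (!length(idx)) next
    kap <- vonmises_concentration(cp$kappa)
    jit <- rvonmises(length(idx), kap)
    new_phase <- base_phase[idx, src] + cp$phase_lag + jit
    win <- if (is.null(cp$window)) range(times) else cp$window
    tsel <- times >= win[1] & times <= win[2]
    f <- cp$carrier_freq_hz
    repl <- sin(outer(new_phase, 2 * pi * f * times[tsel], `+`))
    base <- sin(outer(base_phase[idx, tgt], 2 * pi * carriers[tgt] * times[tsel], `+`))
    dat[idx, tgt, tsel] <- dat[idx, tgt, tsel] - base + repl
    phase[idx, tgt] <- new_phase
  }
  out <- epoch_array(dat, sfreq, times, schedule, channels)
  attr(out, "phases") <- phase
  out
}
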