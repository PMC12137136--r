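## Design specifications and trial-schedule generation.
##
## The presets reproduce the study designs exactly: MEG = 10 runs x 4
## blocks, 8 non-targets per category per block, 2-6 targets per block,
## 2.0-s fixed trial plus truncated-exponential ITI (mean 0.4 s on
## [0.2, 2.0] s), 1,440 trials total; iEEG = the same with 5 runs (720
## trials); fMRI = 8 runs x 4 blocks, 4 non-targets per category per
## block, 1-3 targets, ITI mean 3 s on [2.5, 10] s, 576 trials.

#' Design specification for a trial schedule
#'
#' @param modality `"meg"`, `"ieeg"` or `"fmri"`, selecting the study
#'   preset; individual fields may be overridden.
#' @param n_runs,blocks_per_run run/block structure.
#' @param nontargets_per_category_per_block exact non-target count per
#'   category in every block.
#' @param target_range integer `c(min, max)` targets per block.
#' @param trial_fixed_s fixed trial length in seconds (stimulus + blank).
#' @param iti_mean_s,iti_range_s mean and support of the truncated
#'   exponential inter-trial jitter.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(modality = c("meg", "ieeg", "fmri"),
                        n_runs = NULL, blocks_per_run = 4,
                        nontargets_per_category_per_block = NULL,
                        target_range = NULL, trial_fixed_s = NULL,
                        iti_mean_s = NULL, iti_range_s = NULL) {
  modality <- match.arg(modality)
  preset <- switch(modality,
    meg = list(n_runs = 10, nt = 8, tr = c(2, 6), fix = 2.0,
               iti_mean = 0.4, iti_range = c(0.2, 2.0)),
    ieeg = list(n_runs = 5, nt = 8, tr = c(2, 6), fix = 2.0,
                iti_mean = 0.4, iti_range = c(0.2, 2.0)),
    fmri = list(n_runs = 8, nt = 4, tr = c(1, 3), fix = 2.0,
                iti_mean = 3.0, iti_range = c(2.5, 10.0)))
  spec <- list(
    modality = modality,
    n_runs = if (is.null(n_runs)) preset$n_runs else n_runs,
    blocks_per_run = blocks_per_run,
    nontargets_per_category_per_block =
      if (is.null(nontargets_per_category_per_block)) preset$nt
      else nontargets_per_category_per_block,
    target_range = if (is.null(target_range)) preset$tr else target_range,
    trial_fixed_s = if (is.null(trial_fixed_s)) preset$fix else trial_fixed_s,
    iti_mean_s = if (is.null(iti_mean_s)) preset$iti_mean else iti_mean_s,
    iti_range_s = if (is.null(iti_range_s)) preset$iti_range else iti_range_s)
  nt <- spec$nontargets_per_category_per_block
  if (nt %% 4 != 0)
    stop("non-target count per category per block must be divisible by 4 ",
         "for the 2:1:1 front:left:right orientation ratio")
  if (spec$blocks_per_run %% 2 != 0)
    stop("blocks_per_run must be even to pair the two tasks within a run")
  class(spec) <- "design_spec"
  spec
}

#' Rate of an exponential truncated to \[lo, hi\] with a given mean
#'
#' Solves numerically for the rate of an exponential distribution whose
#' truncation to `[lo, hi]` has mean `target_mean`.
#'
#' @param target_mean desired mean of the truncated distribution.
#' @param lo,hi truncation bounds.
#' @return the rate (1/scale).
#' @keywords internal
#' @export
truncexp_rate <- function(target_mean, lo, hi) {
  stopifnot(lo < target_mean, target_mean < (lo + hi) / 2 + (hi - lo))
  m <- function(rate) {
    ea <- exp(-rate * lo); eb <- exp(-rate * hi)
    1 / rate + (lo * ea - hi * eb) / (ea - eb)
  }
  stats::uniroot(function(r) m(r) - target_mean,
                 lower = 1e-6, upper = 100, tol = 1e-12)$root
}

#' Sample from a truncated exponential by CDF inversion
#' @keywords internal
rtruncexp <- function(n, rate, lo, hi) {
  u <- stats::runif(n)
  fa <- stats::pexp(lo, rate); fb <- stats::pexp(hi, rate)
  stats::qexp(fa + u * (fb - fa), rate)
}

#' Generate a trial schedule for a design
#'
#' Produces a full randomized schedule honouring the design's exact
#' arithmetic: per block, the stated number of non-targets per category
#' (relevant pair determined by the block's task, alternating and
#' counterbalanced across runs), orientations at a 2:1:1
#' front:left:right ratio within every category, and a target count within
#' `target_range` drawn so that each run's total is exact (blocks get
#' paired counts `x` and `max+min-x`), keeping the grand total at its
#' design value (1,440 MEG / 720 iEEG / 576 fMRI). Durations are dealt
#' maximally evenly (cell counts differ by at most one) within each
#' category x relevance pool; identities cycle through the 20 exemplars per
#' category, excluding a block's target identities from its non-target
#' pool. Onsets accumulate the fixed trial length plus a truncated
#' exponential inter-trial jitter.
#'
#' @param design a [design_spec()].
#' @param seed integer seed; the full schedule is reproducible from it.
#' @return a [trial_table()].
#' @export
generate_schedule <- function(design = design_spec("meg"), seed = 1) {
  stopifnot(inherits(design, "design_spec"))
  set.seed(seed)
  n_runs <- design$n_runs
  bpr <- design$blocks_per_run
  nt <- design$nontargets_per_category_per_block
  trange <- design$target_range

  pict <- c("face", "object"); symb <- c("letter", "false_font")

  # task pairing per block: alternate within run, counterbalance across runs
  block_task <- matrix("", n_runs, bpr)
  for (r in seq_len(n_runs)) {
    first <- if (r %% 2 == 1) "pict" else "symb"
    second <- if (first == "pict") "symb" else "pict"
    block_task[r, ] <- rep(c(first, second), length.out = bpr)
  }

  # target identities: one per relevant category per block, never repeated
  # across blocks (fresh shuffled identity pools per category)
  n_pict_blocks <- sum(block_task == "pict")
  n_symb_blocks <- sum(block_task == "symb")
  draw_targets <- function(n_blocks) {
    # cycle shuffled 1..20 without within-cycle repeats
    ids <- integer(0)
    while (length(ids) < n_blocks) ids <- c(ids, sample.int(20))
    ids[seq_len(n_blocks)]
  }
  tgt_ids <- list(face = draw_targets(n_pict_blocks),
                  object = draw_targets(n_pict_blocks),
                  letter = draw_targets(n_symb_blocks),
                  false_font = draw_targets(n_symb_blocks))

  # target counts: paired draws so each run totals bpr * mean(trange)
  pairsum <- trange[1] + trange[2]
  target_counts <- matrix(0L, n_runs, bpr)
  for (r in seq_len(n_runs)) {
    xs <- sample(seq(trange[1], trange[2]), bpr / 2, replace = TRUE)
    cnt <- as.vector(rbind(xs, pairsum - xs))
    target_counts[r, ] <- sample(cnt)  # order within run randomized
  }

  # duration pools per category x relevance, maximally even
  n_blocks_per_task <- n_pict_blocks  # == n_symb_blocks by construction
  stopifnot(n_pict_blocks == n_symb_blocks)
  dur_pool <- function(n_slots) {
    base <- rep(DURATIONS, each = n_slots %/% 3)
    rem <- n_slots - length(base)
    if (rem > 0) base <- c(base, sample(DURATIONS, rem))
    sample(base)
  }
  # orientation pool per block per category: 2:1:1 exactly
  ori_block <- function(n) sample(rep(ORIENTATIONS, times = c(n / 2, n / 4, n / 4)))

  # identity cycling per category x relevance pool
  id_pool <- function(n_slots) {
    ids <- integer(0)
    while (length(ids) < n_slots) ids <- c(ids, sample.int(20))
    ids[seq_len(n_slots)]
  }

  pools <- list()
  for (cat in CATEGORIES) {
    for (rel in c("relevant_nontarget", "irrelevant")) {
      n_slots <- nt * n_blocks_per_task
      pools[[paste(cat, rel)]] <- list(
        duration = dur_pool(n_slots), identity = id_pool(n_slots), ptr = 0L)
    }
  }
  take <- function(key, n) {
    p <- pools[[key]]
    idx <- p$ptr + seq_len(n)
    pools[[key]]$ptr <<- p$ptr + n
    list(duration = p$duration[idx], identity = p$identity[idx])
  }

  rows <- vector("list", n_runs * bpr)
  blk_counter <- c(pict = 0L, symb = 0L)
  for (r in seq_len(n_runs)) {
    for (b in seq_len(bpr)) {
      task <- block_task[r, b]
      blk_counter[task] <- blk_counter[task] + 1L
      rel_cats <- if (task == "pict") pict else symb
      irr_cats <- if (task == "pict") symb else pict
      bi <- blk_counter[task]
      tgt_id <- c(tgt_ids[[rel_cats[1]]][bi], tgt_ids[[rel_cats[2]]][bi])
      names(tgt_id) <- rel_cats

      blk <- list()
      for (cat in CATEGORIES) {
        rel <- if (cat %in% rel_cats) "relevant_nontarget" else "irrelevant"
        tk <- take(paste(cat, rel), nt)
        ids <- tk$identity
        if (cat %in% rel_cats) {
          # a block's target identity never appears among its non-targets
          clash <- ids == tgt_id[[cat]]
          while (any(clash)) {
            ids[clash] <- (ids[clash] %% 20L) + 1L
            clash <- ids == tgt_id[[cat]]
          }
        }
        blk[[cat]] <- data.frame(
          category = cat, identity = ids, orientation = ori_block(nt),
          duration_s = tk$duration, relevance = rel,
          stringsAsFactors = FALSE)
      }
      # targets: alternate deterministically between the two target identities
      n_tgt <- target_counts[r, b]
      tcat <- rel_cats[(seq_len(n_tgt) - 1L) %% 2L + 1L]
      tgt <- data.frame(
        category = tcat, identity = tgt_id[tcat],
        orientation = ORIENTATIONS[(seq_len(n_tgt) - 1L) %% 3L + 1L],
        duration_s = DURATIONS[(seq_len(n_tgt) - 1L) %% 3L + 1L],
        relevance = "target", stringsAsFactors = FALSE)
      bdf <- rbind(do.call(rbind, blk), tgt)
      bdf <- bdf[sample.int(nrow(bdf)), , drop = FALSE]
      bdf$block <- b
      bdf$run <- r
      rows[[(r - 1L) * bpr + b]] <- bdf
    }
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  iti <- rtruncexp(n, truncexp_rate(design$iti_mean_s,
                                    design$iti_range_s[1],
                                    design$iti_range_s[2]),
                   design$iti_range_s[1], design$iti_range_s[2])
  step <- design$trial_fixed_s + iti
  df$onset_s <- c(0, cumsum(step[-n]))
  df$trial_id <- seq_len(n)
  rownames(df) <- NULL
  trial_table(df)
}

#' Realized trial lengths for a design's timing preset
#'
#' Samples `n` trial lengths (fixed trial duration plus truncated
#' exponential inter-trial jitter) from a design's timing parameters; the
#' mean converges to the design's analytic mean trial length (2.4 s for the
#' MEG/iEEG preset).
#'
#' @param design a [design_spec()].
#' @param n number of trials to sample.
#' @param seed integer seed.
#' @return numeric vector of trial lengths in seconds.
#' @export
sample_trial_lengths <- function(design = design_spec("meg"), n = 10000,
                                 seed = 1) {
  set.seed(seed)
  rate <- truncexp_rate(design$iti_mean_s, design$iti_range_s[1],
                        design$iti_range_s[2])
  design$trial_fixed_s + rtruncexp(n, rate, design$iti_range_s[1],
                                   design$iti_range_s[2])
}
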