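## Trial tables: one row per trial with the five design factors, plus
## BIDS-style events.tsv reading/writing.

CATEGORIES <- c("face", "object", "letter", "false_font")
ORIENTATIONS <- c("front", "left", "right")
DURATIONS <- c(0.5, 1.0, 1.5)
RELEVANCE <- c("target", "relevant_nontarget", "irrelevant")

#' Construct and validate a trial table
#'
#' A trial table holds one row per trial with the experiment's five factors:
#' stimulus category (face/object/letter/false_font), identity (1-20 within
#' category), orientation (front/left/right), duration (0.5/1.0/1.5 s) and
#' task relevance (target/relevant_nontarget/irrelevant), plus block, run
#' and onset in seconds from recording start.
#'
#' Blocks pair tasks: in face-object blocks the pictorial categories are
#' relevant and the symbolic ones irrelevant, and vice versa; relevance must
#' be consistent with the block's pairing, and onsets must be strictly
#' increasing.
#'
#' @param df data.frame with columns `trial_id`, `onset_s`, `category`,
#'   `identity`, `orientation`, `duration_s`, `relevance`, `block`, `run`.
#' @return the validated data.frame with class `trial_table`.
#' @export
trial_table <- function(df) {
  req <- c("trial_id", "onset_s", "category", "identity", "orientation",
           "duration_s", "relevance", "block", "run")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$category <- as.character(df$category)
  df$orientation <- as.character(df$orientation)
  df$relevance <- as.character(df$relevance)

  bad_dur <- which(!vapply(df$duration_s,
                           function(d) any(abs(d - DURATIONS) < 1e-9),
                           logical(1)))
  if (length(bad_dur)) {
    stop(sprintf("invalid duration_s (must be one of 0.5, 1.0, 1.5) for trial_id: %s",
                 paste(df$trial_id[bad_dur], collapse = ", ")))
  }
  if (!all(df$category %in% CATEGORIES))
    stop("invalid category value(s)")
  if (!all(df$orientation %in% ORIENTATIONS))
    stop("invalid orientation value(s)")
  if (!all(df$relevance %in% RELEVANCE))
    stop("invalid relevance value(s)")
  if (!all(df$identity %in% 1:20))
    stop("identity must be an integer in 1..20")
  if (is.unsorted(df$onset_s, strictly = TRUE))
    stop("onsets must be strictly increasing")

  # relevance consistent with the block's task pairing
  pict <- c("face", "object")
  for (b in unique(paste(df$run, df$block))) {
    sel <- paste(df$run, df$block) == b
    rel_cats <- unique(df$category[sel & df$relevance != "irrelevant"])
    irr_cats <- unique(df$category[sel & df$relevance == "irrelevant"])
    if (length(rel_cats) && length(irr_cats)) {
      rel_pict <- all(rel_cats %in% pict)
      if (rel_pict && any(irr_cats %in% pict) ||
          !rel_pict && any(!(irr_cats %in% pict)))
        stop("relevance inconsistent with block task pairing in run/block ", b)
    }
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read a BIDS-style events.tsv into a trial table
#'
#' Expects a tab-separated file with `onset` and `duration` columns (both in
#' seconds) plus the factor columns `category`, `identity`, `orientation`,
#' `relevance`, `block`, `run` and `trial_id`. Round-trips with
#' [write_events()].
#'
#' @param path path to the events.tsv file.
#' @return a [trial_table()].
#' @examples
#' f <- system.file("extdata", "example_events.tsv", package = "sustig")
#' head(load_events(f))
#' @export
load_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("onset", "duration", "category", "identity", "orientation",
           "relevance", "block", "run", "trial_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("events file format error: missing column(s) ",
         paste(miss, collapse = ", "))
  trial_table(data.frame(
    trial_id = df$trial_id, onset_s = df$onset, category = df$category,
    identity = df$identity, orientation = df$orientation,
    duration_s = df$duration, relevance = df$relevance,
    block = df$block, run = df$run))
}

#' Write a trial table as a BIDS-style events.tsv
#'
#' @param trials a [trial_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  out <- data.frame(
    onset = trials$onset_s, duration = trials$duration_s,
    category = trials$category, identity = trials$identity,
    orientation = trials$orientation, relevance = trials$relevance,
    block = trials$block, run = trials$run, trial_id = trials$trial_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Channel metadata table
#'
#' @param name unique channel names.
#' @param roi one of `posterior`, `prefrontal`, `v1v2`, `other` per channel.
#' @param ground_truth_profile optional planted profile labels (synthetic
#'   channels only).
#' @return data.frame with class `channel_info`.
#' @export
channel_info <- function(name, roi = "other", ground_truth_profile = NA) {
  stopifnot(!anyDuplicated(name))
  roi <- rep_len(roi, length(name))
  stopifnot(all(roi %in% c("posterior", "prefrontal", "v1v2", "other")))
  df <- data.frame(name = as.character(name), roi = roi,
                   ground_truth_profile = rep_len(ground_truth_profile,
                                                  length(name)),
                   stringsAsFactors = FALSE)
  class(df) <- c("channel_info", "data.frame")
  df
}
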