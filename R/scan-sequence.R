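#' Generate scanner trial sequences
#'
#' Builds one event-related trial sequence per run. Each run presents all
#' scenes exactly once, with the two presentation set halves shown in
#' contiguous half-blocks (pairmates therefore never co-occur within a half),
#' null-fixation trials split into lead-in, lead-out and randomly interleaved
#' positions, and a fixed count of uniformly sampled red-cross target flags
#' (`round(target_rate * trials_per_run)`). Half-block order alternates
#' AB/BA across runs; the starting order is decided by the seed. Trial orders
#' are re-randomized for every run.
#'
#' @param stimset a `stimulus_set`
#' @param spec the matching [design_spec()]
#' @return a `trial_sequence`: data frame with columns `run`, `onset`,
#'   `duration`, `trial_type` ("scene"/"null"), `stimulus_id` (NA for nulls)
#'   and `target` (0/1 flag)
#' @export
make_scan_sequence <- function(stimset, spec = attr(stimset, "spec")) {
  validate_stimulus_set(stimset)
  validate_design_spec(spec)
  n_scene <- nrow(stimset)
  n_null <- spec$n_null_interleaved + spec$n_null_lead_in +
    spec$n_null_lead_out
  n_trials <- n_scene + n_null
  n_target <- round(spec$target_rate * n_trials)
  if (spec$target_rate > 0 && n_target == 0L)
    stop("target_rate > 0 but target count rounds to 0 for ", n_trials,
         " trials per run", call. = FALSE)
  if (spec$n_null_interleaved %% 2L != 0L)
    stop("n_null_interleaved must be even to split across half-blocks",
         call. = FALSE)
  with_substream(spec$seed, "sequence", {
    first_half <- sample(c("A", "B"), 1L)
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      halves <- if ((r %% 2L) == 1L) c(first_half,
                                       setdiff(c("A", "B"), first_half))
      else c(setdiff(c("A", "B"), first_half), first_half)
      per_half_null <- spec$n_null_interleaved %/% 2L
      kinds <- character(0)
      ids <- character(0)
      for (h in halves) {
        sc <- sample(stimset$scene[stimset$set_half == h])
        slot <- sample(length(sc) + per_half_null)
        half_kind <- rep("null", length(sc) + per_half_null)
        half_id <- rep(NA_character_, length(half_kind))
        scene_slots <- sort(slot[seq_along(sc)])
        half_kind[scene_slots] <- "scene"
        half_id[scene_slots] <- sc
        kinds <- c(kinds, half_kind)
        ids <- c(ids, half_id)
      }
      kinds <- c(rep("null", spec$n_null_lead_in), kinds,
                 rep("null", spec$n_null_lead_out))
      ids <- c(rep(NA_character_, spec$n_null_lead_in), ids,
               rep(NA_character_, spec$n_null_lead_out))
      target <- integer(length(kinds))
      target[sample(length(kinds), n_target)] <- 1L
      data.frame(run = r,
                 onset = (seq_along(kinds) - 1) * spec$trial_duration,
                 duration = ifelse(kinds == "scene", spec$stim_duration, 0),
                 trial_type = kinds,
                 stimulus_id = ids,
                 target = target,
                 stringsAsFactors = FALSE)
    })
    structure(do.call(rbind, runs), class = c("trial_sequence", "data.frame"),
              spec = spec)
  })
}

#' Validate trial-sequence invariants
#'
#' Each run holds every scene exactly once and the specified null counts with
#' correct lead-in/lead-out placement; set halves occupy contiguous
#' half-blocks (no pairmate within a half); onsets are multiples of the trial
#' duration; the target count per run is exactly
#' `round(target_rate * trials)`.
#'
#' @param sequence a `trial_sequence`
#' @param stimset the `stimulus_set` it was generated from
#' @return invisibly `TRUE`; stops on violation
#' @export
validate_trial_sequence <- function(sequence, stimset) {
  spec <- attr(sequence, "spec")
  fail <- function(...) stop("invalid trial_sequence: ", ..., call. = FALSE)
  half_of <- setNames(stimset$set_half, stimset$scene)
  for (r in unique(sequence$run)) {
    tr <- sequence[sequence$run == r, ]
    sc <- tr$stimulus_id[tr$trial_type == "scene"]
    if (length(sc) != nrow(stimset) || anyDuplicated(sc))
      fail("run ", r, " does not show every scene exactly once")
    if (sum(tr$trial_type == "null") != spec$n_null_interleaved +
        spec$n_null_lead_in + spec$n_null_lead_out)
      fail("run ", r, " has the wrong null count")
    n_lead <- spec$n_null_lead_in
    if (any(tr$trial_type[seq_len(n_lead)] != "null") ||
        any(tr$trial_type[nrow(tr) - seq_len(spec$n_null_lead_out) + 1L] !=
            "null"))
      fail("run ", r, " lead-in/lead-out trials are not null")
    halves <- half_of[sc]
    if (any(halves != rep(halves[c(1, length(halves))],
                          each = length(halves) / 2)))
      fail("run ", r, " set halves are not contiguous half-blocks")
    if (any(abs(tr$onset / spec$trial_duration -
                round(tr$onset / spec$trial_duration)) > 1e-9))
      fail("run ", r, " onsets are not multiples of trial_duration")
    if (sum(tr$target) != round(spec$target_rate * nrow(tr)))
      fail("run ", r, " target count mismatch")
  }
  invisible(TRUE)
}

#' Write / read a trial sequence as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`, `stimulus_id`, `run`, `target`;
#' missing stimulus ids are written as `n/a` following the BIDS convention.
#' The write/read round trip reproduces the sequence exactly.
#'
#' @param sequence a `trial_sequence`
#' @param path output TSV path
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a `trial_sequence`
#' @export
write_events_tsv <- function(sequence, path) {
  out <- data.frame(onset = sequence$onset,
                    duration = sequence$duration,
                    trial_type = sequence$trial_type,
                    stimulus_id = ifelse(is.na(sequence$stimulus_id), "n/a",
                                         sequence$stimulus_id),
                    run = sequence$run,
                    target = sequence$target)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(onset = "numeric", duration = "numeric",
                                   trial_type = "character",
                                   stimulus_id = "character",
                                   run = "integer", target = "integer"))
  tab$stimulus_id[tab$stimulus_id == "n/a"] <- NA_character_
  tab <- tab[, c("run", "onset", "duration", "trial_type", "stimulus_id",
                 "target")]
  structure(tab, class = c("trial_sequence", "data.frame"))
}
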