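#' Experimental design specification
#'
#' Parameters of the pairmate scanning paradigm: 36 similar-scene pairs, 12
#' per learning condition (No Face / Different Face / Same Face), balanced
#' over indoor/outdoor subcategories; scanner runs of 72 scene trials plus
#' 24 null-fixation trials (18 interleaved, 3 lead-in, 3 lead-out) at 4 s
#' per trial, TR 2 s, with infrequent red-cross target trials (8.33%).
#'
#' @param n_pairs_total total number of scene pairs (default 36)
#' @param n_pairs_per_condition pairs per learning condition (default 12)
#' @param conditions learning condition labels
#' @param subcategories scene subcategory labels, balanced within condition
#' @param n_runs number of scanner runs (8-10 in the paradigm; default 8)
#' @param trial_duration trial length in seconds
#' @param stim_duration stimulus-on time in seconds
#' @param tr repetition time in seconds
#' @param n_null_interleaved,n_null_lead_in,n_null_lead_out null-trial counts
#' @param target_rate fraction of all trials flagged as red-cross targets
#' @param seed integer seed; all design randomness derives from it
#' @return an object of class `design_spec`
#' @export
design_spec <- function(n_pairs_total = 36L,
                        n_pairs_per_condition = 12L,
                        conditions = c("NoFace", "DifferentFace", "SameFace"),
                        subcategories = c("indoor", "outdoor"),
                        n_runs = 8L,
                        trial_duration = 4.0,
                        stim_duration = 0.5,
                        tr = 2.0,
                        n_null_interleaved = 18L,
                        n_null_lead_in = 3L,
                        n_null_lead_out = 3L,
                        target_rate = 1 / 12,
                        seed = 1L) {
  spec <- structure(
    list(n_pairs_total = as.integer(n_pairs_total),
         n_pairs_per_condition = as.integer(n_pairs_per_condition),
         conditions = as.character(conditions),
         subcategories = as.character(subcategories),
         n_runs = as.integer(n_runs),
         trial_duration = trial_duration,
         stim_duration = stim_duration,
         tr = tr,
         n_null_interleaved = as.integer(n_null_interleaved),
         n_null_lead_in = as.integer(n_null_lead_in),
         n_null_lead_out = as.integer(n_null_lead_out),
         target_rate = target_rate,
         seed = as.integer(seed)),
    class = "design_spec")
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  if (spec$n_pairs_per_condition * length(spec$conditions) !=
      spec$n_pairs_total)
    stop("invalid design_spec: n_pairs_per_condition * number of conditions",
         " must equal n_pairs_total", call. = FALSE)
  if (spec$n_pairs_per_condition %% length(spec$subcategories) != 0L)
    stop("invalid design_spec: pairs per condition cannot be balanced over ",
         length(spec$subcategories), " subcategories", call. = FALSE)
  if (spec$target_rate < 0 || spec$target_rate >= 0.5)
    stop("invalid design_spec: target_rate must lie in [0, 0.5)",
         call. = FALSE)
  if (anyDuplicated(spec$conditions) || anyDuplicated(spec$subcategories))
    stop("invalid design_spec: duplicated condition or subcategory labels",
         call. = FALSE)
  if (spec$trial_duration <= 0 || spec$tr <= 0)
    stop("invalid design_spec: trial_duration and tr must be positive",
         call. = FALSE)
  invisible(spec)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design_spec:", x$n_pairs_total, "pairs (",
      x$n_pairs_per_condition, "per condition:",
      paste(x$conditions, collapse = ", "), ")\n")
  cat("  runs:", x$n_runs, " trial:", x$trial_duration, "s  TR:", x$tr,
      "s  target rate:", round(x$target_rate, 4), "\n")
  invisible(x)
}
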