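#' Generative truth for the behaviour model
#'
#' Log-odds of a pair being retrieved correctly (vs an interference error)
#' on a given scene-object test repetition:
#' `intercept + slope * score + condition effect + repetition_effect * rep +
#'  interaction * score * rep + subject intercept`.
#' Defaults are generative analogues of the reported group-level effects: a
#' negative score slope (lower representational overlap protects from
#' interference), a Different Face advantage, accuracy increasing over test
#' repetitions, and a negative score-by-repetition interaction.
#'
#' @param intercept baseline log-odds of a correct pair at repetition 1
#' @param slope_score effect of the scene pair difference score
#' @param condition_effects named log-odds offsets per condition
#' @param repetition_effect per-repetition log-odds increment (repetition
#'   is coded 0, 1, 2)
#' @param interaction score-by-repetition interaction
#' @param subject_sd sd of the Gaussian per-subject random intercept
#' @param other_rate fixed rate of "other" (nonpairmate-foil) outcomes,
#'   generated independently of the score and excluded downstream
#' @return a `behavior_model_truth` object
#' @export
behavior_model_truth <- function(intercept = 0.7,
                                 slope_score = -2.0,
                                 condition_effects = c(DifferentFace = 1.12,
                                                       SameFace = 0),
                                 repetition_effect = 1.2,
                                 interaction = 0,
                                 subject_sd = 0.5,
                                 other_rate = 0.04) {
  if (subject_sd < 0) stop("subject_sd must be >= 0", call. = FALSE)
  if (other_rate < 0 || other_rate >= 1)
    stop("other_rate must lie in [0, 1)", call. = FALSE)
  structure(list(intercept = intercept, slope_score = slope_score,
                 condition_effects = condition_effects,
                 repetition_effect = repetition_effect,
                 interaction = interaction, subject_sd = subject_sd,
                 other_rate = other_rate),
            class = "behavior_model_truth")
}

#' Simulate pair-level memory outcomes from difference scores
#'
#' Each (subject, pair, repetition) cell is drawn "correct" vs
#' "interference" with the log-odds given by [behavior_model_truth()]; a
#' small fixed fraction of cells is relabelled "other" (both pairmates
#' matched to nonpairmate foils), mirroring trials excluded from analysis.
#'
#' @param truth a [behavior_model_truth()]
#' @param pair_scores a `pair_score_table`; when it covers several subjects
#'   the `subject` column links scores to simulated subjects, otherwise the
#'   same scores are reused for every simulated subject
#' @param n_subjects number of subjects (ignored when `pair_scores` already
#'   carries subjects)
#' @param n_repetitions test repetitions (default 3)
#' @param seed integer seed
#' @return a `behavior_table` data frame: `subject`, `pair`, `condition`,
#'   `repetition`, `outcome` ("correct"/"interference"/"other"),
#'   `n_interference_errors`
#' @export
simulate_behavior <- function(truth, pair_scores, n_subjects = 18L,
                              n_repetitions = 3L, seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (!all(is.finite(pair_scores$difference_score)))
    stop("difference scores must be finite", call. = FALSE)
  has_subjects <- !all(is.na(pair_scores$subject))
  subjects <- if (has_subjects) unique(pair_scores$subject)
  else seq_len(n_subjects)
  with_substream(seed, "behaviour", {
    u <- setNames(rnorm(length(subjects), sd = truth$subject_sd),
                  as.character(subjects))
    rows <- list()
    for (s in subjects) {
      sc <- if (has_subjects)
        pair_scores[pair_scores$subject == s, , drop = FALSE]
      else pair_scores
      for (rep_i in seq_len(n_repetitions)) {
        ce <- truth$condition_effects[sc$condition]
        ce[is.na(ce)] <- 0
        eta <- truth$intercept +
          truth$slope_score * sc$difference_score +
          as.numeric(ce) +
          truth$repetition_effect * (rep_i - 1) +
          truth$interaction * sc$difference_score * (rep_i - 1) +
          u[[as.character(s)]]
        correct <- rbinom(nrow(sc), 1L, plogis(eta))
        other <- runif(nrow(sc)) < truth$other_rate
        n_err <- ifelse(correct == 1L, 0L, sample(1:2, nrow(sc),
                                                  replace = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, pair = sc$pair, condition = sc$condition,
          repetition = rep_i,
          outcome = ifelse(other, "other",
                           ifelse(correct == 1L, "correct", "interference")),
          n_interference_errors = ifelse(other, 0L, n_err),
          stringsAsFactors = FALSE)
      }
    }
    structure(do.call(rbind, rows),
              class = c("behavior_table", "data.frame"))
  })
}
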