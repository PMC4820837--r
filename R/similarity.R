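#' Fisher z-transform of a Pearson correlation
#'
#' `z = arctanh(r)` after clipping `|r|` to `1 - 1e-7`, so that degenerate
#' (noiseless) correlations of exactly +/-1 stay finite. Odd and strictly
#' increasing on `[-1, 1]`.
#'
#' @param r correlation value(s) in `[-1, 1]`
#' @param clip clipping bound applied to `|r|` before `arctanh`
#' @return Fisher z value(s)
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  atanh(pmax(pmin(r, clip), -clip))
}

#' Cross-set similarity matrix of Fisher-z correlations
#'
#' Correlates, over ROI voxels, the pattern of each set-A scene with the
#' pattern of each set-B scene: entry (i, j) is the Fisher-z Pearson
#' correlation between the set-A scene of pair i and the set-B scene of
#' pair j. No within-set correlation is ever computed (pairmates live in
#' opposite halves of every run, so only across-set values are temporally
#' unconfounded). The diagonal holds pairmate similarities; cells that pair
#' scenes from different conditions are flagged invalid and excluded from
#' all downstream averages.
#'
#' @param patterns a `pattern_estimates` (its `tmap` is used), a
#'   `ground_truth_patterns`, or a bare scene x voxel matrix with scene row
#'   names
#' @param stimset the `stimulus_set` describing pairs/conditions/halves
#' @param roi optional logical `roi_mask` over voxels (default: all)
#' @param use "tmap" or "beta" when `patterns` is a `pattern_estimates`
#' @param zscore z-score each pattern across voxels before correlating
#'   (off by default; Pearson correlation already centres and scales)
#' @return a `similarity_matrix`: list with `z` (n_pairs x n_pairs),
#'   `valid` mask, `pairs`, `condition`
#' @export
build_similarity_matrix <- function(patterns, stimset, roi = NULL,
                                    use = c("tmap", "beta"),
                                    zscore = FALSE) {
  use <- match.arg(use)
  mat <- if (inherits(patterns, "pattern_estimates")) patterns[[use]]
  else if (inherits(patterns, "ground_truth_patterns")) patterns$pattern
  else patterns
  if (is.null(rownames(mat)))
    stop("patterns must carry scene row names", call. = FALSE)
  if (!all(stimset$scene %in% rownames(mat)))
    stop("every scene needs a pattern estimate", call. = FALSE)
  if (!is.null(roi)) mat <- mat[, roi, drop = FALSE]
  if (ncol(mat) < 2L)
    stop("need at least 2 voxels to correlate patterns", call. = FALSE)
  sds <- apply(mat[stimset$scene, , drop = FALSE], 1, sd)
  if (any(sds == 0))
    stop("zero-variance pattern for scene(s): ",
         paste(stimset$scene[sds == 0], collapse = ", "),
         "; correlation undefined", call. = FALSE)
  if (zscore) mat <- t(scale(t(mat)))
  prs <- pairs_of(stimset)
  prs <- prs[order(prs$pair), ]
  a_scenes <- half_scenes(stimset, "A")
  b_scenes <- half_scenes(stimset, "B")
  r <- cor(t(mat[a_scenes, , drop = FALSE]), t(mat[b_scenes, , drop = FALSE]))
  z <- fisher_z(r)
  dimnames(z) <- list(prs$pair, prs$pair)
  valid <- outer(prs$condition, prs$condition, `==`)
  dimnames(valid) <- dimnames(z)
  structure(list(z = z, valid = valid, pairs = prs$pair,
                 condition = setNames(prs$condition, prs$pair)),
            class = "similarity_matrix")
}

#' Scene pair difference scores
#'
#' For each pair, the pairmate similarity (diagonal cell) minus the mean
#' similarity of each pairmate to all other same-condition nonpairmate
#' scenes (the valid off-diagonal cells of that pair's row and column,
#' averaged jointly; with 12 pairs per condition this averages 2 x 11 = 22
#' cells).
#'
#' @param simmat a `similarity_matrix`
#' @param subject optional subject id carried into the table
#' @param roi optional ROI label carried into the table
#' @return a `pair_score_table` data frame: `pair`, `condition`,
#'   `pairmate_z`, `mean_nonpairmate_z`, `difference_score`, `subject`,
#'   `roi`
#' @export
pair_difference_scores <- function(simmat, subject = NA, roi = NA) {
  z <- simmat$z
  valid <- simmat$valid
  n <- nrow(z)
  out <- lapply(seq_len(n), function(i) {
    same <- which(valid[i, ] & seq_len(n) != i)
    if (length(same) == 0L)
      stop("pair ", simmat$pairs[i], " has no same-condition nonpairmates",
           call. = FALSE)
    np <- mean(c(z[i, same], z[same, i]))
    data.frame(pair = simmat$pairs[i],
               condition = simmat$condition[[i]],
               pairmate_z = z[i, i],
               mean_nonpairmate_z = np,
               difference_score = z[i, i] - np,
               subject = subject, roi = roi,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("pair_score_table", "data.frame"))
}

#' Condition summaries of pair scores
#'
#' Subject-level means are taken first, then the across-subject mean and
#' s.e.m. per condition, for the difference score and its two components.
#'
#' @param table a `pair_score_table` (possibly several subjects)
#' @return data frame with one row per condition: means and s.e.m. of
#'   `difference_score`, `pairmate_z`, `mean_nonpairmate_z`, plus
#'   `n_subjects`
#' @export
condition_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty pair score table", call. = FALSE)
  measures <- c("difference_score", "pairmate_z", "mean_nonpairmate_z")
  subj <- aggregate(table[measures],
                    by = list(subject = table$subject,
                              condition = table$condition), FUN = mean)
  out <- lapply(split(subj, subj$condition), function(d) {
    n <- nrow(d)
    row <- data.frame(condition = d$condition[1], n_subjects = n)
    for (m in measures) {
      row[[paste0("mean_", m)]] <- mean(d[[m]])
      row[[paste0("sem_", m)]] <- if (n > 1) sd(d[[m]]) / sqrt(n) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
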