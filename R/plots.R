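#' Bar plot of condition-wise difference scores (mean +/- s.e.m.)
#'
#' @param summary one ROI's [condition_summary()] table
#' @param main plot title
#' @return invisibly, the bar midpoints
#' @export
plot_condition_summary <- function(summary, main = "") {
  m <- summary$mean_difference_score
  s <- summary$sem_difference_score
  ylim <- range(0, m - 1.5 * s, m + 1.5 * s)
  mid <- graphics::barplot(m, names.arg = summary$condition, ylim = ylim,
                           ylab = "scene pair difference score (z)",
                           main = main, border = NA, col = "grey60")
  graphics::arrows(mid, m - s, mid, m + s, angle = 90, code = 3,
                   length = 0.05)
  graphics::abline(h = 0)
  invisible(mid)
}

#' Scatter of an MDS embedding with pairmates joined
#'
#' @param embedding an `mds_embedding`
#' @param main plot title
#' @return invisibly `NULL`
#' @export
plot_mds <- function(embedding, main = "") {
  pts <- embedding$points
  np <- length(embedding$pairs)
  graphics::plot(pts, asp = 1, pch = 19,
                 col = rep(seq_len(np), 2), xlab = "dim 1", ylab = "dim 2",
                 main = main)
  graphics::segments(pts[seq_len(np), 1], pts[seq_len(np), 2],
                     pts[np + seq_len(np), 1], pts[np + seq_len(np), 2],
                     col = "grey70")
  invisible(NULL)
}

#' Fitted logistic curves of accuracy against difference score
#'
#' @param joined behaviour rows joined with `difference_score`
#' @param main plot title
#' @return invisibly `NULL`
#' @export
plot_logistic_fit <- function(joined, main = "") {
  d <- joined[joined$outcome != "other", ]
  y <- as.integer(d$outcome == "correct")
  graphics::plot(d$difference_score, jitter(y, amount = 0.03), pch = 16,
                 cex = 0.5, col = "grey50",
                 xlab = "scene pair difference score (z)",
                 ylab = "P(correct)", main = main)
  fit <- stats::glm(y ~ difference_score, binomial(), data = d)
  xs <- seq(min(d$difference_score), max(d$difference_score),
            length.out = 100)
  graphics::lines(xs, stats::predict(fit,
                                     data.frame(difference_score = xs),
                                     type = "response"), lwd = 2)
  invisible(NULL)
}
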