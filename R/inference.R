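#' Mixed-effects logistic regression of memory outcomes
#'
#' Fits a logistic model of correct-vs-interference outcomes with Gaussian
#' random effects by maximum likelihood (Laplace approximation, via lme4).
#' `random = "maximal"` requests per-subject random slopes for all
#' within-subject fixed terms plus the intercept; if that model fails to
#' converge the fit falls back down a documented ladder (maximal ->
#' intercept-only) and records the simplification. `random = "none"` fits a
#' plain logistic regression (used, e.g., when the generative truth has no
#' subject variance).
#'
#' Rows with outcome "other" are excluded before fitting (pairs whose only
#' errors were nonpairmate-foil choices are not informative about
#' interference).
#'
#' @param data a `behavior_table` joined with its pair scores (needs
#'   `outcome`, `subject`, plus every term in `fixed`)
#' @param fixed character vector of fixed-effect terms; interactions may be
#'   written "a:b"
#' @param random "maximal", "intercept" or "none"
#' @param response column holding the outcome (default "outcome";
#'   "correct" is coded 1, "interference" 0)
#' @return a `glmm_fit`: coefficient table, random-effect variances,
#'   log-likelihood, parameter count, convergence info, the underlying
#'   model object, and the random structure actually used
#' @export
fit_mixed_logistic <- function(data,
                               fixed = c("difference_score", "condition",
                                         "repetition"),
                               random = c("maximal", "intercept", "none"),
                               response = "outcome") {
  random <- match.arg(random)
  data <- data[data[[response]] != "other", , drop = FALSE]
  y <- as.integer(data[[response]] == "correct")
  if (length(unique(y)) < 2L)
    stop("response has a single class; nothing to model", call. = FALSE)
  if (random != "none" && length(unique(data$subject)) < 2L)
    stop("need >= 2 subjects for random effects", call. = FALSE)
  df <- data
  df$.y <- y
  fixed_part <- paste(fixed, collapse = " + ")
  fit_one <- function(structure_name) {
    form <- switch(structure_name,
      none = as.formula(paste(".y ~", fixed_part)),
      intercept = as.formula(paste(".y ~", fixed_part, "+ (1 | subject)")),
      maximal = {
        # random slopes for the numeric/within-subject main-effect terms
        slopes <- setdiff(fixed, grep(":", fixed, value = TRUE))
        as.formula(paste(".y ~", fixed_part, "+ (1 +",
                         paste(slopes, collapse = " + "), "| subject)"))
      })
    if (structure_name == "none") # glm warns on its way to separation;
      return(list(model = suppressWarnings(stats::glm(form, binomial(),
                                                      data = df)),
                  ok = TRUE, structure = "none")) # we diagnose it below
    m <- suppressMessages(suppressWarnings(
      lme4::glmer(form, data = df, family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE))))
    ok <- length(m@optinfo$conv$lme4$messages) == 0L &&
      m@optinfo$conv$opt == 0
    list(model = m, ok = ok, structure = structure_name)
  }
  ladder <- switch(random, none = "none", intercept = "intercept",
                   maximal = c("maximal", "intercept"))
  fit <- NULL
  for (s in ladder) {
    fit <- tryCatch(fit_one(s), error = function(e) NULL)
    if (!is.null(fit) && fit$ok) break
  }
  if (is.null(fit))
    stop("mixed logistic model could not be fitted", call. = FALSE)
  m <- fit$model
  is_glmm <- inherits(m, "merMod")
  cf <- if (is_glmm) summary(m)$coefficients else summary(m)$coefficients
  coef_tab <- data.frame(term = rownames(cf), estimate = cf[, 1],
                         se = cf[, 2], z = cf[, 3],
                         row.names = NULL, stringsAsFactors = FALSE)
  # separation guard: deviance collapse with runaway coefficients
  mu <- fitted(m)
  if (max(abs(coef_tab$estimate)) > 15 &&
      all(abs(y - mu) < 1e-6))
    stop("complete separation detected: fitted probabilities are 0/1 and ",
         "coefficients diverge", call. = FALSE)
  ll <- as.numeric(logLik(m))
  npar <- attr(logLik(m), "df")
  re_var <- if (is_glmm)
    unlist(lapply(lme4::VarCorr(m), function(v) diag(v))) else numeric(0)
  structure(list(coefficients = coef_tab,
                 ranef_var = re_var,
                 logLik = ll, npar = npar,
                 n = length(y),
                 converged = fit$ok,
                 random_structure = fit$structure,
                 requested_structure = random,
                 fixed = fixed,
                 model = m),
            class = "glmm_fit")
}

#' Wald confidence interval for one fixed-effect term
#'
#' @param fit a `glmm_fit`
#' @param term coefficient name
#' @param level confidence level
#' @return length-2 numeric (lower, upper)
#' @export
fixef_ci <- function(fit, term, level = 0.95) {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) stop("unknown term: ", term, call. = FALSE)
  zq <- qnorm(1 - (1 - level) / 2)
  c(row$estimate - zq * row$se, row$estimate + zq * row$se)
}

#' Likelihood-ratio test of nested fits
#'
#' `chi^2 = 2 (ll_full - ll_nested)` with degrees of freedom equal to the
#' parameter-count difference; p from the upper chi-squared tail. The
#' nested model's fixed terms must be a subset of the full model's, fitted
#' to the same observations.
#'
#' @param full,nested `glmm_fit` objects
#' @return a `test_result`: statistic, df, p, method
#' @export
lrt <- function(full, nested) {
  if (!all(nested$fixed %in% full$fixed))
    stop("models are not nested: nested fixed terms must be a subset of ",
         "the full model's", call. = FALSE)
  if (full$n != nested$n)
    stop("models were fitted to different numbers of observations",
         call. = FALSE)
  stat <- 2 * (full$logLik - nested$logLik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  df <- full$npar - nested$npar
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1
  structure(list(statistic = stat, df = df, p = p,
                 method = "likelihood ratio test"),
            class = "test_result")
}

#' Repeated-measures tests on subject-level scores
#'
#' Dispatches on the number of within-subject levels: a two-tailed paired t
#' (2 levels), a one-way repeated-measures ANOVA (>= 3 levels), a one-sample
#' t against 0 (a single level), with Wilcoxon signed-rank and Friedman
#' nonparametric counterparts. With `test = "auto"`, Shapiro-Wilk screening
#' is advisory: when normality of the paired differences (or per-cell
#' scores) is rejected at alpha = 0.05 the nonparametric counterpart is
#' used and reported.
#'
#' @param scores a `pair_score_table` (or any data frame with `subject`,
#'   a factor column, and `difference_score`)
#' @param factor name of the within-subject factor column
#' @param measure measured column (default "difference_score")
#' @param test "auto", "paired_t", "rm_anova", "wilcoxon", "friedman" or
#'   "one_sample_t"
#' @param mu null value for the one-sample test
#' @return a `test_result`: statistic, df, p, method, plus the Shapiro p
#'   when screening ran
#' @export
paired_tests <- function(scores, factor = "condition",
                         measure = "difference_score",
                         test = c("auto", "paired_t", "rm_anova", "wilcoxon",
                                  "friedman", "one_sample_t"),
                         mu = 0) {
  test <- match.arg(test)
  agg <- aggregate(scores[[measure]],
                   by = list(subject = scores$subject,
                             level = scores[[factor]]), FUN = mean)
  wide <- unstack_scores(agg)
  n <- nrow(wide)
  k <- ncol(wide)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  shapiro_p <- NA_real_
  if (test == "auto") {
    if (k == 1L) test <- "one_sample_t"
    else if (k == 2L) {
      shapiro_p <- shapiro.test(wide[, 1] - wide[, 2])$p.value
      test <- if (shapiro_p < 0.05) "wilcoxon" else "paired_t"
    } else {
      shapiro_p <- min(apply(wide, 2, function(x) shapiro.test(x)$p.value))
      test <- if (shapiro_p < 0.05) "friedman" else "rm_anova"
    }
  }
  res <- switch(test,
    one_sample_t = {
      ht <- t.test(wide[, 1], mu = mu)
      list(statistic = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value, method = "one-sample t test")
    },
    paired_t = {
      need_k(k, 2L, "paired_t")
      diffs <- wide[, 1] - wide[, 2]
      if (all(diffs == 0)) { # degenerate: identical vectors
        list(statistic = 0, df = n - 1, p = 1, method = "paired t test")
      } else {
        ht <- t.test(wide[, 1], wide[, 2], paired = TRUE)
        list(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, method = "paired t test")
      }
    },
    wilcoxon = {
      need_k(k, 2L, "wilcoxon")
      ht <- suppressWarnings(wilcox.test(wide[, 1], wide[, 2],
                                         paired = TRUE, correct = TRUE))
      list(statistic = unname(ht$statistic), df = NA_real_, p = ht$p.value,
           method = "Wilcoxon signed rank test")
    },
    rm_anova = rm_anova_ss(wide),
    friedman = {
      ht <- friedman.test(as.matrix(wide))
      list(statistic = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value, method = "Friedman test")
    })
  structure(c(res, list(shapiro_p = shapiro_p, n_subjects = n)),
            class = "test_result")
}

need_k <- function(k, want, name) {
  if (k != want)
    stop(name, " needs exactly ", want, " factor levels, got ", k,
         call. = FALSE)
}

unstack_scores <- function(agg) {
  subs <- sort(unique(agg$subject))
  levs <- unique(agg$level)
  wide <- matrix(NA_real_, length(subs), length(levs),
                 dimnames = list(subs, levs))
  wide[cbind(match(agg$subject, subs), match(agg$level, levs))] <- agg$x
  if (anyNA(wide))
    stop("incomplete within-subject table; every subject needs every level",
         call. = FALSE)
  wide
}

# one-way repeated-measures ANOVA by explicit sums-of-squares partition
rm_anova_ss <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  ss_total <- sum((wide - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(statistic = f, df = c(df1, df2),
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       method = "one-way repeated-measures ANOVA")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", paste(signif(x$statistic, 5)),
      ", df = ", paste(x$df, collapse = ", "),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}
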