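#' Fit the pattern-estimation GLM
#'
#' Per run: ordinary least squares, or AR(1)-prewhitened generalized least
#' squares ("prewhiten = ar1": the lag-1 autocorrelation is estimated from
#' pooled OLS residuals, the model is transformed and re-fit — a documented
#' approximation to FSL's local autocorrelation correction). Nuisance terms
#' (an intercept and optional polynomial drift regressors) are appended
#' per run. Run-level estimates are combined across runs by fixed-effects
#' inverse-variance weighting, producing per-scene t-maps (beta / se).
#'
#' @param timeseries a `bold_timeseries` (voxel x timepoint per run), or a
#'   single matrix for one run
#' @param designs a `design_matrix`, or list of per-run design matrices
#'   (event regressors only)
#' @param prewhiten "none" or "ar1"
#' @param poly_drift order of polynomial drift nuisance regressors per run
#'   (0 = intercept only)
#' @param combine "fixed" (inverse-variance fixed-effects across runs) or
#'   "none" (return per-run estimates)
#' @param t_cap absolute cap for t-statistics when `se == 0` (noiseless
#'   data); capped cells are flagged in the `capped` matrix
#' @return a `pattern_estimates` object: `beta`, `se`, `tmap` (scene x
#'   voxel), `dof`, `capped`, plus per-run details when `combine = "none"`
#' @export
fit_glm <- function(timeseries, designs, prewhiten = c("none", "ar1"),
                    poly_drift = 1L, combine = c("fixed", "none"),
                    t_cap = 1e6) {
  prewhiten <- match.arg(prewhiten)
  combine <- match.arg(combine)
  if (inherits(timeseries, "bold_timeseries")) {
    data <- timeseries$data
  } else if (is.matrix(timeseries)) {
    data <- list(timeseries)
  } else data <- timeseries
  if (inherits(designs, "design_matrix") || (is.matrix(designs)))
    designs <- list(designs)
  if (length(data) != length(designs))
    stop("number of runs differs between time series and designs",
         call. = FALSE)
  run_fits <- Map(function(Y, X) fit_glm_run(t(Y), X, prewhiten, poly_drift,
                                             t_cap),
                  data, designs)
  if (length(run_fits) == 1L) return(run_fits[[1]])
  if (combine == "none") return(structure(list(runs = run_fits),
                                          class = "pattern_estimates_runs"))
  combine_runs_fixed_effects(run_fits, t_cap)
}

# Y: timepoint x voxel; X: event regressors (timepoint x n_events)
fit_glm_run <- function(Y, X, prewhiten, poly_drift, t_cap) {
  n_tp <- nrow(Y)
  if (nrow(X) != n_tp)
    stop("design has ", nrow(X), " timepoints but data has ", n_tp,
         call. = FALSE)
  event_names <- colnames(X)
  tgrid <- seq_len(n_tp) / n_tp - 0.5
  nuis <- vapply(0:poly_drift, function(k) tgrid^k, numeric(n_tp))
  colnames(nuis) <- paste0("drift", 0:poly_drift)
  Xf <- cbind(X, nuis)
  check_full_rank(Xf)
  ols <- solve_ols(Xf, Y)
  if (prewhiten == "ar1") {
    phi <- pooled_ar1(ols$resid)
    Yw <- ar1_transform(Y, phi)
    Xw <- ar1_transform(Xf, phi)
    ols <- solve_ols(Xw, Yw)
    ols$phi <- phi
  }
  keep <- seq_along(event_names)
  dof <- n_tp - ncol(Xf)
  sigma2 <- colSums(ols$resid^2) / dof
  se <- sqrt(outer(diag(ols$XtXinv)[keep], sigma2))
  beta <- ols$beta[keep, , drop = FALSE]
  tstat <- beta / se
  capped <- !is.finite(tstat) | abs(tstat) > t_cap
  tstat[capped] <- sign(beta[capped]) * t_cap
  tstat[capped & beta == 0] <- 0
  rownames(beta) <- rownames(se) <- rownames(tstat) <- event_names
  structure(list(beta = beta, se = se, tmap = tstat, dof = dof,
                 capped = capped, sigma2 = sigma2,
                 cov_unscaled = ols$XtXinv[keep, keep, drop = FALSE],
                 phi = ols$phi),
            class = "pattern_estimates")
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(qrX)
}

solve_ols <- function(X, Y) {
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  inv_pivoted <- chol2inv(qr.R(qrX)) # in pivoted variable order
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qrX$pivot, qrX$pivot] <- inv_pivoted
  list(beta = beta, resid = resid, XtXinv = XtXinv, phi = NULL)
}

pooled_ar1 <- function(resid) {
  num <- sum(resid[-1, , drop = FALSE] * resid[-nrow(resid), , drop = FALSE])
  den <- sum(resid^2)
  phi <- if (den > 0) num / den else 0
  max(min(phi, 0.99), -0.99)
}

ar1_transform <- function(M, phi) {
  out <- M
  out[1, ] <- sqrt(1 - phi^2) * M[1, ]
  out[-1, ] <- M[-1, , drop = FALSE] -
    phi * M[-nrow(M), , drop = FALSE]
  out
}

combine_runs_fixed_effects <- function(run_fits, t_cap = 1e6) {
  w <- lapply(run_fits, function(f) 1 / f$se^2)
  wsum <- Reduce(`+`, w)
  beta <- Reduce(`+`, Map(function(f, wi) f$beta * wi, run_fits, w)) / wsum
  se <- sqrt(1 / wsum)
  tstat <- beta / se
  capped <- !is.finite(tstat) | abs(tstat) > t_cap
  tstat[capped] <- sign(beta[capped]) * t_cap
  structure(list(beta = beta, se = se, tmap = tstat,
                 dof = sum(vapply(run_fits, `[[`, numeric(1), "dof")),
                 capped = capped,
                 n_runs = length(run_fits)),
            class = "pattern_estimates")
}

#' Category-selectivity contrast from a localizer GLM fit
#'
#' Computes a per-voxel z-statistic for a linear contrast of category
#' regressors (e.g. scenes > faces & objects with weights +1, -1/2, -1/2).
#' z is obtained from the contrast t-statistic via the probability
#' transform.
#'
#' @param estimates a single-run `pattern_estimates` carrying
#'   `cov_unscaled` and `sigma2` (i.e. from `fit_glm(..., combine =
#'   "none")` on the localizer)
#' @param weights named contrast vector over category regressors; must sum
#'   to zero
#' @return a `selectivity_map`: per-voxel z values
#' @export
localizer_contrast <- function(estimates, weights) {
  if (abs(sum(weights)) > 1e-12)
    stop("contrast weights must sum to zero", call. = FALSE)
  if (is.null(estimates$cov_unscaled))
    stop("localizer_contrast needs a run-level fit (combine = \"none\")",
         call. = FALSE)
  if (is.null(names(weights)) ||
      !all(names(weights) %in% rownames(estimates$beta)))
    stop("contrast weights must be named by localizer regressors",
         call. = FALSE)
  cvec <- setNames(numeric(nrow(estimates$beta)), rownames(estimates$beta))
  cvec[names(weights)] <- weights
  est <- drop(crossprod(cvec, estimates$beta))
  var_unscaled <- drop(crossprod(cvec, estimates$cov_unscaled %*% cvec))
  se <- sqrt(var_unscaled * estimates$sigma2)
  tstat <- est / se
  z <- t_to_z(tstat, estimates$dof)
  structure(list(z = z, dof = estimates$dof), class = "selectivity_map")
}

# convert t to z through tail probabilities (log scale for stability)
t_to_z <- function(tstat, dof) {
  sign(tstat) * qnorm(pt(abs(tstat), dof, lower.tail = FALSE,
                         log.p = TRUE),
                      lower.tail = FALSE, log.p = TRUE)
}

#' Select voxels by selectivity threshold or split them into terciles
#'
#' Threshold mode keeps voxels with `z` strictly greater than `z_min`.
#' Tercile mode partitions voxels by rank (least to most selective) into
#' three near-equal groups; when `n mod 3 != 0` the extra voxels go to the
#' *lower* terciles, and ties in `z` are broken by voxel index.
#'
#' @param selectivity a `selectivity_map` or bare numeric vector of z values
#' @param mode "threshold" or "tercile"
#' @param z_min threshold (threshold mode)
#' @param label ROI label attached to the mask(s)
#' @return threshold mode: a logical `roi_mask` with attributes `label`;
#'   tercile mode: list of 3 `roi_mask`s ordered least to most selective
#' @export
select_voxels <- function(selectivity, mode = c("threshold", "tercile"),
                          z_min = 1, label = "ROI") {
  mode <- match.arg(mode)
  z <- if (inherits(selectivity, "selectivity_map")) selectivity$z
  else selectivity
  if (mode == "threshold") {
    mask <- z > z_min
    if (!any(mask))
      stop("no voxels survive z > ", z_min,
           "; a lower threshold is needed to yield enough voxels",
           call. = FALSE)
    return(structure(mask, label = label, class = "roi_mask"))
  }
  n <- length(z)
  if (n < 3L) stop("tercile mode needs at least 3 voxels", call. = FALSE)
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- base + as.integer(seq_len(3L) <= extra) # extras to lower terciles
  rank_idx <- order(z, seq_along(z)) # ascending z, ties by voxel index
  tercile <- integer(n)
  tercile[rank_idx] <- rep(1:3, times = sizes)
  lapply(1:3, function(k)
    structure(tercile == k, label = paste0(label, "_tercile", k),
              tercile = k, class = "roi_mask"))
}
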