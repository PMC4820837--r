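#' Noise specification for BOLD simulation
#'
#' @param sigma marginal sd of the AR(1) thermal/physiological noise
#' @param ar1_phi lag-1 autocorrelation in `[0, 1)`
#' @param drift_amplitude scale of the slow scanner drift (linear trend plus
#'   a low-frequency cosine with random phase)
#' @param run_jitter_sd sd of a small run-specific re-draw of each scene's
#'   voxel pattern, so that repeated estimates of the same scene are not
#'   degenerate copies
#' @param seed integer seed
#' @return a `noise_spec` object
#' @export
noise_spec <- function(sigma = 1.0, ar1_phi = 0.3, drift_amplitude = 1.0,
                       run_jitter_sd = 0.1, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (ar1_phi < 0 || ar1_phi >= 1)
    stop("ar1_phi must lie in [0, 1)", call. = FALSE)
  if (run_jitter_sd < 0) stop("run_jitter_sd must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, ar1_phi = ar1_phi,
                 drift_amplitude = drift_amplitude,
                 run_jitter_sd = run_jitter_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

# AR(1) noise with marginal sd sigma; one column per voxel
ar1_noise <- function(n, n_voxels, sigma, phi) {
  if (sigma == 0) return(matrix(0, n, n_voxels))
  innov <- matrix(rnorm(n * n_voxels, sd = sigma * sqrt(1 - phi^2)),
                  n, n_voxels)
  innov[1, ] <- rnorm(n_voxels, sd = sigma)
  mat <- stats::filter(innov, phi, method = "recursive")
  matrix(as.numeric(mat), n, n_voxels)
}

#' Simulate BOLD time series from ground-truth patterns
#'
#' Forward model: per run, each scene's impulse onset train is convolved
#' with the double-gamma HRF and scaled by that scene's voxel pattern
#' (plus optional run-specific pattern jitter); AR(1) Gaussian noise and a
#' slow drift (linear + low-frequency cosine) are added per voxel.
#'
#' @param patterns a `ground_truth_patterns` object
#' @param sequence a `trial_sequence` over the same stimulus set
#' @param hrf an [hrf_spec()]
#' @param noise a [noise_spec()]
#' @param tr repetition time (s); defaults to the sequence's design spec
#' @return a `bold_timeseries`: list of per-run voxel x timepoint matrices,
#'   with `tr` and the per-run design matrices used for the signal
#' @export
simulate_bold <- function(patterns, sequence, hrf = hrf_spec(),
                          noise = noise_spec(),
                          tr = attr(sequence, "spec")$tr) {
  if (is.null(tr) || tr <= 0) stop("TR must be positive", call. = FALSE)
  spec <- attr(sequence, "spec")
  trial_dur <- if (!is.null(spec)) spec$trial_duration else
    max(diff(sort(unique(sequence$onset[sequence$run ==
                                          sequence$run[1]]))))
  if (trial_dur <= 0) stop("trial duration must be positive", call. = FALSE)
  if (!all(stats::na.omit(sequence$stimulus_id) %in%
           rownames(patterns$pattern)))
    stop("sequence references scenes missing from the patterns",
         call. = FALSE)
  with_substream(noise$seed, paste0("bold:", patterns$roi), {
    runs <- lapply(sort(unique(sequence$run)), function(r) {
      seq_r <- sequence[sequence$run == r, , drop = FALSE]
      n_tp <- ceiling((max(seq_r$onset) + trial_dur) / tr)
      X <- build_design_matrix(seq_r, hrf, tr, n_tp, events_as = "impulse")
      P <- patterns$pattern[colnames(X), , drop = FALSE]
      if (noise$run_jitter_sd > 0)
        P <- P + matrix(rnorm(length(P), sd = noise$run_jitter_sd),
                        nrow(P), ncol(P))
      signal <- X %*% P # timepoint x voxel
      n_v <- ncol(signal)
      eps <- ar1_noise(n_tp, n_v, noise$sigma, noise$ar1_phi)
      tgrid <- (seq_len(n_tp) - 1) * tr
      drift <- if (noise$drift_amplitude > 0) {
        vapply(seq_len(n_v), function(v) {
          noise$drift_amplitude *
            (runif(1, -1, 1) * (tgrid / max(tgrid) - 0.5) +
               runif(1, 0.5, 1) * cos(2 * pi * tgrid / 240 + runif(1, 0,
                                                                   2 * pi)))
        }, numeric(n_tp))
      } else matrix(0, n_tp, n_v)
      t(signal + eps + drift) # voxel x timepoint
    })
    structure(list(data = runs, tr = tr, roi = patterns$roi,
                   runs = sort(unique(sequence$run))),
              class = "bold_timeseries")
  })
}

#' FSL-style Gaussian-weighted running-line high-pass filter
#'
#' At each timepoint, a straight line is fitted to the series by weighted
#' least squares with Gaussian weights of width `sigma` seconds centred on
#' that timepoint, and the fitted value is subtracted. Constants and pure
#' linear ramps map to (numerically) zero; fluctuations slow relative to
#' `sigma` are strongly attenuated while fast ones pass through.
#'
#' @param timeseries a `bold_timeseries`, or a single voxel x timepoint
#'   matrix
#' @param sigma filter width in seconds (default 64 s)
#' @param tr sampling interval, required when a bare matrix is given
#' @return the filtered object, same shape as the input
#' @export
highpass_filter <- function(timeseries, sigma = 64, tr = NULL) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  filt_mat <- function(mat, tr) {
    n <- ncol(mat)
    H <- running_line_hat(n, sigma / tr)
    mat - mat %*% t(H)
  }
  if (inherits(timeseries, "bold_timeseries")) {
    timeseries$data <- lapply(timeseries$data, filt_mat, tr = timeseries$tr)
    timeseries
  } else {
    if (is.null(tr)) stop("tr is required for a bare matrix", call. = FALSE)
    filt_mat(timeseries, tr)
  }
}

# hat matrix of the Gaussian-weighted local line fit (time unit = volumes)
running_line_hat <- function(n, sigma_vol) {
  tt <- seq_len(n)
  H <- matrix(0, n, n)
  for (i in tt) {
    w <- exp(-0.5 * ((tt - i) / sigma_vol)^2)
    x <- tt - i
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
    det <- sw * swxx - swx^2
    # fitted value at x = 0 from the weighted straight-line fit
    a <- (swxx * w - swx * (w * x)) / det
    H[i, ] <- a
  }
  H
}
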