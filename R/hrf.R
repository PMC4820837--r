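#' Canonical double-gamma haemodynamic response function
#'
#' The "canonical" HRF: a gamma density peaking around `peak_delay` seconds
#' minus a scaled gamma undershoot, normalized to unit peak height.
#' Defaults: peak 6 s, undershoot 16 s, dispersions 1, undershoot ratio 1/6.
#'
#' @param peak_delay,undershoot_delay response / undershoot delays (s)
#' @param peak_disp,undershoot_disp dispersions (s)
#' @param ratio undershoot amplitude relative to the peak
#' @param dt internal sampling resolution (s)
#' @param duration kernel length (s)
#' @return an `hrf_spec` object
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 1 / 6, dt = 0.1, duration = 32) {
  if (peak_delay <= 0 || undershoot_delay <= 0 || peak_disp <= 0 ||
      undershoot_disp <= 0 || dt <= 0)
    stop("hrf_spec: delays, dispersions and dt must be positive",
         call. = FALSE)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, dt = dt, duration = duration),
            class = "hrf_spec")
}

#' Evaluate the double-gamma HRF at given times
#'
#' @param t times in seconds (>= 0; negative times return 0)
#' @param spec an [hrf_spec()]
#' @return HRF values, peak-normalized to 1
#' @export
hrf_kernel <- function(t, spec = hrf_spec()) {
  h <- function(x) {
    dgamma(x, shape = spec$peak_delay / spec$peak_disp,
           scale = spec$peak_disp) -
      spec$ratio * dgamma(x, shape = spec$undershoot_delay /
                            spec$undershoot_disp,
                          scale = spec$undershoot_disp)
  }
  # peak-normalize on a fine grid so hrf_kernel(t) is consistent across calls
  grid <- seq(0, spec$duration, by = spec$dt)
  peak <- max(h(grid))
  # the kernel has finite support [0, duration]
  ifelse(t < 0 | t > spec$duration, 0, h(pmax(t, 0)) / peak)
}

#' Build a GLM design matrix by HRF convolution
#'
#' One column per event type (scene), each the convolution of its onset
#' train with the canonical HRF sampled at the TR. Events are modelled as
#' impulses (main task) or boxcars of their duration (localizer blocks).
#'
#' @param sequence a `trial_sequence` for a *single run* (or a data frame
#'   with columns `onset`, `trial_type`, `stimulus_id`, `duration`)
#' @param hrf an [hrf_spec()]
#' @param tr repetition time (s)
#' @param n_timepoints number of volumes
#' @param events_as "impulse" or "boxcar"
#' @return a `design_matrix`: matrix `n_timepoints` x regressors with
#'   regressor names; attribute `events_as`
#' @export
build_design_matrix <- function(sequence, hrf = hrf_spec(), tr,
                                n_timepoints,
                                events_as = c("impulse", "boxcar")) {
  events_as <- match.arg(events_as)
  if (length(unique(sequence$run)) > 1L)
    stop("build_design_matrix expects a single run; split by run first",
         call. = FALSE)
  ev <- sequence[!is.na(sequence$stimulus_id), , drop = FALSE]
  scan_end <- n_timepoints * tr
  if (any(ev$onset < 0 | ev$onset >= scan_end))
    stop("event onsets fall outside the scan window [0, ", scan_end, ")",
         call. = FALSE)
  dt <- hrf$dt
  n_fine <- ceiling(scan_end / dt) + 1L
  kern <- hrf_kernel(seq(0, hrf$duration, by = dt), hrf)
  ids <- sort(unique(ev$stimulus_id))
  vol_idx <- round((0:(n_timepoints - 1)) * tr / dt) + 1L
  stick <- matrix(0, n_fine, length(ids), dimnames = list(NULL, ids))
  for (k in seq_len(nrow(ev))) {
    j <- match(ev$stimulus_id[k], ids)
    i0 <- round(ev$onset[k] / dt) + 1L
    if (events_as == "impulse") {
      stick[i0, j] <- stick[i0, j] + 1
    } else {
      i1 <- min(n_fine, i0 + max(1L, round(ev$duration[k] / dt)) - 1L)
      stick[i0:i1, j] <- stick[i0:i1, j] + 1
    }
  }
  # causal convolution of every onset train with the kernel at once (FFT)
  n_pad <- stats::nextn(n_fine + length(kern) - 1L, 2)
  kpad <- c(kern, numeric(n_pad - length(kern)))
  spad <- rbind(stick, matrix(0, n_pad - n_fine, ncol(stick)))
  conv <- Re(stats::mvfft(stats::mvfft(spad) * c(stats::fft(kpad)),
                          inverse = TRUE)) / n_pad
  X <- conv[vol_idx, , drop = FALSE]
  dimnames(X) <- list(NULL, ids)
  structure(X, events_as = events_as, tr = tr, class = c("design_matrix",
                                                         "matrix", "array"))
}
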