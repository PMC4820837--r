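#' Latent representation model with condition-dependent pairmate coupling
#'
#' Scene representations are continuous Gaussian factor read-outs. For a
#' scene in condition k, each latent feature unit is
#' \deqn{u = \sqrt{c_g} G_k + s \sqrt{|c_p|} F_p + \sqrt{1 - c_g - |c_p|} E,}
#' where \eqn{G_k} is a condition-level factor shared by all scenes of the
#' condition, \eqn{F_p} a pair-level factor and \eqn{E} scene-unique, all
#' i.i.d. standard normal across units. The sign \eqn{s} is +1 for both
#' pairmates when the pair coupling `c_pair` is positive (shared features,
#' clustering) and opposite for the two pairmates when `c_pair` is negative
#' (repulsion past orthogonality). The construction gives exactly
#' `c_global + c_pair` expected correlation between pairmates and `c_global`
#' between same-condition nonpairmates.
#'
#' Voxels read the units out through a random linear projection; a per-voxel
#' `selectivity_profile` weight in `[0, 1]` scales how much of each
#' condition's *deviation from the baseline condition's couplings* reaches
#' that voxel (the hook for selectivity-tercile effects). With the default
#' all-ones profile every voxel carries the full condition couplings and the
#' closed-form correlations above hold (attenuated by
#' `1 / (1 + pattern_noise_sd^2)` when idiosyncratic voxel noise is added).
#'
#' @param n_voxels voxels per simulated ROI
#' @param n_units number of latent feature units (>= 2)
#' @param c_global named vector, per condition: target correlation among
#'   same-condition nonpairmates
#' @param c_pair named vector, per condition: additional pairmate coupling
#'   (negative = repulsion); `c_global + c_pair` must lie in (-1, 1) and
#'   `c_global + |c_pair|` must not exceed 1
#' @param selectivity_profile per-voxel weights in `[0, 1]`, or `NULL` for
#'   all ones
#' @param pattern_noise_sd per-voxel idiosyncratic variability (sd, signal
#'   units are variance 1)
#' @param baseline_condition condition whose couplings define the baseline
#'   for selectivity scaling
#' @param seed integer seed
#' @return an object of class `representation_model`
#' @export
representation_model <- function(n_voxels = 100L,
                                 n_units = 200L,
                                 c_global = c(NoFace = 0.10,
                                              DifferentFace = 0.18,
                                              SameFace = 0.18),
                                 c_pair = c(NoFace = 0.15,
                                            DifferentFace = -0.03,
                                            SameFace = -0.15),
                                 selectivity_profile = NULL,
                                 pattern_noise_sd = 0.1,
                                 baseline_condition = "NoFace",
                                 seed = 1L) {
  if (n_units < 2L) stop("n_units must be >= 2", call. = FALSE)
  if (is.null(names(c_global)) || is.null(names(c_pair)) ||
      !setequal(names(c_global), names(c_pair)))
    stop("c_global and c_pair must be named by the same conditions",
         call. = FALSE)
  c_pair <- c_pair[names(c_global)]
  if (any(c_global < 0))
    stop("c_global must be non-negative", call. = FALSE)
  bad <- abs(c_global + c_pair) >= 1 | (c_global + abs(c_pair)) > 1
  if (any(bad))
    stop("couplings out of range for condition(s) ",
         paste(names(c_global)[bad], collapse = ", "),
         ": need |c_global + c_pair| < 1 and c_global + |c_pair| <= 1",
         call. = FALSE)
  if (!is.null(selectivity_profile)) {
    if (length(selectivity_profile) != n_voxels ||
        any(selectivity_profile < 0 | selectivity_profile > 1))
      stop("selectivity_profile must hold n_voxels weights in [0, 1]",
           call. = FALSE)
  }
  if (pattern_noise_sd < 0) stop("pattern_noise_sd must be >= 0",
                                 call. = FALSE)
  structure(list(n_voxels = as.integer(n_voxels),
                 n_units = as.integer(n_units),
                 c_global = c_global, c_pair = c_pair,
                 selectivity_profile = selectivity_profile,
                 pattern_noise_sd = pattern_noise_sd,
                 baseline_condition = baseline_condition,
                 seed = as.integer(seed)),
            class = "representation_model")
}

# draw the unit-space scene matrix (n_units x n_scenes) for given couplings;
# factor draws G (condition), F (pair), E (scene) are passed in so that the
# baseline and condition-specific versions used for selectivity mixing share
# no randomness with each other but are each internally coherent
unit_patterns <- function(stimset, c_global, c_pair, G, F_, E) {
  n_units <- nrow(E)
  U <- matrix(0, n_units, nrow(stimset))
  for (i in seq_len(nrow(stimset))) {
    cond <- stimset$condition[i]
    cg <- c_global[[cond]]
    cp <- c_pair[[cond]]
    sgn <- if (cp >= 0) 1 else ifelse(stimset$set_half[i] == "A", 1, -1)
    U[, i] <- sqrt(cg) * G[, cond] +
      sgn * sqrt(abs(cp)) * F_[, stimset$pair[i]] +
      sqrt(1 - cg - abs(cp)) * E[, i]
  }
  U
}

#' Sample ground-truth scene-by-voxel patterns
#'
#' @param model a [representation_model()]
#' @param stimset a `stimulus_set`
#' @param roi label stored with the patterns (e.g. "HIPP")
#' @return a `ground_truth_patterns` object: list with `pattern` (scene x
#'   voxel matrix, rows named by scene), the generating components (for
#'   [apply_differentiation()]), `selectivity`, and metadata
#' @export
sample_ground_truth_patterns <- function(model, stimset, roi = "ROI") {
  validate_stimulus_set(stimset)
  conds <- unique(stimset$condition)
  missing <- setdiff(conds, names(model$c_global))
  if (length(missing))
    stop("model lacks couplings for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  with_substream(model$seed, paste0("patterns:", roi), {
    n_u <- model$n_units
    n_v <- model$n_voxels
    pair_ids <- unique(stimset$pair)
    draw_factors <- function() {
      list(G = matrix(rnorm(n_u * length(conds)), n_u,
                      dimnames = list(NULL, conds)),
           F_ = matrix(rnorm(n_u * length(pair_ids)), n_u,
                       dimnames = list(NULL, pair_ids)),
           E = matrix(rnorm(n_u * nrow(stimset)), n_u))
    }
    fc <- draw_factors() # condition-specific couplings
    fb <- draw_factors() # baseline couplings (independent draw)
    sel <- model$selectivity_profile
    if (is.null(sel)) sel <- rep(1, n_v)
    base <- model$baseline_condition
    cg_base <- setNames(rep(model$c_global[[base]], length(conds)), conds)
    cp_base <- setNames(rep(model$c_pair[[base]], length(conds)), conds)
    U_cond <- unit_patterns(stimset, model$c_global, model$c_pair,
                            fc$G, fc$F_, fc$E)
    U_base <- unit_patterns(stimset, cg_base, cp_base, fb$G, fb$F_, fb$E)
    W <- matrix(rnorm(n_u * n_v, sd = 1 / sqrt(n_u)), n_u, n_v)
    noise <- matrix(rnorm(nrow(stimset) * n_v, sd = model$pattern_noise_sd),
                    nrow(stimset), n_v)
    pattern <- crossprod(U_cond, W) * rep(sqrt(sel), each = nrow(stimset)) +
      crossprod(U_base, W) * rep(sqrt(1 - sel), each = nrow(stimset)) +
      noise
    rownames(pattern) <- stimset$scene
    structure(list(pattern = pattern,
                   roi = roi,
                   components = list(fc = fc, fb = fb, W = W, noise = noise),
                   selectivity = sel,
                   model = model,
                   stimset = stimset),
              class = "ground_truth_patterns")
  })
}

#' Apply feature-unit differentiation to ground-truth patterns
#'
#' Implements targeted differentiation as (a) "dropout" of a fraction of the
#' shared pair-factor units — only pairs with positive pair coupling have
#' shared units to lose — and (b) an opposite-signed voxel-space
#' perturbation pushing the two pairmates apart, scaled by
#' `repulsion_strength` and by each voxel's selectivity weight. Expected
#' pairmate correlation is non-increasing in both arguments; a sufficiently
#' strong repulsion drives the expected scene pair difference score negative.
#'
#' @param patterns a `ground_truth_patterns` object
#' @param dropout_fraction fraction of shared pair-factor units zeroed
#' @param repulsion_strength sd of the anti-symmetric pairmate perturbation
#' @return a new `ground_truth_patterns` object
#' @export
apply_differentiation <- function(patterns, dropout_fraction = 0,
                                  repulsion_strength = 0) {
  if (dropout_fraction < 0 || dropout_fraction > 1)
    stop("dropout_fraction must lie in [0, 1]", call. = FALSE)
  if (repulsion_strength < 0)
    stop("repulsion_strength must be >= 0", call. = FALSE)
  if (dropout_fraction == 0 && repulsion_strength == 0) return(patterns)
  model <- patterns$model
  stimset <- patterns$stimset
  with_substream(model$seed, paste0("differentiation:", patterns$roi), {
    comp <- patterns$components
    n_u <- model$n_units
    n_drop <- round(dropout_fraction * n_u)
    fc <- comp$fc
    U_cond <- unit_patterns(stimset, model$c_global, model$c_pair,
                            fc$G, fc$F_, fc$E)
    if (n_drop > 0) {
      # a dropped shared unit stops being shared: its pair-factor
      # contribution is replaced by fresh scene-unique variance, so scene
      # variance is preserved and expected pairmate correlation interpolates
      # linearly from c_global + c_pair down to c_global at full dropout
      for (p in colnames(fc$F_)) {
        cond <- stimset$condition[match(p, stimset$pair)]
        cp <- model$c_pair[[cond]]
        if (cp > 0) { # only shared (positively coupled) units can drop out
          drop <- sample.int(n_u, n_drop)
          for (i in which(stimset$pair == p))
            U_cond[drop, i] <- U_cond[drop, i] +
              sqrt(cp) * (rnorm(n_drop) - fc$F_[drop, p])
        }
      }
    }
    base <- model$baseline_condition
    conds <- unique(stimset$condition)
    cg_base <- setNames(rep(model$c_global[[base]], length(conds)), conds)
    cp_base <- setNames(rep(model$c_pair[[base]], length(conds)), conds)
    U_base <- unit_patterns(stimset, cg_base, cp_base,
                            comp$fb$G, comp$fb$F_, comp$fb$E)
    sel <- patterns$selectivity
    pattern <- crossprod(U_cond, comp$W) *
      rep(sqrt(sel), each = nrow(stimset)) +
      crossprod(U_base, comp$W) * rep(sqrt(1 - sel), each = nrow(stimset)) +
      comp$noise
    if (repulsion_strength > 0) {
      for (p in unique(stimset$pair)) {
        rows <- which(stimset$pair == p)
        perturb <- repulsion_strength * sel * rnorm(model$n_voxels)
        pattern[rows[1], ] <- pattern[rows[1], ] + perturb
        pattern[rows[2], ] <- pattern[rows[2], ] - perturb
      }
    }
    rownames(pattern) <- stimset$scene
    out <- patterns
    out$pattern <- pattern
    out$components$fc <- fc
    out$differentiation <- list(dropout_fraction = dropout_fraction,
                                repulsion_strength = repulsion_strength)
    out
  })
}
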