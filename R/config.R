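#' Default pipeline configuration
#'
#' Nested sections mirroring the pipeline stages. All randomness in a run
#' derives from the single top-level `seed` via named substreams. ROI
#' parameterizations: a hippocampus-like ROI in which learning both raises
#' nonpairmate coupling and drives pairmate coupling negative (Same Face)
#' or to zero (Different Face), and control ROIs (PPA-like, EVC-like) whose
#' couplings do not change with condition.
#'
#' @param ... top-level overrides, e.g. `seed = 7`, or whole sections as
#'   named lists (`design = list(n_runs = 2)`)
#' @return a validated `pipeline_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_subjects = 18L,
    design = list(n_pairs_total = 36L, n_pairs_per_condition = 12L,
                  n_runs = 8L, trial_duration = 4.0, stim_duration = 0.5,
                  tr = 2.0, target_rate = 1 / 12),
    rois = list(
      HIPP = list(n_voxels = 128L, n_units = 200L,
                  c_global = c(NoFace = 0.10, DifferentFace = 0.18,
                               SameFace = 0.18),
                  c_pair = c(NoFace = 0.15, DifferentFace = -0.03,
                             SameFace = -0.15)),
      PPA = list(n_voxels = 128L, n_units = 200L,
                 c_global = c(NoFace = 0.15, DifferentFace = 0.15,
                              SameFace = 0.15),
                 c_pair = c(NoFace = 0.18, DifferentFace = 0.18,
                            SameFace = 0.18)),
      EVC = list(n_voxels = 128L, n_units = 200L,
                 c_global = c(NoFace = 0.20, DifferentFace = 0.20,
                              SameFace = 0.20),
                 c_pair = c(NoFace = 0.20, DifferentFace = 0.20,
                            SameFace = 0.20))),
    pattern_noise_sd = 0.1,
    noise = list(sigma = 1.0, ar1_phi = 0.3, drift_amplitude = 1.0,
                 run_jitter_sd = 0.1),
    glm = list(prewhiten = "ar1", highpass_sigma = 64, poly_drift = 1L),
    rsa = list(zscore = FALSE),
    behavior = list(intercept = 0.7, slope_score = -2.0,
                    repetition_effect = 1.2, interaction = 0,
                    subject_sd = 0.5, other_rate = 0.04,
                    condition_effects = c(DifferentFace = 1.12,
                                          SameFace = 0)),
    inference = list(random = "intercept"))
  validate_config(modify_config(cfg, list(...)))
}

modify_config <- function(cfg, over) {
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Validate (and default-fill) a pipeline configuration
#'
#' Accepts a config list or a path to a YAML/JSON file. Unknown keys are
#' rejected with their field path; numeric ranges are checked; missing
#' fields are filled from [default_config()].
#'
#' @param config list or file path
#' @return a `pipeline_config`
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- read_config_file(config)
  }
  base <- list(
    seed = 1L, n_subjects = 18L,
    design = list(n_pairs_total = 36L, n_pairs_per_condition = 12L,
                  n_runs = 8L, trial_duration = 4.0, stim_duration = 0.5,
                  tr = 2.0, target_rate = 1 / 12),
    rois = NULL, pattern_noise_sd = 0.1,
    noise = list(sigma = 1.0, ar1_phi = 0.3, drift_amplitude = 1.0,
                 run_jitter_sd = 0.1),
    glm = list(prewhiten = "ar1", highpass_sigma = 64, poly_drift = 1L),
    rsa = list(zscore = FALSE),
    behavior = list(intercept = 0.7, slope_score = -2.0,
                    repetition_effect = 1.2, interaction = 0,
                    subject_sd = 0.5, other_rate = 0.04,
                    condition_effects = c(DifferentFace = 1.12,
                                          SameFace = 0)),
    inference = list(random = "intercept"))
  check_keys <- function(given, allowed, path) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  check_keys(config, names(base), "")
  for (sec in c("design", "noise", "glm", "rsa", "behavior", "inference"))
    if (!is.null(config[[sec]])) {
      check_keys(config[[sec]], names(base[[sec]]), paste0(sec, "."))
      base[[sec]] <- modifyList(base[[sec]], config[[sec]])
    }
  for (k in c("seed", "n_subjects", "pattern_noise_sd"))
    if (!is.null(config[[k]])) base[[k]] <- config[[k]]
  if (!is.null(config$rois)) {
    for (r in names(config$rois))
      check_keys(config$rois[[r]],
                 c("n_voxels", "n_units", "c_global", "c_pair",
                   "selectivity_profile"), paste0("rois.", r, "."))
    base$rois <- config$rois
  } else {
    base$rois <- default_config()$rois
  }
  # file parsers return named lists where the API uses named vectors
  base$behavior$condition_effects <- unlist(base$behavior$condition_effects)
  for (r in names(base$rois)) {
    base$rois[[r]]$c_global <- unlist(base$rois[[r]]$c_global)
    base$rois[[r]]$c_pair <- unlist(base$rois[[r]]$c_pair)
  }
  fail <- function(field, msg) stop("invalid config: ", field, " ", msg,
                                    call. = FALSE)
  if (base$n_subjects < 1) fail("n_subjects", "must be >= 1")
  if (base$noise$sigma < 0) fail("noise.sigma", "must be >= 0")
  if (base$noise$ar1_phi < 0 || base$noise$ar1_phi >= 1)
    fail("noise.ar1_phi", "must lie in [0, 1)")
  if (base$pattern_noise_sd < 0) fail("pattern_noise_sd", "must be >= 0")
  if (!base$glm$prewhiten %in% c("none", "ar1"))
    fail("glm.prewhiten", "must be \"none\" or \"ar1\"")
  if (!base$inference$random %in% c("maximal", "intercept", "none"))
    fail("inference.random", "must be maximal/intercept/none")
  for (r in names(base$rois)) {
    roi <- base$rois[[r]]
    cg <- unlist(roi$c_global); cp <- unlist(roi$c_pair)
    if (any(abs(cg + cp) >= 1) || any(cg + abs(cp) > 1) || any(cg < 0))
      fail(paste0("rois.", r), "couplings out of range")
  }
  # design section feeds design_spec(), which re-validates
  do.call(design_spec, c(base$design, list(seed = base$seed)))
  structure(base, class = "pipeline_config")
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a config to YAML or JSON
#'
#' @param config a `pipeline_config`
#' @param path output path (.yaml/.yml or .json)
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(config)
  # named vectors serialize as key-value maps, not bare arrays
  plain$behavior$condition_effects <-
    as.list(plain$behavior$condition_effects)
  for (r in names(plain$rois)) {
    plain$rois[[r]]$c_global <- as.list(plain$rois[[r]]$c_global)
    plain$rois[[r]]$c_pair <- as.list(plain$rois[[r]]$c_pair)
  }
  if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(plain, path, precision = 15L)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
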