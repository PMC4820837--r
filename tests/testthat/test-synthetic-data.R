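# Monte-Carlo oracle for the factor model: empirical mean pairmate /
# nonpairmate correlations converge to c_global + c_pair and c_global
# (attenuated by 1/(1 + noise_sd^2)). Because every cell of one pattern set
# shares the same condition-factor draw, cells are correlated: the oracle
# averages over independent replicate draws and takes its Monte-Carlo s.e.
# across replicate means.
empirical_couplings <- function(patterns, stimset) {
  sm <- build_similarity_matrix(patterns, stimset)
  r <- tanh(sm$z) # back to correlation units for the oracle comparison
  c(pairmate = mean(diag(r)), nonpair = mean(r[row(r) != col(r)]))
}

replicate_couplings <- function(ss, cg, cp, n_rep = 12L, noise_sd = 0,
                                base_seed = 100L) {
  reps <- vapply(seq_len(n_rep), function(k) {
    m <- wide_model(cg, cp, n_voxels = 150L, n_units = 300L,
                    seed = base_seed + k, pattern_noise_sd = noise_sd)
    empirical_couplings(sample_ground_truth_patterns(m, ss), ss)
  }, numeric(2))
  list(pairmate = mean(reps["pairmate", ]),
       pairmate_se = sd(reps["pairmate", ]) / sqrt(n_rep),
       nonpair = mean(reps["nonpair", ]),
       nonpair_se = sd(reps["nonpair", ]) / sqrt(n_rep))
}

test_that("factor-model correlations match the closed-form oracle", {
  spec <- wide_spec(60L, seed = 2L)
  ss <- make_stimulus_set(spec)
  for (cc in list(c(cg = 0.2, cp = 0.3), c(cg = 0.15, cp = -0.15),
                  c(cg = 0.3, cp = 0))) {
    emp <- replicate_couplings(ss, cc[["cg"]], cc[["cp"]])
    expect_lt(abs(emp$pairmate - (cc[["cg"]] + cc[["cp"]])),
              3 * emp$pairmate_se + 0.01) # finite-units/voxels bias floor
    expect_lt(abs(emp$nonpair - cc[["cg"]]), 3 * emp$nonpair_se + 0.01)
  }
})

test_that("pattern noise attenuates correlations as 1/(1 + sd^2)", {
  spec <- wide_spec(60L, seed = 3L)
  ss <- make_stimulus_set(spec)
  emp <- replicate_couplings(ss, 0.3, 0.3, noise_sd = 0.5, base_seed = 300L)
  expect_lt(abs(emp$pairmate - 0.6 / 1.25), 3 * emp$pairmate_se + 0.01)
})

test_that("pair factor absent makes pairmates exchangeable (score ~ 0)", {
  spec <- wide_spec(200L, seed = 4L)
  ss <- make_stimulus_set(spec)
  m <- wide_model(0.2, 0, n_voxels = 150L, n_units = 300L, seed = 5L)
  sc <- pair_difference_scores(
    build_similarity_matrix(sample_ground_truth_patterns(m, ss), ss))
  se <- sd(sc$difference_score) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$difference_score)), 3 * se + 0.01)
})

test_that("SameFace defaults yield pairmate < nonpairmate similarity", {
  spec <- small_spec(seed = 6L)
  ss <- make_stimulus_set(spec)
  pt <- sample_ground_truth_patterns(
    representation_model(n_voxels = 200L, seed = 8L), ss)
  sc <- pair_difference_scores(build_similarity_matrix(pt, ss))
  sf <- sc[sc$condition == "SameFace", ]
  expect_lt(mean(sf$pairmate_z), mean(sf$mean_nonpairmate_z))
})

test_that("out-of-range couplings are rejected", {
  expect_error(representation_model(c_global = c(NoFace = 0.8),
                                    c_pair = c(NoFace = 0.5)),
               "out of range")
  expect_error(representation_model(c_global = c(NoFace = 0.2),
                                    c_pair = c(Other = 0.1)),
               "named by the same conditions")
})

test_that("differentiation: identity, full dropout, monotone repulsion", {
  spec <- wide_spec(60L, seed = 9L)
  ss <- make_stimulus_set(spec)
  pt0 <- sample_ground_truth_patterns(
    wide_model(0.2, 0.3, n_voxels = 150L, n_units = 300L, seed = 10L), ss)
  expect_identical(apply_differentiation(pt0, 0, 0)$pattern, pt0$pattern)
  # full dropout of shared units: pairmate correlation falls to c_global,
  # averaged over independent replicate draws (cells within a draw are
  # correlated through the shared condition factor)
  reps <- vapply(1:12, function(k) {
    pt <- sample_ground_truth_patterns(
      wide_model(0.2, 0.3, n_voxels = 150L, n_units = 300L,
                 seed = 400L + k), ss)
    empirical_couplings(apply_differentiation(pt, 1, 0), ss)[["pairmate"]]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.2), 3 * sd(reps) / sqrt(length(reps)) + 0.01)
  # repulsion sweep: expected difference score decreases, crossing zero
  means <- vapply(c(0, 0.4, 0.8, 1.2), function(r) {
    sc <- pair_difference_scores(build_similarity_matrix(
      apply_differentiation(pt0, 1, r), ss))
    mean(sc$difference_score)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_lt(means[4], 0)
})

test_that("selectivity profile scales the coupling change per voxel", {
  # half the voxels carry the condition couplings fully, half not at all:
  # their mixture sits halfway between baseline and condition couplings.
  # All pairs are NoFace (pairmate corr 0.2); the baseline condition "X"
  # has pairmate corr 0.8: expected mixture = (0.2 + 0.8) / 2 = 0.5
  spec <- wide_spec(60L, seed = 12L)
  ss <- make_stimulus_set(spec)
  reps <- vapply(1:12, function(k) {
    m <- representation_model(n_voxels = 200L, n_units = 300L,
                              c_global = c(NoFace = 0.1, X = 0.5),
                              c_pair = c(NoFace = 0.1, X = 0.3),
                              baseline_condition = "X",
                              selectivity_profile = rep(c(0, 1), 100L),
                              pattern_noise_sd = 0, seed = 500L + k)
    empirical_couplings(sample_ground_truth_patterns(m, ss),
                        ss)[["pairmate"]]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.5), 3 * sd(reps) / sqrt(length(reps)) + 0.01)
})

test_that("noiseless single-scene BOLD equals the sampled HRF", {
  seq1 <- structure(data.frame(run = 1L, onset = 0, duration = 0.5,
                               trial_type = "scene", stimulus_id = "s1",
                               target = 0L),
                    class = c("trial_sequence", "data.frame"),
                    spec = list(tr = 2, trial_duration = 32))
  pat <- structure(list(pattern = matrix(1, 1, 1,
                                         dimnames = list("s1", NULL)),
                        roi = "toy"),
                   class = "ground_truth_patterns")
  bold <- simulate_bold(pat, seq1, hrf_spec(),
                        noise_spec(sigma = 0, drift_amplitude = 0,
                                   run_jitter_sd = 0), tr = 2)
  expect_equal(drop(bold$data[[1]]),
               hrf_kernel(seq(0, 30, by = 2)), tolerance = 1e-8)
})

test_that("noiseless full design is recovered exactly by the GLM", {
  spec <- tiny_spec(seed = 2L)
  ss <- make_stimulus_set(spec)
  sq <- make_scan_sequence(ss, spec)
  pt <- sample_ground_truth_patterns(
    representation_model(n_voxels = 5L, n_units = 20L,
                         c_global = c(NoFace = 0.2, SameFace = 0.2),
                         c_pair = c(NoFace = 0.2, SameFace = -0.2),
                         pattern_noise_sd = 0, seed = 3L), ss)
  bold <- simulate_bold(pt, sq, noise = noise_spec(sigma = 0,
                                                   drift_amplitude = 0,
                                                   run_jitter_sd = 0))
  designs <- lapply(sort(unique(sq$run)), function(r)
    build_design_matrix(sq[sq$run == r, ], hrf_spec(), 2,
                        ncol(bold$data[[r]])))
  est <- fit_glm(bold, designs, prewhiten = "none")
  expect_equal(est$beta[rownames(pt$pattern), ], pt$pattern,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(est$capped))
})

test_that("AR(1) residual noise has the requested lag-1 autocorrelation", {
  set.seed(1)
  x <- pairdiff:::ar1_noise(2000L, 3L, sigma = 1, phi = 0.5)
  ac <- apply(x, 2, function(v) cor(v[-1], v[-length(v)]))
  expect_lt(max(abs(ac - 0.5)), 0.08)
  expect_lt(abs(sd(as.vector(x)) - 1), 0.08)
})

test_that("behaviour generator respects its null and saturation limits", {
  scores <- data.frame(pair = sprintf("p%02d", 1:24),
                       condition = rep(c("DifferentFace", "SameFace"), 12),
                       difference_score = seq(-0.3, 0.3, length.out = 24),
                       subject = NA)
  null_truth <- behavior_model_truth(intercept = 0.3, slope_score = 0,
                                     condition_effects = c(DifferentFace = 0,
                                                           SameFace = 0),
                                     repetition_effect = 0, subject_sd = 0,
                                     other_rate = 0)
  beh <- simulate_behavior(null_truth, scores, n_subjects = 40L, seed = 2L)
  joined <- merge(beh, scores[, c("pair", "difference_score")], by = "pair")
  fit <- glm(I(outcome == "correct") ~ difference_score, binomial(),
             data = joined)
  ci <- confint.default(fit)["difference_score", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  # saturation: a huge intercept makes every outcome correct
  sat <- simulate_behavior(behavior_model_truth(intercept = 30,
                                                other_rate = 0),
                           scores, n_subjects = 3L, seed = 3L)
  expect_true(all(sat$outcome == "correct"))
})

test_that("identical config + seed reproduce bit-identical outputs", {
  spec <- tiny_spec(seed = 8L)
  ss <- make_stimulus_set(spec)
  m <- representation_model(n_voxels = 10L, n_units = 20L,
                            c_global = c(NoFace = 0.2, SameFace = 0.2),
                            c_pair = c(NoFace = 0.2, SameFace = -0.2),
                            seed = 4L)
  expect_identical(sample_ground_truth_patterns(m, ss)$pattern,
                   sample_ground_truth_patterns(m, ss)$pattern)
  sq <- make_scan_sequence(ss, spec)
  ns <- noise_spec(seed = 5L)
  expect_identical(simulate_bold(sample_ground_truth_patterns(m, ss), sq,
                                 noise = ns)$data,
                   simulate_bold(sample_ground_truth_patterns(m, ss), sq,
                                 noise = ns)$data)
})
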