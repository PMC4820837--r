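toy_sequence <- function(onsets, ids, run = 1L, duration = 0.5) {
  structure(data.frame(run = run, onset = onsets, duration = duration,
                       trial_type = "scene", stimulus_id = ids,
                       target = 0L),
            class = c("trial_sequence", "data.frame"))
}

test_that("an impulse column is the HRF sampled at the TR", {
  sq <- toy_sequence(0, "s1")
  X <- build_design_matrix(sq, hrf_spec(), tr = 2, n_timepoints = 16L)
  expect_equal(drop(X), hrf_kernel(seq(0, 30, by = 2)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("convolution is linear: two events sum their shifted HRFs", {
  sq <- toy_sequence(c(0, 8), c("s1", "s1"))
  X <- build_design_matrix(sq, hrf_spec(), tr = 2, n_timepoints = 24L)
  t_grid <- seq(0, by = 2, length.out = 24L)
  expect_equal(drop(X), hrf_kernel(t_grid) + hrf_kernel(t_grid - 8),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("boxcar mode integrates the HRF over the block duration", {
  sq <- toy_sequence(0, "blk", duration = 6)
  Xb <- build_design_matrix(sq, hrf_spec(), tr = 2, n_timepoints = 20L,
                            events_as = "boxcar")
  # oracle: superposition of impulses every dt across the 6 s block
  dt <- hrf_spec()$dt
  t_grid <- seq(0, by = 2, length.out = 20L)
  oracle <- Reduce(`+`, lapply(seq(0, 6 - dt, by = dt), function(o)
    hrf_kernel(t_grid - o)))
  expect_equal(drop(Xb), oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a full default run yields 72 scene regressors", {
  spec <- design_spec(n_runs = 1L)
  ss <- make_stimulus_set(spec)
  sq <- make_scan_sequence(ss, spec)
  X <- build_design_matrix(sq, hrf_spec(), tr = 2, n_timepoints = 192L)
  expect_identical(ncol(X), 72L)
  expect_true(all(colSums(abs(X)) > 0))
})

test_that("events beyond the scan window are rejected", {
  expect_error(build_design_matrix(toy_sequence(100, "s1"), hrf_spec(),
                                   tr = 2, n_timepoints = 16L),
               "outside the scan window")
})

test_that("highpass filter kills constants/ramps and passes fast signals", {
  n <- 200L
  tt <- seq_len(n)
  const <- matrix(5, 1, n)
  expect_lt(max(abs(highpass_filter(const, 64, tr = 2))), 1e-8)
  ramp <- matrix(0.03 * tt, 1, n)
  expect_lt(max(abs(highpass_filter(ramp, 64, tr = 2))), 1e-8)
  # empirical transfer function: slow sinusoid removed, fast one kept
  slow <- sin(2 * pi * tt * 2 / 600) # period 600 s at TR 2
  fast <- sin(2 * pi * tt * 2 / 20) # period 20 s
  slow_out <- drop(highpass_filter(matrix(slow, 1), 64, tr = 2))
  fast_out <- drop(highpass_filter(matrix(fast, 1), 64, tr = 2))
  expect_lt(sd(slow_out) / sd(slow), 0.25)
  expect_gt(sd(fast_out) / sd(fast), 0.9)
})

test_that("GLM matches the closed-form OLS oracle on random instances", {
  set.seed(42)
  for (rep_i in 1:10) {
    n <- sample(10:20, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("ev", seq_len(p))))
    y <- rnorm(n)
    est <- fit_glm(matrix(y, 1), X, prewhiten = "none", poly_drift = 0L)
    orc <- ols_oracle(cbind(X, 1), y)
    expect_equal(drop(est$beta), orc$beta[seq_len(p)], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(drop(est$se), orc$se[seq_len(p)], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(est$dof, orc$dof, ignore_attr = TRUE)
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_glm(matrix(rnorm(20), 1), X, poly_drift = 0L),
               "rank deficient")
})

test_that("AR(1) prewhitening is at least as efficient as OLS", {
  set.seed(7)
  n <- 150L
  X <- matrix(stats::rbinom(n, 1, 0.2) * 1.0, n, 1,
              dimnames = list(NULL, "ev"))
  betas <- replicate(200, {
    y <- 2 * X[, 1] + pairdiff:::ar1_noise(n, 1L, sigma = 1, phi = 0.6)
    c(ols = unname(fit_glm(matrix(y, 1), X,
                           prewhiten = "none")$beta[1, 1]),
      gls = unname(fit_glm(matrix(y, 1), X,
                           prewhiten = "ar1")$beta[1, 1]))
  })
  expect_lt(var(betas["gls", ]), var(betas["ols", ]))
  expect_lt(abs(mean(betas["gls", ]) - 2), 0.1)
})

test_that("fixed-effects run combination is inverse-variance weighting", {
  f1 <- list(beta = matrix(1, 1, 1), se = matrix(0.5, 1, 1), dof = 10)
  f2 <- list(beta = matrix(3, 1, 1), se = matrix(1, 1, 1), dof = 12)
  comb <- pairdiff:::combine_runs_fixed_effects(list(f1, f2))
  w <- c(1 / 0.25, 1)
  expect_equal(comb$beta[1, 1], sum(c(1, 3) * w) / sum(w))
  expect_equal(comb$se[1, 1], sqrt(1 / sum(w)))
  expect_identical(comb$dof, 22)
})

test_that("localizer contrast matches a hand-computed 3-category toy", {
  # 3 category regressors, known design, known noise-free responses + jitter
  set.seed(3)
  n <- 80L # 60 block volumes + 20 rest volumes (else categories + intercept
  X <- matrix(0, n, 3, dimnames = list(NULL, c("scene", "face", "object")))
  X[cbind(1:60, rep(1:3, each = 20))] <- 1 # are collinear)
  b_true <- c(2, 0.5, 0.5)
  y <- drop(X %*% b_true) + rnorm(n, sd = 0.3)
  est <- fit_glm(matrix(y, 1), X, prewhiten = "none", poly_drift = 0L)
  w <- c(scene = 1, face = -0.5, object = -0.5)
  sel <- localizer_contrast(est, w)
  # oracle: c'beta / sqrt(c'(X'X)^-1 c * sigma2), then t -> z
  orc <- ols_oracle(cbind(X, 1), y)
  cvec <- c(w, 0)
  XtXinv <- solve(t(cbind(X, 1)) %*% cbind(X, 1))
  tval <- sum(cvec * orc$beta) /
    sqrt(drop(t(cvec) %*% XtXinv %*% cvec) * sum((y - cbind(X, 1) %*%
                                                    orc$beta)^2) / orc$dof)
  z_orc <- sign(tval) * qnorm(pt(abs(tval), orc$dof, lower.tail = FALSE),
                              lower.tail = FALSE)
  expect_equal(sel$z, z_orc, tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(sel$z, 3) # scene-preferring voxel by construction
  expect_error(localizer_contrast(est, c(scene = 1, face = -0.5)),
               "sum to zero")
})

test_that("voxel selection: threshold, terciles, remainder and ties", {
  expect_equal(sum(select_voxels(c(0.5, 1.2, 3.5), "threshold", z_min = 1)),
               2)
  expect_error(select_voxels(c(0.1, 0.2), "threshold", z_min = 5),
               "lower threshold")
  t9 <- select_voxels(rnorm(9), "tercile")
  expect_equal(vapply(t9, sum, numeric(1)), c(3, 3, 3))
  # 10 voxels: sizes 4/3/3, extras to the lowest tercile; ties by index
  z10 <- c(rep(0, 5), rep(1, 5))
  t10 <- select_voxels(z10, "tercile")
  expect_equal(vapply(t10, sum, numeric(1)), c(4, 3, 3))
  expect_true(all(which(t10[[1]]) == 1:4)) # tie-break by voxel index
  # rank order: every tercile-3 z >= every tercile-1 z
  z <- rnorm(10)
  tz <- select_voxels(z, "tercile")
  expect_gte(min(z[tz[[3]]]), max(z[tz[[1]]]))
})

test_that("masks are permutation-equivariant under voxel relabelling", {
  set.seed(11)
  z <- rnorm(12)
  perm <- sample(12)
  m1 <- select_voxels(z, "threshold", z_min = 0)
  m2 <- select_voxels(z[perm], "threshold", z_min = 0)
  expect_identical(as.logical(m1)[perm], as.logical(m2))
})

test_that("noise degrades pattern recovery monotonically", {
  spec <- tiny_spec(seed = 4L)
  ss <- make_stimulus_set(spec)
  sq <- make_scan_sequence(ss, spec)
  pt <- sample_ground_truth_patterns(
    representation_model(n_voxels = 30L, n_units = 50L,
                         c_global = c(NoFace = 0.2, SameFace = 0.2),
                         c_pair = c(NoFace = 0.2, SameFace = -0.2),
                         pattern_noise_sd = 0, seed = 5L), ss)
  recov <- vapply(c(0, 1, 6), function(sg) {
    bold <- simulate_bold(pt, sq, noise = noise_spec(sigma = sg,
                                                     drift_amplitude = 0,
                                                     run_jitter_sd = 0,
                                                     seed = 6L))
    designs <- lapply(sort(unique(sq$run)), function(r)
      build_design_matrix(sq[sq$run == r, ], hrf_spec(), 2,
                          ncol(bold$data[[r]])))
    est <- fit_glm(bold, designs, prewhiten = "none")
    mean(diag(cor(t(est$beta[rownames(pt$pattern), ]), t(pt$pattern))))
  }, numeric(1))
  expect_gt(recov[1], 0.999)
  expect_true(all(diff(recov) < 0))
})
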