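# Shared fixtures: small designs and models kept cheap enough for unit tests.

tiny_spec <- function(seed = 1L) {
  # 2 conditions x 2 pairs, 1 pair per subcategory: 8 scenes
  design_spec(n_pairs_total = 4L, n_pairs_per_condition = 2L,
              conditions = c("NoFace", "SameFace"),
              n_runs = 2L, n_null_interleaved = 4L,
              n_null_lead_in = 1L, n_null_lead_out = 1L,
              target_rate = 0, seed = seed)
}

small_spec <- function(seed = 1L, n_runs = 2L) {
  # full 36-pair design but few runs, for mid-weight tests
  design_spec(n_runs = n_runs, seed = seed)
}

# one-condition wide design: many pairs for factor-model Monte Carlo oracles
wide_spec <- function(n_pairs = 200L, seed = 1L) {
  design_spec(n_pairs_total = n_pairs, n_pairs_per_condition = n_pairs,
              conditions = "NoFace", n_runs = 2L, target_rate = 0,
              seed = seed)
}

wide_model <- function(cg, cp, n_voxels = 150L, n_units = 400L, seed = 1L,
                       pattern_noise_sd = 0) {
  representation_model(n_voxels = n_voxels, n_units = n_units,
                       c_global = c(NoFace = cg), c_pair = c(NoFace = cp),
                       pattern_noise_sd = pattern_noise_sd,
                       baseline_condition = "NoFace", seed = seed)
}

# closed-form OLS oracle: beta, se via explicit (X'X)^{-1} X'y
ols_oracle <- function(X, y) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dof
  list(beta = drop(beta), se = sqrt(diag(XtXinv) * sigma2), dof = dof)
}

# brute-force difference scores: all-pairs loop straight off the z matrix
brute_force_scores <- function(z, condition) {
  n <- nrow(z)
  vapply(seq_len(n), function(i) {
    cells <- c()
    for (j in seq_len(n)) {
      if (j == i || condition[j] != condition[i]) next
      cells <- c(cells, z[i, j], z[j, i])
    }
    z[i, i] - mean(cells)
  }, numeric(1))
}

expect_no_error <- function(expr) expect_error(expr, NA)
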