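#' Classifier-based face evidence for scene-viewing patterns
#'
#' Trains an L2-regularized logistic regression (LIBLINEAR-style objective
#' `0.5 * ||w||^2 + C * sum log(1 + exp(-y f))`, regularization parameter
#' `C = 1`, unpenalized intercept) to discriminate face from scene
#' localizer block patterns, then scores each scene-viewing pattern. Every
#' pattern is z-scored across voxels before training and prediction. Face
#' evidence is the logit of the face-class probability after clipping to
#' `[1e-6, 1 - 1e-6]`; evidence 0 corresponds to probability 0.5.
#'
#' @param train_patterns training patterns (examples x voxels), e.g.
#'   localizer block estimates
#' @param train_labels character/factor labels with exactly two classes;
#'   the class named `positive_class` is scored
#' @param scene_patterns patterns to score (scenes x voxels, row-named)
#' @param positive_class label treated as the "face" class
#' @param C LIBLINEAR regularization parameter
#' @return a `face_evidence` data frame: `scene`, `predicted`, `p_face`,
#'   `evidence`
#' @export
face_evidence <- function(train_patterns, train_labels, scene_patterns,
                          positive_class = "face", C = 1) {
  lab <- as.character(train_labels)
  classes <- sort(unique(lab))
  if (length(classes) != 2L)
    stop("training labels must contain exactly two classes", call. = FALSE)
  if (!positive_class %in% classes)
    stop("positive_class not present in training labels", call. = FALSE)
  if (min(table(lab)) < 2L)
    stop("need >= 2 training examples per class", call. = FALSE)
  Xtr <- zscore_rows(train_patterns)
  Xte <- zscore_rows(scene_patterns)
  y <- ifelse(lab == positive_class, 1, -1)
  w <- ridge_logistic_liblinear(Xtr, y, C = C)
  eta <- drop(cbind(1, Xte) %*% w)
  p <- plogis(eta)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  data.frame(scene = if (!is.null(rownames(scene_patterns)))
    rownames(scene_patterns) else seq_len(nrow(Xte)),
    predicted = ifelse(eta > 0, positive_class,
                       setdiff(classes, positive_class)),
    p_face = p,
    evidence = qlogis(p),
    row.names = NULL, stringsAsFactors = FALSE)
}

zscore_rows <- function(mat) {
  sds <- apply(mat, 1, sd)
  if (any(sds == 0))
    stop("zero-variance pattern in row(s): ",
         paste(which(sds == 0), collapse = ", "),
         "; z-scoring undefined", call. = FALSE)
  t(scale(t(mat)))[, , drop = FALSE]
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Newton iterations for 0.5 w'w + C sum log(1 + exp(-y (b + x'w)));
# intercept b unpenalized. Returns c(b, w).
ridge_logistic_liblinear <- function(X, y, C = 1, max_iter = 100,
                                     tol = 1e-10) {
  Xb <- cbind(1, X)
  p <- ncol(Xb)
  pen <- diag(c(0, rep(1, p - 1)))
  w <- numeric(p)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(Xb %*% w)
    mu <- plogis(y * eta)
    grad <- pen %*% w - C * drop(crossprod(Xb, y * (1 - mu)))
    wgt <- mu * (1 - mu)
    H <- pen + C * crossprod(Xb * wgt, Xb)
    step <- solve(H, grad)
    w_new <- w - step
    obj <- 0.5 * sum((pen %*% w_new) * w_new) +
      C * sum(softplus(-y * drop(Xb %*% w_new)))
    # halve the step if the objective did not improve
    half <- 0
    while (obj > obj_old + 1e-12 && half < 30) {
      step <- step / 2
      w_new <- w - step
      obj <- 0.5 * sum((pen %*% w_new) * w_new) +
        C * sum(softplus(-y * drop(Xb %*% w_new)))
      half <- half + 1
    }
    done <- abs(obj_old - obj) < tol * (abs(obj) + 1)
    w <- w_new
    obj_old <- obj
    if (done) break
  }
  w
}
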