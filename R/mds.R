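#' Classical MDS embedding of the representational space
#'
#' Builds a full symmetric scene-by-scene dissimilarity matrix from the
#' cross-set similarity matrix and embeds it in two dimensions with
#' classical (Torgerson) MDS. Within-set cells, which are never computed,
#' are imputed from the across-set symmetric counterpart
#' (`(z[i,j] + z[j,i]) / 2` at the pair level); the default dissimilarity
#' rule is `d = z_max - z` over the observed cells. The embedding is
#' deterministic up to rotation/reflection and centred at the origin.
#'
#' @param simmat a `similarity_matrix`
#' @param dissimilarity either the string "zmax_minus_z" (default) or a
#'   function mapping the full symmetric z matrix to a dissimilarity matrix
#' @param pairs optional subset of pair ids to embed (e.g. the pairs of one
#'   or two conditions, as in a representational-space figure)
#' @return an `mds_embedding`: list with `points` (scene x 2, row-named),
#'   `stress` (Kruskal stress-1), `eig`
#' @export
mds_embed <- function(simmat, dissimilarity = "zmax_minus_z", pairs = NULL) {
  z <- simmat$z
  if (is.null(pairs)) pairs <- simmat$pairs
  idx <- match(pairs, simmat$pairs)
  if (anyNA(idx)) stop("unknown pair id(s)", call. = FALSE)
  z <- z[idx, idx, drop = FALSE]
  np <- length(pairs)
  if (2L * np < 3L) stop("need at least 3 scenes to embed", call. = FALSE)
  # full 2n x 2n symmetric z: scenes ordered (A scenes, B scenes) by pair
  n2 <- 2L * np
  zz <- matrix(NA_real_, n2, n2)
  a <- seq_len(np); b <- np + seq_len(np)
  zz[a, b] <- z
  zz[b, a] <- t(z)
  within <- (z + t(z)) / 2 # imputed within-set counterpart
  zz[a, a] <- within
  zz[b, b] <- within
  diag(zz) <- max(zz[row(zz) != col(zz)])
  d <- if (is.function(dissimilarity)) dissimilarity(zz)
  else if (identical(dissimilarity, "zmax_minus_z"))
    max(zz[row(zz) != col(zz)]) - zz
  else stop("unknown dissimilarity rule", call. = FALSE)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  fit <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  pts <- fit$points
  rownames(pts) <- c(paste0(pairs, ":A"), paste0(pairs, ":B"))
  dhat <- as.matrix(dist(pts))
  off <- row(d) != col(d)
  stress <- sqrt(sum((dhat[off] - d[off])^2) / sum(d[off]^2))
  structure(list(points = pts, stress = stress, eig = fit$eig,
                 pairs = pairs),
            class = "mds_embedding")
}

#' Mean embedded pairmate vs nonpairmate distances
#'
#' Convenience summary of an embedding: clustering corresponds to the mean
#' pairmate distance falling below the mean nonpairmate distance, repulsion
#' to the reverse.
#'
#' @param embedding an `mds_embedding`
#' @return list with `pairmate`, `nonpairmate` mean distances
#' @export
embedding_distances <- function(embedding) {
  pts <- embedding$points
  np <- length(embedding$pairs)
  d <- as.matrix(dist(pts))
  a <- seq_len(np); b <- np + seq_len(np)
  pm <- mean(d[cbind(a, b)])
  mask <- matrix(TRUE, np, np); diag(mask) <- FALSE
  npm <- mean(c(d[a, b][mask], d[a, a][mask], d[b, b][mask]))
  list(pairmate = pm, nonpairmate = npm)
}
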