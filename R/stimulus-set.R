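#' Build the stimulus set: pairs, conditions, set halves, associates
#'
#' Randomly (but deterministically, given `spec$seed`) assigns scene pairs to
#' learning conditions while balancing scene subcategory within condition,
#' splits each pair across the two presentation set halves (pairmates never
#' share a half), and assigns face and object associates. Same Face pairmates
#' share one face, Different Face pairmates receive distinct faces, No Face
#' scenes none; every scene gets a unique object.
#'
#' @param spec a [design_spec()]
#' @return a `stimulus_set`: a data frame with one row per scene and columns
#'   `scene`, `pair`, `condition`, `subcategory`, `set_half`, `face`,
#'   `object`, with the spec attached as an attribute.
#' @export
make_stimulus_set <- function(spec = design_spec()) {
  validate_design_spec(spec)
  n_pair <- spec$n_pairs_total
  n_cond <- length(spec$conditions)
  n_sub <- length(spec$subcategories)
  with_substream(spec$seed, "design", {
    pair_id <- sprintf("pair%02d", seq_len(n_pair))
    # subcategories are a fixed property of the pairs (equal overall split);
    # conditions are dealt at random within each subcategory so that every
    # condition receives the same number of pairs of each subcategory
    subcat <- rep(spec$subcategories, length.out = n_pair)
    per_cell <- spec$n_pairs_per_condition %/% n_sub
    cond <- character(n_pair)
    for (sc in spec$subcategories) {
      idx <- sample(which(subcat == sc))
      cond[idx] <- rep(spec$conditions, each = per_cell)
    }
    # two scenes per pair, dealt at random into presentation set halves
    half_first <- sample(c("A", "B"), n_pair, replace = TRUE)
    scenes <- data.frame(
      scene = sprintf("%s_s%d", rep(pair_id, each = 2L), rep(1:2, n_pair)),
      pair = rep(pair_id, each = 2L),
      condition = rep(cond, each = 2L),
      subcategory = rep(subcat, each = 2L),
      set_half = as.vector(rbind(half_first,
                                 ifelse(half_first == "A", "B", "A"))),
      stringsAsFactors = FALSE)
    # associates: faces shared within SameFace pairs, distinct within
    # DifferentFace pairs, absent otherwise; objects unique per scene
    scenes$face <- NA_character_
    face_counter <- 0L
    for (p in pair_id) {
      rows <- which(scenes$pair == p)
      pc <- cond[match(p, pair_id)]
      if (identical(pc, "SameFace")) {
        face_counter <- face_counter + 1L
        scenes$face[rows] <- sprintf("face%03d", face_counter)
      } else if (identical(pc, "DifferentFace")) {
        scenes$face[rows] <- sprintf("face%03d", face_counter + 1:2)
        face_counter <- face_counter + 2L
      }
    }
    scenes$object <- sprintf("obj%03d", sample(nrow(scenes)))
    structure(scenes, class = c("stimulus_set", "data.frame"), spec = spec)
  })
}

#' Validate stimulus-set invariants
#'
#' Checks: every scene in exactly one pair; pairmates share condition and
#' subcategory but never a set half; Same Face pairmates share one face;
#' Different Face pairmates have distinct faces; all objects distinct;
#' subcategory balance within condition.
#'
#' @param stimset a `stimulus_set`
#' @return invisibly `TRUE`; stops on violation
#' @export
validate_stimulus_set <- function(stimset) {
  spec <- attr(stimset, "spec")
  fail <- function(...) stop("invalid stimulus_set: ", ..., call. = FALSE)
  if (anyDuplicated(stimset$scene)) fail("duplicated scene ids")
  sizes <- table(stimset$pair)
  if (any(sizes != 2L)) fail("every pair must own exactly 2 scenes")
  if (anyDuplicated(stimset$object)) fail("objects must be unique per scene")
  for (p in unique(stimset$pair)) {
    rows <- stimset[stimset$pair == p, ]
    if (length(unique(rows$condition)) != 1L ||
        length(unique(rows$subcategory)) != 1L)
      fail("pairmates of ", p, " differ in condition or subcategory")
    if (rows$set_half[1] == rows$set_half[2])
      fail("pairmates of ", p, " share a set half")
    if (identical(rows$condition[1], "SameFace") &&
        rows$face[1] != rows$face[2])
      fail("SameFace pairmates of ", p, " must share a face")
    if (identical(rows$condition[1], "DifferentFace") &&
        rows$face[1] == rows$face[2])
      fail("DifferentFace pairmates of ", p, " must have distinct faces")
    if (identical(rows$condition[1], "NoFace") && !all(is.na(rows$face)))
      fail("NoFace scenes of ", p, " must have no face")
  }
  tab <- table(stimset$condition[!duplicated(stimset$pair)],
               stimset$subcategory[!duplicated(stimset$pair)])
  if (length(unique(as.vector(tab))) != 1L)
    fail("subcategory counts unbalanced across conditions")
  if (!is.null(spec)) {
    if (length(unique(stimset$pair)) != spec$n_pairs_total)
      fail("pair count does not match spec")
  }
  invisible(TRUE)
}

pairs_of <- function(stimset) {
  stimset[!duplicated(stimset$pair),
          c("pair", "condition", "subcategory"), drop = FALSE]
}

# scene ids of a given set half, ordered by pair id
half_scenes <- function(stimset, half) {
  rows <- stimset[stimset$set_half == half, ]
  rows$scene[order(rows$pair)]
}
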