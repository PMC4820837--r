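#' Generate the associative learning schedule
#'
#' Produces the day-1 scene-face schedule (two study-test cycles over random
#' halves of the Same/Different Face pairs, followed by four whole-set test
#' blocks, so an error-free learner is tested on each association exactly six
#' times) and the post-scan scene-object schedule (three study-test cycles;
#' each cycle partitions the pairs into sets of 24 trials balanced by
#' condition). Test trials carry three choices: the target, the pairmate
#' foil, and a nonpairmate foil drawn from the same condition and, where a
#' study block precedes the test, from that immediately preceding study set.
#' Day-1 Same Face test trials instead carry two nonpairmate foils (the
#' pairmate's face *is* the target face).
#'
#' Adaptive day-1 retesting (extra blocks until criterion) is only generated
#' when a simulated learner is attached; the default schedule assumes an
#' error-free learner.
#'
#' @param stimset a `stimulus_set`
#' @param spec the matching [design_spec()]
#' @return a `learning_schedule`: list with data frames `day1` (scene-face)
#'   and `scene_object`
#' @export
make_learning_schedule <- function(stimset, spec = attr(stimset, "spec")) {
  validate_stimulus_set(stimset)
  with_substream(spec$seed, "schedule", {
    structure(list(day1 = schedule_day1(stimset),
                   scene_object = schedule_scene_object(stimset)),
              class = "learning_schedule", spec = spec)
  })
}

# sample() semantics change when x has length 1; these never do
sample1 <- function(x) x[sample.int(length(x), 1L)]
sample_n <- function(x, n) x[sample.int(length(x), n)]

# faces available as nonpairmate foils for a cue: same condition, other pairs
foil_faces <- function(stimset, cue_row, pool_scenes) {
  pool <- stimset[stimset$scene %in% pool_scenes &
                    stimset$condition == cue_row$condition &
                    stimset$pair != cue_row$pair, ]
  unique(pool$face[!is.na(pool$face)])
}

scene_face_test_block <- function(stimset, scenes, pool_scenes, cycle, block) {
  scenes <- sample(scenes)
  rows <- stimset[match(scenes, stimset$scene), ]
  foil1 <- foil2 <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    cue <- rows[i, ]
    pool <- foil_faces(stimset, cue, pool_scenes)
    pool <- setdiff(pool, cue$face)
    if (identical(cue$condition, "DifferentFace")) {
      mate <- stimset[stimset$pair == cue$pair & stimset$scene != cue$scene, ]
      foil1[i] <- mate$face
      foil2[i] <- sample1(setdiff(pool, mate$face))
    } else { # SameFace: pairmate foil would equal the target; two nonpairmates
      fs <- sample_n(pool, 2L)
      foil1[i] <- fs[1]
      foil2[i] <- fs[2]
    }
  }
  data.frame(phase = "test", cycle = cycle, block = block,
             trial = seq_len(nrow(rows)), scene = rows$scene,
             condition = rows$condition, target = rows$face,
             foil_pairmate = ifelse(rows$condition == "DifferentFace",
                                    foil1, NA_character_),
             foil_nonpairmate_1 = ifelse(rows$condition == "DifferentFace",
                                         foil2, foil1),
             foil_nonpairmate_2 = ifelse(rows$condition == "DifferentFace",
                                         NA_character_, foil2),
             stringsAsFactors = FALSE)
}

schedule_day1 <- function(stimset) {
  face_pairs <- pairs_of(stimset)
  face_pairs <- face_pairs[face_pairs$condition %in%
                             c("DifferentFace", "SameFace"), ]
  if (nrow(face_pairs) == 0L)
    return(data.frame())
  out <- list()
  # two study-test cycles over random halves, balanced by condition
  for (cyc in 1:2) {
    halves <- unlist(lapply(split(face_pairs$pair, face_pairs$condition),
                            function(p) {
                              s <- sample(p)
                              split(s, rep(1:2, each = length(s) / 2))
                            }), recursive = FALSE)
    grp1 <- unlist(halves[grepl("\\.1$", names(halves))], use.names = FALSE)
    grp2 <- unlist(halves[grepl("\\.2$", names(halves))], use.names = FALSE)
    for (g in list(grp1, grp2)) {
      scenes <- stimset$scene[stimset$pair %in% g]
      st <- stimset[match(sample(scenes), stimset$scene), ]
      out[[length(out) + 1L]] <- data.frame(
        phase = "study", cycle = cyc, block = NA_integer_,
        trial = seq_len(nrow(st)), scene = st$scene,
        condition = st$condition, target = st$face,
        foil_pairmate = NA_character_, foil_nonpairmate_1 = NA_character_,
        foil_nonpairmate_2 = NA_character_, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <-
        scene_face_test_block(stimset, scenes, pool_scenes = scenes,
                              cycle = cyc, block = NA_integer_)
    }
  }
  # four whole-set test blocks; foils drawn from the whole condition
  all_scenes <- stimset$scene[stimset$pair %in% face_pairs$pair]
  for (b in 1:4)
    out[[length(out) + 1L]] <-
      scene_face_test_block(stimset, all_scenes, pool_scenes = all_scenes,
                            cycle = NA_integer_, block = b)
  do.call(rbind, out)
}

schedule_scene_object <- function(stimset) {
  prs <- pairs_of(stimset)
  n_cond <- length(unique(prs$condition))
  pairs_per_set <- 12L # 12 pairs = 24 trials per set
  if (nrow(prs) %% pairs_per_set != 0L || pairs_per_set %% n_cond != 0L)
    pairs_per_set <- nrow(prs) # reduced designs: a single set of all pairs
  per_cond <- pairs_per_set %/% n_cond
  n_sets <- nrow(prs) %/% pairs_per_set
  if (n_sets * pairs_per_set != nrow(prs) ||
      per_cond * n_cond != pairs_per_set)
    stop("scene-object schedule requires pair counts divisible into ",
         "condition-balanced sets", call. = FALSE)
  out <- list()
  for (cyc in 1:3) {
    # random partition of pairs into sets, balanced by condition
    assign <- unlist(lapply(split(prs$pair, prs$condition), function(p) {
      setNames(rep(seq_len(n_sets), each = per_cond), sample(p))
    }))
    names(assign) <- sub("^[^.]*\\.", "", names(assign))
    for (s in seq_len(n_sets)) {
      set_pairs <- names(assign)[assign == s]
      scenes <- stimset$scene[stimset$pair %in% set_pairs]
      st <- stimset[match(sample(scenes), stimset$scene), ]
      out[[length(out) + 1L]] <- data.frame(
        phase = "study", cycle = cyc, set = s, trial = seq_len(nrow(st)),
        scene = st$scene, condition = st$condition, target = st$object,
        foil_pairmate = NA_character_, foil_nonpairmate = NA_character_,
        stringsAsFactors = FALSE)
      te <- stimset[match(sample(scenes), stimset$scene), ]
      foil_np <- vapply(seq_len(nrow(te)), function(i) {
        cand <- te[te$condition == te$condition[i] & te$pair != te$pair[i], ]
        sample1(cand$object)
      }, character(1))
      mate_obj <- vapply(seq_len(nrow(te)), function(i) {
        stimset$object[stimset$pair == te$pair[i] &
                         stimset$scene != te$scene[i]]
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        phase = "test", cycle = cyc, set = s, trial = seq_len(nrow(te)),
        scene = te$scene, condition = te$condition, target = te$object,
        foil_pairmate = mate_obj, foil_nonpairmate = foil_np,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Validate learning-schedule invariants
#'
#' @param schedule a `learning_schedule`
#' @param stimset the `stimulus_set` it was generated from
#' @return invisibly `TRUE`; stops on violation
#' @export
validate_learning_schedule <- function(schedule, stimset) {
  fail <- function(...) stop("invalid learning_schedule: ", ..., call. = FALSE)
  d1 <- schedule$day1
  if (nrow(d1)) {
    tests <- d1[d1$phase == "test", ]
    n_tests <- table(tests$scene)
    if (any(n_tests < 6L)) fail("day-1 schedule tests an association < 6 times")
    sf <- tests[tests$condition == "SameFace", ]
    tgt_face <- setNames(stimset$face, stimset$scene)
    if (any(sf$foil_nonpairmate_1 == tgt_face[sf$scene], na.rm = TRUE) ||
        any(sf$foil_nonpairmate_2 == tgt_face[sf$scene], na.rm = TRUE))
      fail("SameFace foil equals the target (pairmate) face")
  }
  so <- schedule$scene_object
  tests <- so[so$phase == "test", ]
  if (length(unique(so$cycle)) != 3L) fail("need 3 scene-object cycles")
  obj_of <- setNames(stimset$object, stimset$scene)
  mate_of <- vapply(tests$scene, function(s) {
    stimset$scene[stimset$pair == stimset$pair[stimset$scene == s] &
                    stimset$scene != s]
  }, character(1))
  if (!all(tests$target == obj_of[tests$scene]))
    fail("scene-object targets are wrong")
  if (!all(tests$foil_pairmate == obj_of[mate_of]))
    fail("pairmate foils are not the pairmate's object")
  cond_of_obj <- setNames(stimset$condition, stimset$object)
  if (!all(cond_of_obj[tests$foil_nonpairmate] == tests$condition))
    fail("nonpairmate foils cross conditions")
  # balanced-by-condition 24-trial sets; foils come from the same set
  for (cyc in unique(so$cycle)) for (s in unique(so$set[so$cycle == cyc])) {
    blk <- so[so$cycle == cyc & so$set == s, ]
    study <- blk[blk$phase == "study", ]
    te <- blk[blk$phase == "test", ]
    if (nrow(study) != nrow(te))
      fail("study and test set sizes differ")
    if (length(unique(table(study$condition))) != 1L)
      fail("study set not balanced by condition")
    if (!all(te$foil_nonpairmate %in% obj_of[study$scene]))
      fail("nonpairmate foil not from the immediately preceding study set")
  }
  invisible(TRUE)
}
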