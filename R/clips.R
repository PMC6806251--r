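# Clip segmentation and dataset assembly: annotation segments are cut
# to bounded action clips (segments shorter than 0.2 s are dropped as
# too short to express an action; segments longer than 4 s are divided
# into consecutive 4 s pieces, keeping a trailing remainder when it is
# itself at least 0.2 s), classes are balanced by seeded undersampling,
# and train/test splits are made subject-wise so no subject leaks
# across the split.

#' Segment annotation segments into bounded action clips
#'
#' @param segments List of [annotation_segment()] objects.
#' @param fps Frames per second.
#' @param min_s Minimum clip duration in seconds (shorter clips are
#'   dropped). At 30 fps the default 0.2 s equals 6 frames.
#' @param max_s Maximum clip duration in seconds; longer segments are
#'   cut left-to-right into `max_s` pieces.
#' @return data.frame with columns `clip_id`, `subject_id`,
#'   `start_frame`, `end_frame`, `label`, `n_frames`.
#' @export
segment_clips <- function(segments, fps = 30, min_s = 0.2, max_s = 4.0) {
  min_f <- as.integer(ceiling(min_s * fps))
  max_f <- as.integer(round(max_s * fps))
  rows <- list()
  for (seg in segments) {
    len <- seg$end_frame - seg$start_frame + 1L
    if (len < min_f) next
    starts <- seq.int(seg$start_frame, seg$end_frame, by = max_f)
    for (s in starts) {
      e <- min(s + max_f - 1L, seg$end_frame)
      if (e - s + 1L < min_f) next  # trailing remainder too short
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = seg$subject_id, start_frame = s, end_frame = e,
        label = seg$label, n_frames = e - s + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(clip_id = character(0), subject_id = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      label = character(0), n_frames = integer(0)))
  df <- do.call(rbind, rows)
  df <- cbind(clip_id = sprintf("clip_%05d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  df
}

#' Balance classes by seeded undersampling
#'
#' Classes whose clip count exceeds `cap` are reduced to exactly `cap`
#' clips by uniform sampling without replacement; smaller classes are
#' untouched. Deterministic for a fixed seed.
#'
#' @param clips data.frame with a `label` column (e.g. from
#'   [segment_clips()]).
#' @param cap Maximum clips per class (> 0).
#' @param seed RNG seed.
#' @return Subset of `clips`, original row order preserved.
#' @export
balance_classes <- function(clips, cap, seed = 1L) {
  if (cap <= 0) stop("cap must be > 0")
  keep <- with_local_seed(seed, {
    idx <- logical(nrow(clips))
    for (lab in unique(clips$label)) {
      rows <- which(clips$label == lab)
      if (length(rows) > cap) rows <- sort(sample(rows, cap))
      idx[rows] <- TRUE
    }
    idx
  })
  clips[keep, , drop = FALSE]
}

#' Subject-wise train/test split
#'
#' @param clips data.frame with a `subject_id` column.
#' @param test_subject_ids Subjects held out for testing.
#' @return List with `train` and `test` data.frames; no subject appears
#'   on both sides and the union is the input. Warns about test ids
#'   absent from the data.
#' @export
split_by_subject <- function(clips, test_subject_ids) {
  missing_ids <- setdiff(test_subject_ids, unique(clips$subject_id))
  if (length(missing_ids))
    warning("test subject id(s) absent from data: ",
            paste(missing_ids, collapse = ", "))
  is_test <- clips$subject_id %in% test_subject_ids
  list(train = clips[!is_test, , drop = FALSE],
       test = clips[is_test, , drop = FALSE])
}

#' Extract per-clip keypoint sequences from a fused track
#'
#' For each clip row, collects the track's keypoints over the clip's
#' frame interval; frames where the track has no detection become
#' zero-confidence keypoints (rendered as zero heatmaps downstream).
#'
#' @param track A track from [fuse_to_track()].
#' @param clips data.frame from [segment_clips()].
#' @return List of clips `list(clip_id, subject_id, label, keypoints)`
#'   with `keypoints` an `F x 17 x 3` array.
#' @export
extract_clip_keypoints <- function(track, clips) {
  frames <- vapply(track$detections, `[[`, integer(1), "frame")
  lookup <- setNames(seq_along(frames), frames)
  lapply(seq_len(nrow(clips)), function(i) {
    fs <- clips$start_frame[i]:clips$end_frame[i]
    kparr <- array(0, dim = c(length(fs), 17, 3))
    for (k in seq_along(fs)) {
      j <- lookup[as.character(fs[k])]
      if (!is.na(j)) kparr[k, , ] <- track$detections[[j]]$keypoints
    }
    list(clip_id = clips$clip_id[i], subject_id = clips$subject_id[i],
         label = clips$label[i], keypoints = kparr)
  })
}
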