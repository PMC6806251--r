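# Readers and writers for the on-disk formats:
#   detections.jsonl  one frame per line:
#     {"frame": f, "detections": [{"box": [x0,y0,x1,y1], "box_conf": c,
#      "keypoints": [[x,y,c] x 17], "appearance": [f x D] (optional)}]}
#   annotations.csv   header subject_id,start_frame,end_frame,label
#   tracklets.csv     tracklet_id,frame,det_index
#   track.csv         frame,det_index,tracklet_id
#   pose-map container: serialized list of arrays keyed by clip id, with
#     a JSON sidecar of labels.

#' Read a detection stream from a JSON-lines file
#'
#' Each line holds one frame record. Frames must appear in strictly
#' increasing frame order; each detection must carry exactly 17
#' keypoints. Parse failures report the offending line number.
#'
#' @param path Path to a `.jsonl` file.
#' @return List of [frame_detections()], ascending in frame index.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stream <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error at line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(rec$frame))
      stop("parse error at line ", i, ": missing 'frame' field")
    dets <- lapply(seq_along(rec$detections), function(k) {
      dr <- rec$detections[[k]]
      kp <- dr$keypoints
      if (length(kp) != 17L)
        stop("parse error at line ", i, ": detection ", k, " has ",
             length(kp), " keypoints (expected 17)", call. = FALSE)
      kpm <- do.call(rbind, lapply(kp, function(p) as.numeric(unlist(p))))
      if (ncol(kpm) != 3L)
        stop("parse error at line ", i,
             ": keypoints must be [x, y, conf] triplets", call. = FALSE)
      app <- if (!is.null(dr$appearance)) as.numeric(unlist(dr$appearance))
      detection(rec$frame, as.numeric(unlist(dr$box)),
                as.numeric(dr$box_conf), kpm, appearance = app,
                det_index = k - 1L)
    })
    stream[[i]] <- frame_detections(rec$frame, dets)
  }
  validate_stream(stream)
  stream
}

#' Write a detection stream to a JSON-lines file
#'
#' Numbers are serialized with 17 significant digits (the schema is
#' simple enough to emit directly) so that a round trip preserves
#' coordinates bit-for-bit.
#'
#' @param stream List of [frame_detections()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(stream, path) {
  validate_stream(stream)
  num <- function(x) sprintf("%.17g", x)
  arr <- function(x) paste0("[", paste(num(x), collapse = ","), "]")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fd in stream) {
    dets <- vapply(fd$detections, function(d) {
      kp <- paste(vapply(seq_len(17), function(r)
        arr(d$keypoints[r, ]), character(1)), collapse = ",")
      app <- if (!is.null(d$appearance))
        paste0(',"appearance":', arr(d$appearance)) else ""
      paste0('{"box":', arr(d$box), ',"box_conf":', num(d$box_conf),
             ',"keypoints":[', kp, "]", app, "}")
    }, character(1))
    writeLines(paste0('{"frame":', fd$frame, ',"detections":[',
                      paste(dets, collapse = ","), "]}"), con)
  }
  invisible(path)
}

#' Read action annotation segments from CSV
#'
#' Expects a header `subject_id,start_frame,end_frame,label`. Labels are
#' restricted to the five action classes; overlapping segments within a
#' subject are rejected.
#'
#' @param path Path to a CSV file.
#' @return List of [annotation_segment()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "start_frame", "end_frame", "label")
  if (!all(needed %in% names(df)))
    stop("annotations CSV must have header: ", paste(needed, collapse = ","))
  segs <- lapply(seq_len(nrow(df)), function(i)
    annotation_segment(df$subject_id[i], df$start_frame[i],
                       df$end_frame[i], df$label[i]))
  check_no_overlap(segs)
  segs
}

check_no_overlap <- function(segs) {
  by_subj <- split(segs, vapply(segs, `[[`, character(1), "subject_id"))
  for (subj in names(by_subj)) {
    ss <- by_subj[[subj]]
    iv <- cbind(vapply(ss, `[[`, integer(1), "start_frame"),
                vapply(ss, `[[`, integer(1), "end_frame"))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping annotation segments for subject '", subj, "'")
  }
  invisible(segs)
}

#' Write annotation segments to CSV
#'
#' @param segments List of [annotation_segment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segments, path) {
  df <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    start_frame = vapply(segments, `[[`, integer(1), "start_frame"),
    end_frame = vapply(segments, `[[`, integer(1), "end_frame"),
    label = vapply(segments, `[[`, character(1), "label"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write tracklets to CSV (tracklet_id, frame, det_index)
#' @param tracklets List of tracklet objects from [build_tracklets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracklets <- function(tracklets, path) {
  rows <- do.call(rbind, lapply(tracklets, function(tr) {
    data.frame(tracklet_id = tr$id,
               frame = vapply(tr$detections, `[[`, integer(1), "frame"),
               det_index = vapply(tr$detections, `[[`, integer(1),
                                  "det_index"))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fused track to CSV (frame, det_index, tracklet_id)
#' @param track A track object from [fuse_to_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  df <- data.frame(
    frame = vapply(track$detections, `[[`, integer(1), "frame"),
    det_index = vapply(track$detections, `[[`, integer(1), "det_index"),
    tracklet_id = track$detection_tracklet)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pose-evolution maps to a container with a JSON label sidecar
#'
#' Maps are stored as a serialized named list of arrays keyed by clip id
#' (R serialization, version 3); labels and array dimensions go to
#' `<path>.labels.json` so the label table is readable without loading
#' the arrays.
#'
#' @param maps Named list of pose-evolution arrays, or a feature matrix
#'   from [featurize_clips()].
#' @param labels Character vector of labels, same length/order as `maps`.
#' @param path Output path for the container.
#' @return `path`, invisibly.
#' @export
write_pose_maps <- function(maps, labels, path) {
  if (is.matrix(maps)) {
    dims <- attr(maps, "map_dim")
    ids <- colnames(maps)
    if (is.null(ids)) ids <- sprintf("clip_%05d", seq_len(ncol(maps)))
    maps <- lapply(seq_len(ncol(maps)), function(j)
      array(maps[, j], dim = dims))
    names(maps) <- ids
  }
  if (length(labels) != length(maps))
    stop("labels must match maps in length")
  if (is.null(names(maps)))
    names(maps) <- sprintf("clip_%05d", seq_along(maps))
  saveRDS(maps, path, version = 3)
  sidecar <- lapply(seq_along(maps), function(i)
    list(clip_id = names(maps)[i], label = labels[[i]],
         dim = dim(maps[[i]])))
  jsonlite::write_json(sidecar, paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read pose-evolution maps written by [write_pose_maps()]
#' @param path Container path.
#' @return List with elements `maps` (named list of arrays) and
#'   `labels` (character vector).
#' @export
read_pose_maps <- function(path) {
  maps <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".labels.json"))
  labels <- vapply(side, function(s) s$label, character(1))
  names(labels) <- vapply(side, function(s) s$clip_id, character(1))
  list(maps = maps, labels = labels[names(maps)])
}

#' Read a flat key-value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Unknown keys are an error (fail fast). Values are coerced to the type
#' of the corresponding [pipeline_config()] default.
#'
#' @param path Path to the config file.
#' @return A [pipeline_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- pipeline_config()
  known <- setdiff(names(defaults), "classifier")
  vals <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known)
      stop("unknown configuration key '", key, "'")
    vals[[key]] <- as.numeric(val)
  }
  do.call(pipeline_config, vals)
}

#' Write a metadata block alongside an output artifact
#'
#' Records the configuration hash, the seed and the package version so
#' that a rerun with identical config and seed can be verified to
#' reproduce the artifact.
#'
#' @param path Path of the artifact; metadata goes to `<path>.meta.json`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed used by the producing stage.
#' @return The metadata list, invisibly.
#' @export
write_run_metadata <- function(path, config, seed = config$seed) {
  meta <- list(config_hash = config_hash(config), seed = seed,
               package = "poseaction",
               version = as.character(utils::packageVersion("poseaction")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(meta)
}

config_hash <- function(config) {
  canon <- paste(vapply(setdiff(names(config), "classifier"), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 17), collapse = ",")),
    character(1)), collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}
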