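# Domain types: detections, frame streams, annotation segments,
# pipeline configuration.
#
# Geometry conventions used throughout: pixel coordinates, 0-based,
# origin at the top-left corner with y pointing down; boxes are
# half-open intervals [x_min, x_max) x [y_min, y_max), so
# width = x_max - x_min. Frames are indexed from 0 and times derived as
# t = frame / fps.

#' Construct a single-person detection
#'
#' A detection is one person hypothesis in one frame: a bounding box,
#' its confidence, and 17 keypoints in COCO order, optionally carrying a
#' fixed-dimension appearance vector (from a simulator or an embedder).
#'
#' @param frame Integer frame index (>= 0).
#' @param box Numeric length-4 vector `(x_min, y_min, x_max, y_max)` in
#'   pixels; half-open, so `x_min < x_max` and `y_min < y_max`.
#' @param box_conf Box confidence in `[0, 1]`.
#' @param keypoints 17 x 3 numeric matrix with columns `(x, y, conf)` in
#'   COCO keypoint order (see [coco_keypoint_names()]).
#' @param appearance Optional numeric appearance vector.
#' @param det_index Optional 0-based index of the detection within its
#'   frame (used to join against ground truth and CSV outputs).
#' @return An object of class `"detection"`.
#' @export
detection <- function(frame, box, box_conf, keypoints, appearance = NULL,
                      det_index = NA_integer_) {
  d <- structure(list(frame = as.integer(frame), box = as.numeric(box),
                      box_conf = as.numeric(box_conf),
                      keypoints = keypoints, appearance = appearance,
                      det_index = as.integer(det_index)),
                 class = "detection")
  validate_detection(d)
  d
}

validate_detection <- function(d) {
  if (length(d$box) != 4L || anyNA(d$box))
    stop("box must be a numeric vector (x_min, y_min, x_max, y_max)")
  if (d$frame < 0L) stop("frame index must be >= 0")
  if (d$box[1] >= d$box[3] || d$box[2] >= d$box[4])
    stop("degenerate box: require x_min < x_max and y_min < y_max")
  if (is.na(d$box_conf) || d$box_conf < 0 || d$box_conf > 1)
    stop("box_conf must lie in [0, 1]")
  kp <- d$keypoints
  if (!is.matrix(kp) || nrow(kp) != 17L || ncol(kp) != 3L)
    stop("keypoints must be a 17 x 3 matrix (x, y, conf)")
  if (anyNA(kp)) stop("keypoints must not contain NA")
  if (any(kp[, 3] < 0 | kp[, 3] > 1))
    stop("keypoint confidences must lie in [0, 1]")
  if (!is.null(d$appearance) && !is.numeric(d$appearance))
    stop("appearance must be NULL or a numeric vector")
  invisible(d)
}

#' Construct the detections of one frame
#'
#' @param frame Integer frame index.
#' @param detections List of [detection()] objects, all sharing `frame`.
#' @return An object of class `"frame_detections"`.
#' @export
frame_detections <- function(frame, detections = list()) {
  frame <- as.integer(frame)
  for (d in detections)
    if (d$frame != frame)
      stop("all detections must share the frame index of their frame record")
  structure(list(frame = frame, detections = detections),
            class = "frame_detections")
}

#' Validate a detection stream
#'
#' A stream is a list of [frame_detections()] with strictly increasing
#' frame indices; frames may be empty. All appearance vectors present in
#' the stream must share one dimension.
#'
#' @param stream List of `frame_detections`.
#' @return The stream, invisibly; errors on violation.
#' @export
validate_stream <- function(stream) {
  frames <- vapply(stream, function(f) f$frame, integer(1))
  if (length(frames) > 1L && any(diff(frames) <= 0L))
    stop("frame_index values must be strictly increasing across the stream")
  dim_seen <- NULL
  for (fd in stream) {
    for (d in fd$detections) {
      validate_detection(d)
      if (!is.null(d$appearance)) {
        if (is.null(dim_seen)) dim_seen <- length(d$appearance)
        else if (length(d$appearance) != dim_seen)
          stop("appearance vectors of mixed dimensions in stream (",
               dim_seen, " vs ", length(d$appearance), ")")
      }
    }
  }
  invisible(stream)
}

#' Construct an annotation segment
#'
#' @param subject_id Subject identifier (string).
#' @param start_frame,end_frame Inclusive frame interval.
#' @param label One of [action_labels()].
#' @return An object of class `"annotation_segment"`.
#' @export
annotation_segment <- function(subject_id, start_frame, end_frame, label) {
  if (!label %in% action_labels())
    stop("unknown label '", label, "'; allowed labels: ",
         paste(action_labels(), collapse = ", "))
  start_frame <- as.integer(start_frame); end_frame <- as.integer(end_frame)
  if (start_frame > end_frame) stop("start_frame must be <= end_frame")
  structure(list(subject_id = as.character(subject_id),
                 start_frame = start_frame, end_frame = end_frame,
                 label = label),
            class = "annotation_segment")
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage. Defaults follow the
#' package's reference protocol: 30 fps video, IoU gate 0.1 for
#' frame-to-frame matching, tracklet pruning at 5 frames and 50%
#' well-estimated keypoints, appearance affinity threshold 0.7 on
#' L2-normalized embeddings, 3 time-encoding channels, Gaussian heatmap
#' sigma of 2 px at a working resolution of 1/8 of the native frame.
#'
#' @param fps Frames per second.
#' @param iou_threshold Minimum IoU for a frame-to-frame match.
#' @param min_tracklet_length Pruning: minimum tracklet length (frames).
#' @param min_mean_kp_conf Pruning: minimum mean fraction of keypoints
#'   with confidence >= 0.5.
#' @param affinity_threshold Maximum appearance distance (tau) for a
#'   tracklet to be fused into the target track.
#' @param heatmap_sigma Gaussian kernel sigma (px, working resolution).
#' @param C Number of time-encoding channels (>= 2).
#' @param H,W Working-resolution grid of the pose-evolution maps.
#' @param downscale Factor from native to working resolution.
#' @param classifier List of classifier hyperparameters (see
#'   [model_config()]).
#' @param seed Integer seed recorded in output metadata.
#' @return An object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(fps = 30, iou_threshold = 0.1,
                            min_tracklet_length = 5,
                            min_mean_kp_conf = 0.5,
                            affinity_threshold = 0.7, heatmap_sigma = 2,
                            C = 3, H = 135, W = 240, downscale = 0.125,
                            classifier = list(), seed = 1L) {
  num <- c(fps = fps, iou_threshold = iou_threshold,
           min_tracklet_length = min_tracklet_length,
           min_mean_kp_conf = min_mean_kp_conf,
           affinity_threshold = affinity_threshold,
           heatmap_sigma = heatmap_sigma, C = C, H = H, W = W,
           downscale = downscale)
  if (any(!is.finite(num))) stop("all configuration values must be finite")
  if (C < 2) stop("C (time-encoding channels) must be >= 2")
  structure(list(fps = fps, iou_threshold = iou_threshold,
                 min_tracklet_length = min_tracklet_length,
                 min_mean_kp_conf = min_mean_kp_conf,
                 affinity_threshold = affinity_threshold,
                 heatmap_sigma = heatmap_sigma, C = as.integer(C),
                 H = as.integer(H), W = as.integer(W),
                 downscale = downscale, classifier = classifier,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection> frame %d, box [%.1f, %.1f, %.1f, %.1f], conf %.3f\n",
              x$frame, x$box[1], x$box[2], x$box[3], x$box[4], x$box_conf))
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in setdiff(names(x), "classifier"))
    cat(sprintf("  %-20s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}
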