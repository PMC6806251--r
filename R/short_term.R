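# Short-term tracking: link per-frame detections into tracklets by
# intersection-over-union bipartite matching between consecutive frames.
# Matching is between consecutive frames only (no look-ahead); a gap of
# even one frame terminates a tracklet, and recovery across gaps is the
# long-term tracker's job.

#' Intersection over union of two boxes
#'
#' Boxes are half-open `(x_min, y_min, x_max, y_max)` so that width is
#' `x_max - x_min`. Symmetric; 0 for disjoint boxes; 1 iff identical.
#'
#' @param box_a,box_b Numeric length-4 boxes.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(box_a, box_b) {
  area <- function(b) (b[3] - b[1]) * (b[4] - b[2])
  if (area(box_a) <= 0 || area(box_b) <= 0)
    stop("degenerate (zero-area) box")
  iw <- min(box_a[3], box_b[3]) - max(box_a[1], box_b[1])
  ih <- min(box_a[4], box_b[4]) - max(box_a[2], box_b[2])
  inter <- max(0, iw) * max(0, ih)
  inter / (area(box_a) + area(box_b) - inter)
}

iou_matrix <- function(prev_boxes, cur_boxes) {
  n <- nrow(prev_boxes); m <- nrow(cur_boxes)
  M <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      M[i, j] <- box_iou(prev_boxes[i, ], cur_boxes[j, ])
  M
}

#' Optimal one-to-one assignment between two frames' boxes
#'
#' Solves the bipartite assignment maximizing total IoU (equivalently,
#' minimizing the sum of `1 - IoU`) with the Hungarian algorithm; any
#' assigned pair whose IoU falls below `iou_threshold` is demoted to
#' unmatched. Zero-overlap pairs carry the worst finite cost rather than
#' being forbidden, so the assignment is always solvable; the threshold
#' then removes them. Ties between equal-cost assignments resolve to the
#' lowest combined index order (deterministic).
#'
#' @param prev_boxes,cur_boxes Matrices with one box per row (may have
#'   zero rows).
#' @param iou_threshold Minimum IoU for a match, in `[0, 1]`.
#' @return List with `matches` (2-column matrix of 1-based indices
#'   `prev, cur`), `unmatched_prev`, `unmatched_cur` (integer vectors).
#' @export
match_frames <- function(prev_boxes, cur_boxes, iou_threshold = 0.1) {
  if (is.vector(prev_boxes) && length(prev_boxes) == 4L)
    prev_boxes <- matrix(prev_boxes, nrow = 1)
  if (is.vector(cur_boxes) && length(cur_boxes) == 4L)
    cur_boxes <- matrix(cur_boxes, nrow = 1)
  n <- NROW(prev_boxes); m <- NROW(cur_boxes)
  if (n == 0L || m == 0L)
    return(list(matches = matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("prev", "cur"))),
                unmatched_prev = seq_len(n), unmatched_cur = seq_len(m)))
  iou <- iou_matrix(prev_boxes, cur_boxes)
  cost <- 1 - iou
  if (n <= m) {
    assign <- .hungarian_solve(cost) + 1L
    pairs <- cbind(prev = seq_len(n), cur = assign)
  } else {
    assign <- .hungarian_solve(t(cost)) + 1L
    pairs <- cbind(prev = assign, cur = seq_len(m))
  }
  keep <- iou[pairs] >= iou_threshold & iou[pairs] > 0
  matches <- pairs[keep, , drop = FALSE]
  list(matches = matches,
       unmatched_prev = setdiff(seq_len(n), matches[, 1]),
       unmatched_cur = setdiff(seq_len(m), matches[, 2]))
}

new_tracklet <- function(id, det) {
  structure(list(id = id, detections = list(det),
                 start_frame = det$frame, end_frame = det$frame),
            class = "tracklet")
}

finalize_tracklet <- function(tr) {
  confs <- vapply(tr$detections, function(d)
    mean(d$keypoints[, 3] >= 0.5), numeric(1))
  tr$kp_visibility <- mean(confs)
  tr$length <- length(tr$detections)
  tr
}

#' Build tracklets from a detection stream
#'
#' Tracklets are initialized on the first frame and labels propagated
#' forward one frame at a time: each frame's detections are matched to
#' the boxes of tracklets alive in the immediately preceding frame by
#' [match_frames()]; matched detections extend their tracklet, unmatched
#' ones instantiate new tracklets (ids assigned in creation order).
#' Every input detection ends up in exactly one tracklet, and each
#' tracklet covers consecutive frames with one detection per frame.
#'
#' @param stream List of [frame_detections()] (ascending frames).
#' @param iou_threshold Minimum IoU for a frame-to-frame match.
#' @return List of tracklet objects (`id`, `detections`, `start_frame`,
#'   `end_frame`, `length`, `kp_visibility`).
#' @export
build_tracklets <- function(stream, iou_threshold = 0.1) {
  validate_stream(stream)
  tracklets <- list()   # finished
  active <- list()      # tracklets alive in the previous frame
  prev_frame <- -1L
  next_id <- 1L
  for (fd in stream) {
    if (length(active) && fd$frame != prev_frame + 1L) {
      # frame gap: every active tracklet terminates
      tracklets <- c(tracklets, active)
      active <- list()
    }
    dets <- fd$detections
    if (length(active) == 0L) {
      active <- lapply(dets, function(d) {
        tr <- new_tracklet(next_id, d)
        next_id <<- next_id + 1L
        tr
      })
    } else {
      prev_boxes <- do.call(rbind, lapply(active, function(tr)
        tr$detections[[length(tr$detections)]]$box))
      cur_boxes <- if (length(dets))
        do.call(rbind, lapply(dets, `[[`, "box"))
      else matrix(numeric(0), ncol = 4)
      res <- match_frames(prev_boxes, cur_boxes, iou_threshold)
      new_active <- list()
      if (nrow(res$matches)) {
        for (r in seq_len(nrow(res$matches))) {
          ti <- res$matches[r, 1]; di <- res$matches[r, 2]
          tr <- active[[ti]]
          tr$detections[[length(tr$detections) + 1L]] <- dets[[di]]
          tr$end_frame <- dets[[di]]$frame
          new_active[[length(new_active) + 1L]] <- tr
        }
      }
      for (ti in res$unmatched_prev)
        tracklets <- c(tracklets, list(active[[ti]]))
      for (di in res$unmatched_cur) {
        new_active[[length(new_active) + 1L]] <- new_tracklet(next_id,
                                                              dets[[di]])
        next_id <- next_id + 1L
      }
      active <- new_active
    }
    prev_frame <- fd$frame
  }
  tracklets <- c(tracklets, active)
  tracklets <- lapply(tracklets, finalize_tracklet)
  tracklets[order(vapply(tracklets, `[[`, integer(1), "id"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
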