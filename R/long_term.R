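# Long-term tracking: prune tracklets, sample one representative
# detection per tracklet, embed it, and fuse tracklets whose appearance
# distance to a reference tracklet falls below a threshold into a
# single target track.
#
# The affinity is the Euclidean distance between appearance embeddings
# of the sampled detections. Embeddings are L2-normalized before the
# distance so the acceptance threshold tau is scale-free. The embedder
# is a pluggable contract: the packaged implementations are a
# passthrough of precomputed appearance vectors (e.g., from the
# simulator or an upstream deep feature extractor) and a simple
# image-patch embedder (box crop, fixed grid of mean intensities).

#' Prune tracklets by length and keypoint quality
#'
#' A tracklet survives iff its length (frames) is at least `min_length`
#' and its mean fraction of well-estimated keypoints (confidence >= 0.5)
#' is at least `min_mean_kp_conf`. Order is preserved.
#'
#' @param tracklets List of tracklets from [build_tracklets()].
#' @param min_length Minimum length in frames (>= 0).
#' @param min_mean_kp_conf Minimum mean fraction in `[0, 1]`.
#' @return Filtered list of tracklets.
#' @export
prune_tracklets <- function(tracklets, min_length = 5,
                            min_mean_kp_conf = 0.5) {
  if (min_length < 0 || min_mean_kp_conf < 0)
    stop("pruning thresholds must be >= 0")
  keep <- vapply(tracklets, function(tr)
    tr$length >= min_length && tr$kp_visibility >= min_mean_kp_conf,
    logical(1))
  tracklets[keep]
}

#' Representative detection of a tracklet
#'
#' Returns the detection with the highest box confidence; ties break to
#' the earliest frame.
#'
#' @param tracklet A tracklet object.
#' @return A [detection()].
#' @export
sample_representative <- function(tracklet) {
  if (length(tracklet$detections) == 0L) stop("empty tracklet")
  confs <- vapply(tracklet$detections, `[[`, numeric(1), "box_conf")
  tracklet$detections[[which.max(confs)]]
}

#' Appearance embedding by passthrough of a stored appearance vector
#'
#' @param detection A [detection()] carrying an `appearance` vector.
#' @param ... Ignored.
#' @return Numeric embedding vector.
#' @export
embed_appearance <- function(detection, ...) {
  if (is.null(detection$appearance))
    stop("detection carries no appearance vector; use an image-based ",
         "embedder or supply appearance features upstream")
  detection$appearance
}

#' Appearance embedding from an image patch
#'
#' Crops the detection's box from a grayscale frame (matrix, rows = y),
#' divides the crop into a `grid x grid` lattice of cells and
#' concatenates the per-cell mean intensities. Deterministic in its
#' inputs.
#'
#' @param detection A [detection()].
#' @param frame_image Numeric matrix (H0 x W0) of pixel intensities.
#' @param grid Cells per side; the embedding has `grid^2` dimensions.
#' @return Numeric embedding vector of length `grid^2`.
#' @export
embed_patch <- function(detection, frame_image, grid = 4) {
  if (is.null(frame_image)) stop("embed_patch requires a frame image")
  H0 <- nrow(frame_image); W0 <- ncol(frame_image)
  b <- detection$box
  x0 <- max(0, floor(b[1])); x1 <- min(W0, ceiling(b[3]))
  y0 <- max(0, floor(b[2])); y1 <- min(H0, ceiling(b[4]))
  if (x1 <= x0 || y1 <= y0) return(rep(0, grid * grid))
  xs <- round(seq(x0, x1, length.out = grid + 1))
  ys <- round(seq(y0, y1, length.out = grid + 1))
  out <- numeric(grid * grid)
  k <- 1L
  for (gy in seq_len(grid)) {
    for (gx in seq_len(grid)) {
      rows <- (ys[gy] + 1):max(ys[gy] + 1, ys[gy + 1])
      cols <- (xs[gx] + 1):max(xs[gx] + 1, xs[gx + 1])
      rows <- rows[rows <= H0]; cols <- cols[cols <= W0]
      out[k] <- mean(frame_image[rows, cols])
      k <- k + 1L
    }
  }
  out
}

#' Euclidean affinity between two embeddings
#'
#' The appearance affinity is the Euclidean (L2) distance between the
#' two embedding vectors; lower means more similar. A metric: symmetric,
#' zero iff equal, triangle inequality.
#'
#' @param emb_a,emb_b Numeric vectors of equal dimension.
#' @return Nonnegative distance.
#' @export
affinity <- function(emb_a, emb_b) {
  if (length(emb_a) != length(emb_b))
    stop("embedding dimension mismatch (", length(emb_a), " vs ",
         length(emb_b), ")")
  sqrt(sum((emb_a - emb_b)^2))
}

l2_normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

#' Fuse tracklets into the target track by appearance affinity
#'
#' Each tracklet is represented by its highest-confidence detection,
#' embedded, L2-normalized, and compared to the reference tracklet's
#' embedding by Euclidean distance; tracklets with distance <= `tau`
#' are accepted and their detections concatenated in frame order. If two
#' accepted tracklets overlap on a frame, the detection from the
#' lower-affinity (more reference-like) tracklet wins. The reference
#' tracklet is always accepted.
#'
#' @param tracklets List of tracklets (typically pruned).
#' @param reference_id Tracklet id of the user-supplied reference
#'   (the only supervision the tracker receives).
#' @param tau Acceptance threshold on the embedding distance (>= 0).
#' @param embedder Function `(detection, ...) -> numeric vector`.
#' @param normalize L2-normalize embeddings before the distance
#'   (default TRUE, making `tau` scale-free).
#' @param ... Passed to the embedder (e.g. `frame_image`).
#' @return An object of class `"track"`: `detections` (frame order, at
#'   most one per frame), `detection_tracklet` (source tracklet id per
#'   detection), and `tracklet_table` (data.frame tracklet_id, affinity,
#'   accepted).
#' @export
fuse_to_track <- function(tracklets, reference_id, tau = 0.7,
                          embedder = embed_appearance, normalize = TRUE,
                          ...) {
  if (tau < 0) stop("tau must be >= 0")
  ids <- vapply(tracklets, `[[`, integer(1), "id")
  ref_pos <- match(reference_id, ids)
  if (is.na(ref_pos))
    stop("reference tracklet ", reference_id, " is not among the given ",
         "tracklets; it may have been pruned away - relax the pruning ",
         "thresholds (min_length, min_mean_kp_conf)")
  embs <- lapply(tracklets, function(tr)
    embedder(sample_representative(tr), ...))
  if (normalize) embs <- lapply(embs, l2_normalize)
  ref_emb <- embs[[ref_pos]]
  aff <- vapply(embs, function(e) affinity(e, ref_emb), numeric(1))
  accepted <- aff <= tau
  accepted[ref_pos] <- TRUE

  # concatenate accepted detections; on frame collisions the detection
  # from the lower-affinity tracklet wins
  by_frame <- new.env(parent = emptyenv())
  ord <- order(aff)  # visit more reference-like tracklets first
  for (k in ord) {
    if (!accepted[k]) next
    for (d in tracklets[[k]]$detections) {
      key <- as.character(d$frame)
      if (is.null(by_frame[[key]]))
        by_frame[[key]] <- list(det = d, tracklet = ids[k])
    }
  }
  frames <- sort(as.integer(ls(by_frame)))
  dets <- lapply(as.character(frames), function(k) by_frame[[k]]$det)
  src <- vapply(as.character(frames), function(k) by_frame[[k]]$tracklet,
                integer(1))
  structure(list(detections = dets, detection_tracklet = unname(src),
                 tracklet_table = data.frame(tracklet_id = ids,
                                             affinity = aff,
                                             accepted = accepted),
                 reference_id = reference_id, tau = tau),
            class = "track")
}

#' Binary classification accuracy of the tracklet fusion
#'
#' Treats the long-term tracker as a binary classifier over tracklets:
#' target tracklets are the positive class (accepted) and non-target
#' tracklets the negative class (rejected).
#'
#' @param predicted_labels Logical vector: accepted by the tracker.
#' @param truth_labels Logical vector: tracklet truly belongs to the
#'   target.
#' @return Fraction of tracklets labelled correctly, in `[0, 1]`.
#' @export
tracklet_classification_accuracy <- function(predicted_labels,
                                             truth_labels) {
  if (length(predicted_labels) != length(truth_labels))
    stop("label vectors must have equal length")
  if (length(predicted_labels) == 0L)
    stop("empty label vectors")
  mean(as.logical(predicted_labels) == as.logical(truth_labels))
}

#' @export
print.track <- function(x, ...) {
  tt <- x$tracklet_table
  cat(sprintf(
    "<track> %d detections from %d/%d accepted tracklets (ref %d, tau %.3g)\n",
    length(x$detections), sum(tt$accepted), nrow(tt), x$reference_id,
    x$tau))
  invisible(x)
}
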