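# Pose-evolution representation: a clip's keypoint sequence is turned
# into a fixed-size tensor of time-encoded ("colorized") joint heatmaps.
#
# For each of 14 joints (COCO's four eye/ear keypoints merged into one
# head joint) and each frame, a Gaussian heatmap is placed at the
# keypoint with amplitude equal to the keypoint confidence. Frame t of
# a clip of duration T (normalized to 1) receives piecewise-linear
# channel weights o_j(t) (a partition of unity over C channels:
# channel 1 peaks at the clip start, channel C at the end). The joint
# evolution map is the time-weighted sum of heatmaps per channel,
# normalized by its own spatial maximum; the pose-evolution map
# concatenates the 14 joint maps into a (14*C) x H x W tensor.

.head_parts <- c("left_eye", "right_eye", "left_ear", "right_ear")

#' Reduce 17 COCO keypoints to the 14-joint skeleton
#'
#' Keeps the nose and the twelve body joints and replaces the four head
#' parts (eyes, ears) with a single "head" keypoint at their
#' confidence-weighted mean position; its confidence is the mean of the
#' four part confidences. If all four parts have zero confidence the
#' head keypoint has confidence 0 (and an undefined location, rendered
#' as a zero heatmap downstream).
#'
#' @param kp17 17 x 3 matrix `(x, y, conf)` in COCO order.
#' @return 14 x 3 matrix in [reduced_joint_names()] order.
#' @export
reduce_keypoints <- function(kp17) {
  if (!is.matrix(kp17) || nrow(kp17) != 17L || ncol(kp17) != 3L)
    stop("kp17 must be a 17 x 3 matrix")
  rownames(kp17) <- coco_keypoint_names()
  head_rows <- kp17[.head_parts, , drop = FALSE]
  w <- head_rows[, 3]
  head_kp <- if (sum(w) > 0) {
    c(sum(head_rows[, 1] * w) / sum(w), sum(head_rows[, 2] * w) / sum(w),
      mean(w))
  } else c(0, 0, 0)
  body <- kp17[setdiff(coco_keypoint_names(),
                       c("nose", .head_parts)), , drop = FALSE]
  out <- rbind(nose = kp17["nose", ], head = head_kp, body)
  rownames(out) <- reduced_joint_names()
  colnames(out) <- c("x", "y", "conf")
  out
}

#' Piecewise-linear time-encoding weights
#'
#' The clip duration `T` is divided into `C - 1` intervals of length
#' `l = T / (C - 1)`. A frame at time `t` in interval `k` contributes
#' weight `(k*l - t)/l` to channel `k` and `(t - (k-1)*l)/l` to channel
#' `k + 1`; all other channels get 0. The weights are a partition of
#' unity (sum to 1 for every `t`), channel 1 is one-hot at `t = 0` and
#' channel `C` one-hot at `t = T`.
#'
#' @param t Time(s) in `[0, T]` (vectorized).
#' @param T_clip Clip duration (default 1, normalized time).
#' @param C Number of channels (>= 2).
#' @return Length-C vector, or a `length(t) x C` matrix for vector `t`.
#' @export
time_encoding <- function(t, T_clip = 1, C = 3) {
  if (C < 2) stop("C must be >= 2")
  if (any(t < 0 | t > T_clip)) stop("t must lie in [0, T]")
  l <- T_clip / (C - 1)
  k <- pmin(C - 1, floor(t / l) + 1)
  out <- matrix(0, length(t), C)
  # clamp float residue at interval boundaries (|residue| ~ 1e-16)
  out[cbind(seq_along(t), k)] <- pmin(1, pmax(0, (k * l - t) / l))
  out[cbind(seq_along(t), k + 1)] <-
    pmin(1, pmax(0, (t - (k - 1) * l) / l))
  if (length(t) == 1L) drop(out) else out
}

#' Gaussian joint heatmap for one keypoint in one frame
#'
#' The grid value at cell `(x, y)` (0-based cell centers) is
#' `conf * exp(-((x - kx)^2 + (y - ky)^2) / (2 sigma^2))`. A keypoint
#' outside the grid is no error: the Gaussian tails inside the grid are
#' kept. Zero confidence yields an all-zero grid.
#'
#' @param keypoint Numeric `(x, y)` location in grid pixels.
#' @param conf Keypoint confidence in `[0, 1]`.
#' @param H,W Grid size.
#' @param sigma Gaussian sigma in grid pixels (> 0).
#' @return `H x W` matrix (rows = y).
#' @export
joint_heatmap <- function(keypoint, conf, H, W, sigma = 2) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (conf == 0) return(matrix(0, H, W))
  gy <- exp(-((seq_len(H) - 1 - keypoint[2])^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(W) - 1 - keypoint[1])^2) / (2 * sigma^2))
  conf * outer(gy, gx)
}

#' Pose-evolution map of one clip
#'
#' Computes, for each joint `i` and channel `j`, the time-weighted sum
#' of the joint's Gaussian heatmaps over the clip's frames, normalized
#' by the slice's own spatial maximum (left all-zero when the maximum is
#' 0), and concatenates the slices joint-major into a
#' `(14*C) x H x W` array: slice `(i-1)*C + j` belongs to joint `i`,
#' channel `j`. Frame `f` (0-based) of an F-frame clip maps to
#' normalized time `t = f / (F - 1)` (`t = 0` if `F = 1`).
#'
#' Keypoints with confidence below `conf_floor` are treated as missing
#' (zero heatmap). A clip whose keypoints are all missing produces an
#' all-zero map with a warning.
#'
#' @param kp_seq `F x 17 x 3` or `F x 14 x 3` array of keypoints in grid
#'   coordinates (17-keypoint input is reduced via
#'   [reduce_keypoints()]).
#' @param C Number of time-encoding channels.
#' @param H,W Output grid size.
#' @param sigma Gaussian sigma in grid pixels.
#' @param conf_floor Keypoint confidences below this are zeroed.
#' @return `(14*C) x H x W` array with values in `[0, 1]`; every nonzero
#'   slice has maximum exactly 1.
#' @export
pose_evolution_map <- function(kp_seq, C = 3, H = 135, W = 240,
                               sigma = 2, conf_floor = 0.05) {
  if (length(dim(kp_seq)) != 3L || !dim(kp_seq)[2] %in% c(14L, 17L) ||
      dim(kp_seq)[3] != 3L)
    stop("kp_seq must be an F x 17 x 3 or F x 14 x 3 array")
  F_ <- dim(kp_seq)[1]
  if (F_ < 1L) stop("clip must have at least one frame")
  if (dim(kp_seq)[2] == 17L) {
    red <- array(0, dim = c(F_, 14L, 3L))
    for (f in seq_len(F_)) red[f, , ] <- reduce_keypoints(kp_seq[f, , ])
    kp_seq <- red
  }
  t_norm <- if (F_ == 1L) 0 else (seq_len(F_) - 1) / (F_ - 1)
  ow <- time_encoding(t_norm, 1, C)
  if (F_ == 1L) ow <- matrix(ow, nrow = 1)
  out <- .pose_evolution_accumulate(matrix(kp_seq[, , 1], F_, 14L),
                                    matrix(kp_seq[, , 2], F_, 14L),
                                    matrix(kp_seq[, , 3], F_, 14L),
                                    ow, as.integer(H), as.integer(W),
                                    sigma, conf_floor)
  if (all(out == 0))
    warning("clip has no keypoints above the confidence floor; ",
            "pose-evolution map is all-zero")
  dim(out) <- c(14L * C, H, W)
  out
}

#' Add white-noise augmentation to a pose-evolution map
#'
#' Adds i.i.d. Gaussian noise to every cell and clips the result to
#' `[0, 1]`. Seed-reproducible; `noise_sigma = 0` is the identity.
#'
#' @param map Pose-evolution array.
#' @param noise_sigma Noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Augmented array of the same shape.
#' @export
augment_map <- function(map, noise_sigma, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma == 0) return(map)
  noisy <- with_local_seed(seed,
    map + array(rnorm(length(map), 0, noise_sigma), dim = dim(map)))
  noisy[noisy < 0] <- 0
  noisy[noisy > 1] <- 1
  noisy
}

#' Featurize a list of clips into a pose-evolution feature matrix
#'
#' Scales each clip's keypoints from native to working resolution by
#' `downscale`, computes its pose-evolution map and flattens it into a
#' column of the returned matrix (ready for the classifier).
#'
#' @param clips List of clips (`label`, `keypoints` F x 17 x 3) as from
#'   [generate_clip_dataset()] or [extract_clip_keypoints()].
#' @param C,H,W,sigma,conf_floor See [pose_evolution_map()].
#' @param downscale Factor from native keypoint coordinates to the
#'   `H x W` grid.
#' @return Numeric matrix `(14*C*H*W) x n_clips` with attributes
#'   `map_dim` (`c(14*C, H, W)`), `labels` and `subjects`; column names
#'   are clip ids.
#' @export
featurize_clips <- function(clips, C = 3, H = 34, W = 60, sigma = 2,
                            conf_floor = 0.05, downscale = 0.125) {
  n <- length(clips)
  X <- matrix(0, 14 * C * H * W, n)
  for (i in seq_len(n)) {
    kp <- clips[[i]]$keypoints
    kp[, , 1:2] <- kp[, , 1:2] * downscale
    X[, i] <- as.vector(pose_evolution_map(kp, C, H, W, sigma, conf_floor))
  }
  colnames(X) <- vapply(clips, function(cl)
    cl$clip_id %||% NA_character_, character(1))
  attr(X, "map_dim") <- c(14L * C, as.integer(H), as.integer(W))
  attr(X, "labels") <- vapply(clips, `[[`, character(1), "label")
  attr(X, "subjects") <- vapply(clips, function(cl)
    cl$subject_id %||% NA_character_, character(1))
  X
}
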