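# Independent oracles and small fixture builders used across tests.

# exhaustive assignment oracle: maximum total IoU over all one-to-one
# assignments of the smaller side (enumerates every injection)
brute_force_best_iou <- function(prev_boxes, cur_boxes) {
  n <- nrow(prev_boxes); m <- nrow(cur_boxes)
  iou <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      iou[i, j] <- box_iou(prev_boxes[i, ], cur_boxes[j, ])
  if (n <= m) {
    best <- 0
    rec <- function(i, used, acc) {
      if (i > n) { best <<- max(best, acc); return(invisible()) }
      for (j in seq_len(m)) {
        if (used[j]) next
        used[j] <- TRUE
        rec(i + 1, used, acc + iou[i, j])
        used[j] <- FALSE
      }
    }
    rec(1L, logical(m), 0)
    best
  } else {
    brute_force_best_iou(cur_boxes, prev_boxes)
  }
}

random_boxes <- function(n, lim = 100, min_side = 2, max_side = 30) {
  out <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    w <- runif(1, min_side, max_side); h <- runif(1, min_side, max_side)
    x0 <- runif(1, 0, lim - w); y0 <- runif(1, 0, lim - h)
    out[i, ] <- c(x0, y0, x0 + w, y0 + h)
  }
  out
}

# direct dense evaluation of the pose-evolution definition: time-weighted
# heatmap sums per channel, normalized by each slice's spatial max
pose_evolution_oracle <- function(kp14_seq, C, H, W, sigma,
                                  conf_floor = 0.05) {
  F_ <- dim(kp14_seq)[1]
  t_norm <- if (F_ == 1) 0 else (seq_len(F_) - 1) / (F_ - 1)
  ow <- time_encoding(t_norm, 1, C)
  if (F_ == 1) ow <- matrix(ow, nrow = 1)
  out <- array(0, dim = c(14 * C, H, W))
  for (j in seq_len(14)) {
    for (ch in seq_len(C)) {
      acc <- matrix(0, H, W)
      for (f in seq_len(F_)) {
        cf <- kp14_seq[f, j, 3]
        if (cf < conf_floor) cf <- 0
        acc <- acc + ow[f, ch] *
          joint_heatmap(kp14_seq[f, j, 1:2], cf, H, W, sigma)
      }
      mx <- max(acc)
      if (mx > 0) out[(j - 1) * C + ch, , ] <- acc / mx
    }
  }
  out
}

# random 14-joint clip inside a small grid
random_kp14_clip <- function(F_, H, W, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(0, dim = c(F_, 14, 3))
    for (f in seq_len(F_)) {
      arr[f, , 1] <- runif(14, 2, W - 3)
      arr[f, , 2] <- runif(14, 2, H - 3)
      arr[f, , 3] <- runif(14, 0.2, 1)
    }
    arr
  })
}

# minimal valid 17-keypoint matrix around a centre
toy_keypoints <- function(cx = 50, cy = 50, conf = 0.9) {
  kp <- pose_template("stand", 0, 60)
  kp[, 1] <- kp[, 1] + cx
  kp[, 2] <- kp[, 2] + cy
  kp[, 3] <- conf
  kp
}

toy_detection <- function(frame, cx = 50, cy = 50, conf = 0.9,
                          box_conf = 0.8, appearance = NULL,
                          det_index = 0L) {
  kp <- toy_keypoints(cx, cy, conf)
  b <- c(range(kp[, 1]), range(kp[, 2]))[c(1, 3, 2, 4)]
  detection(frame, b + c(-2, -2, 2, 2), box_conf, kp,
            appearance = appearance, det_index = det_index)
}

# stationary single-actor stream
toy_stream <- function(n_frames, cx = 50, cy = 50, drop_frames = integer(0)) {
  lapply(seq_len(n_frames) - 1L, function(f) {
    if (f %in% drop_frames) frame_detections(f, list())
    else frame_detections(f, list(toy_detection(f, cx, cy)))
  })
}

# hand-built tracklet with given per-detection keypoint confidences
make_test_tracklet <- function(id, start_frame, kp_confs, box_confs = NULL) {
  n <- length(kp_confs)
  if (is.null(box_confs)) box_confs <- rep(0.8, n)
  dets <- lapply(seq_len(n), function(k)
    toy_detection(start_frame + k - 1L, conf = kp_confs[k],
                  box_conf = box_confs[k]))
  structure(list(id = as.integer(id), detections = dets,
                 start_frame = start_frame,
                 end_frame = start_frame + n - 1L,
                 length = n,
                 kp_visibility = mean(vapply(dets, function(d)
                   mean(d$keypoints[, 3] >= 0.5), numeric(1)))),
            class = "tracklet")
}

# reference scenario for tracker tests: 3 actors, occlusions of the
# target and one bystander, one scene change
tracker_scenario <- function(seed, noise_ratio = 20,
                             dropout = 0.02, n_frames = 600) {
  actors <- make_actor_specs(3, separation_noise_ratio = noise_ratio,
                             seed = seed)
  dur <- n_frames / 30
  script <- list(list("sit", dur * 0.25), list("sit-to-stand", dur * 0.05),
                 list("stand", dur * 0.2), list("walk", dur * 0.3),
                 list("stand-to-sit", dur * 0.05), list("sit", dur * 0.15))
  scenario_config(
    n_frames, actors = actors, action_script = script,
    occlusion_windows = list(
      list("actor01", round(n_frames * 0.25), round(n_frames * 0.35)),
      list("actor02", round(n_frames * 0.6), round(n_frames * 0.67))),
    scene_changes = round(n_frames * 0.5),
    detection_dropout_prob = dropout, seed = seed)
}
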