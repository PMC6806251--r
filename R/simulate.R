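# Synthetic skeleton-scene simulator.
#
# Generates multi-actor keypoint-detection streams with ground-truth
# identities and scripted action segments, emulating the phenomena the
# tracking pipeline must survive: occlusion windows, scene changes
# (teleporting all actors), detection dropout, keypoint jitter, and
# identity-stable appearance vectors (a Gaussian cluster per actor,
# standing in for deep re-identification features: what matters for
# appearance-based fusion is that intra-identity distances are much
# smaller than inter-identity distances).
#
# Skeleton geometry is a parametric 17-keypoint stick figure expressed
# in root-centric units of `scale` (pixels), root = hip midpoint,
# y pointing down. Actors are anchored to a floor line: the root is
# placed so that the lowest ankle touches the actor's floor y, which
# makes sitting poses ride lower than standing ones and gives
# transitions a natural vertical root motion.

# canonical stand pose, units of scale, root at hip midpoint
.stand_template <- function() {
  m <- matrix(c(
     0.00, -0.52,   # nose
    -0.03, -0.55,   # left_eye
     0.03, -0.55,   # right_eye
    -0.06, -0.53,   # left_ear
     0.06, -0.53,   # right_ear
    -0.15, -0.40,   # left_shoulder
     0.15, -0.40,   # right_shoulder
    -0.18, -0.20,   # left_elbow
     0.18, -0.20,   # right_elbow
    -0.20, -0.02,   # left_wrist
     0.20, -0.02,   # right_wrist
    -0.10,  0.00,   # left_hip
     0.10,  0.00,   # right_hip
    -0.11,  0.25,   # left_knee
     0.11,  0.25,   # right_knee
    -0.11,  0.50,   # left_ankle
     0.11,  0.50),  # right_ankle
    ncol = 2, byrow = TRUE)
  rownames(m) <- coco_keypoint_names()
  m
}

# seated pose: torso unchanged, knees drawn forward at hip height,
# shanks dropping to a raised foot position (compressed hip-to-ankle
# height relative to standing)
.sit_template <- function() {
  m <- .stand_template()
  m["left_knee", ]   <- c(-0.26, 0.03)
  m["right_knee", ]  <- c( 0.26, 0.03)
  m["left_ankle", ]  <- c(-0.28, 0.30)
  m["right_ankle", ] <- c( 0.28, 0.30)
  m
}

#' Canonical skeleton for one action at a given phase
#'
#' Deterministic parametric stand-in for the five action classes:
#' `sit` and `stand` are static poses; `walk` is the standing pose with
#' antiphase sinusoidal limb swing (left/right ankle offsets proportional
#' to `cos(2*pi*phase)` and its negation; horizontal root translation is
#' the caller's job); `sit-to-stand` interpolates linearly from the sit
#' to the stand pose as `phase` goes 0 to 1, and `stand-to-sit` is the
#' same path reversed.
#'
#' @param label One of [action_labels()].
#' @param phase Phase in `[0, 1)` (gait cycle for walk, transition
#'   progress for the two transitions; ignored for static poses).
#' @param scale Skeleton scale in pixels (hip-to-head distance is about
#'   `0.52 * scale`).
#' @return 17 x 3 matrix `(x, y, conf)` in COCO order, root-centred,
#'   confidences 1.
#' @export
pose_template <- function(label, phase = 0, scale = 140) {
  if (!label %in% action_labels())
    stop("unknown label '", label, "'; allowed labels: ",
         paste(action_labels(), collapse = ", "))
  xy <- switch(label,
    "stand" = .stand_template(),
    "sit" = .sit_template(),
    "walk" = {
      m <- .stand_template()
      sw <- cos(2 * pi * phase)
      m["left_ankle", 1]  <- m["left_ankle", 1]  + 0.12 * sw
      m["right_ankle", 1] <- m["right_ankle", 1] - 0.12 * sw
      m["left_knee", 1]   <- m["left_knee", 1]   + 0.06 * sw
      m["right_knee", 1]  <- m["right_knee", 1]  - 0.06 * sw
      # arms swing in antiphase with the same-side leg
      m["left_wrist", 1]  <- m["left_wrist", 1]  - 0.10 * sw
      m["right_wrist", 1] <- m["right_wrist", 1] + 0.10 * sw
      m["left_elbow", 1]  <- m["left_elbow", 1]  - 0.05 * sw
      m["right_elbow", 1] <- m["right_elbow", 1] + 0.05 * sw
      m
    },
    "sit-to-stand" = (1 - phase) * .sit_template() +
      phase * .stand_template(),
    "stand-to-sit" = phase * .sit_template() +
      (1 - phase) * .stand_template())
  cbind(xy * scale, conf = rep(1, 17))
}

#' Specify one synthetic actor
#'
#' @param actor_id Actor identifier (string).
#' @param identity_vector Appearance centroid (fixed dimension across
#'   actors in a scenario).
#' @param appearance_noise_sigma Per-detection Gaussian noise added to
#'   the identity vector (>= 0).
#' @param skeleton_scale Skeleton scale in pixels.
#' @param is_target Whether this actor is the tracked target.
#' @return An object of class `"actor_spec"`.
#' @export
actor_spec <- function(actor_id, identity_vector,
                       appearance_noise_sigma = 0.05,
                       skeleton_scale = 140, is_target = FALSE) {
  if (appearance_noise_sigma < 0) stop("appearance_noise_sigma must be >= 0")
  structure(list(actor_id = as.character(actor_id),
                 identity_vector = as.numeric(identity_vector),
                 appearance_noise_sigma = appearance_noise_sigma,
                 skeleton_scale = skeleton_scale,
                 is_target = isTRUE(is_target)),
            class = "actor_spec")
}

#' Build a set of actor specs with well-separated identities
#'
#' Identity vectors are drawn uniformly on the unit sphere in `D`
#' dimensions. When `separation_noise_ratio` is given, the appearance
#' noise sigma is set to (minimum pairwise identity distance) / ratio,
#' which pins the difficulty of appearance-based re-identification.
#'
#' @param n Number of actors; the first is the target.
#' @param D Appearance dimension.
#' @param appearance_noise_sigma Noise sigma; overridden by
#'   `separation_noise_ratio` when that is non-NULL.
#' @param separation_noise_ratio Ratio of identity separation to noise.
#' @param skeleton_scale Skeleton scale in pixels.
#' @param seed RNG seed.
#' @return List of [actor_spec()] objects.
#' @export
make_actor_specs <- function(n, D = 16, appearance_noise_sigma = 0.05,
                             separation_noise_ratio = NULL,
                             skeleton_scale = 140, seed = 1L) {
  stopifnot(n >= 1)
  # unit-sphere identities, redrawn until every pair is at least unit
  # distance apart (the separation the affinity threshold is tuned to)
  vecs <- with_local_seed(seed, {
    repeat {
      v <- matrix(rnorm(n * D), nrow = n)
      v <- v / sqrt(rowSums(v^2))
      if (n == 1 || min(stats::dist(v)) >= 1) break
    }
    v
  })
  if (!is.null(separation_noise_ratio)) {
    if (n < 2) stop("separation_noise_ratio needs at least 2 actors")
    dmin <- min(stats::dist(vecs))
    appearance_noise_sigma <- dmin / separation_noise_ratio
  }
  lapply(seq_len(n), function(i)
    actor_spec(sprintf("actor%02d", i), vecs[i, ],
               appearance_noise_sigma = appearance_noise_sigma,
               skeleton_scale = skeleton_scale, is_target = i == 1L))
}

#' Scenario configuration for the simulator
#'
#' @param n_frames Number of frames.
#' @param fps Frames per second.
#' @param actors List of [actor_spec()]; exactly one must be the target.
#' @param action_script List of `list(label, duration_s)` for the
#'   target; durations must sum to `n_frames / fps`.
#' @param occlusion_windows List of `list(actor_id, start_frame,
#'   end_frame)` (inclusive) during which that actor is not detected.
#' @param scene_changes Integer frame indices at which all actor
#'   positions are re-randomized (simulating a cut to a new scene).
#' @param keypoint_jitter_sigma Gaussian jitter sigma on keypoints (px).
#' @param detection_dropout_prob Per-detection dropout probability
#'   outside occlusion windows.
#' @param frame_size `(H0, W0)` native frame size in pixels.
#' @param seed RNG seed; the same config and seed reproduce the stream
#'   exactly.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(n_frames, fps = 30, actors,
                            action_script,
                            occlusion_windows = list(),
                            scene_changes = integer(0),
                            keypoint_jitter_sigma = 1,
                            detection_dropout_prob = 0,
                            frame_size = c(270, 480), seed = 1L) {
  n_target <- sum(vapply(actors, `[[`, logical(1), "is_target"))
  if (n_target != 1L)
    stop("exactly one actor must be flagged as target (got ", n_target, ")")
  total_s <- sum(vapply(action_script, function(a)
    as.numeric(a[[2]]), numeric(1)))
  if (abs(total_s - n_frames / fps) > 1e-9)
    stop("action_script durations sum to ", total_s, " s but the scenario ",
         "is ", n_frames / fps, " s")
  for (a in action_script)
    if (!a[[1]] %in% action_labels())
      stop("unknown label '", a[[1]], "' in action_script")
  for (w in occlusion_windows) {
    if (w[[2]] < 0 || w[[3]] >= n_frames || w[[2]] > w[[3]])
      stop("occlusion window out of range [0, ", n_frames - 1, "]")
  }
  if (length(scene_changes) &&
      (any(scene_changes < 0) || any(scene_changes >= n_frames)))
    stop("scene_changes must lie in [0, n_frames)")
  structure(list(n_frames = as.integer(n_frames), fps = fps,
                 actors = actors, action_script = action_script,
                 occlusion_windows = occlusion_windows,
                 scene_changes = as.integer(scene_changes),
                 keypoint_jitter_sigma = keypoint_jitter_sigma,
                 detection_dropout_prob = detection_dropout_prob,
                 frame_size = frame_size, seed = as.integer(seed)),
            class = "scenario_config")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-frame label/phase table for the target's script
script_timeline <- function(action_script, n_frames, fps,
                            stride_hz = 1.5) {
  labels <- character(n_frames)
  phases <- numeric(n_frames)
  f0 <- 0L
  for (a in action_script) {
    len <- as.integer(round(as.numeric(a[[2]]) * fps))
    if (len == 0L) next
    idx <- seq.int(f0, f0 + len - 1L)
    labels[idx + 1L] <- a[[1]]
    phases[idx + 1L] <- switch(a[[1]],
      "walk" = ((seq_len(len) - 1L) / fps * stride_hz) %% 1,
      "sit-to-stand" = ,
      "stand-to-sit" = (seq_len(len) - 1L) / max(1L, len - 1L),
      0)
    f0 <- f0 + len
  }
  data.frame(label = labels, phase = phases)
}

# place a root-centric pose at (root_x, floor_y): the lowest ankle
# touches the floor line
place_pose <- function(kp, root_x, floor_y) {
  ankle_y <- max(kp[c("left_ankle", "right_ankle"), 2])
  kp[, 1] <- kp[, 1] + root_x
  kp[, 2] <- kp[, 2] + (floor_y - ankle_y)
  kp
}

# tight keypoint bounding box padded by 10% of its diagonal
keypoint_box <- function(kp) {
  xr <- range(kp[, 1]); yr <- range(kp[, 2])
  pad <- 0.1 * sqrt(diff(xr)^2 + diff(yr)^2)
  c(xr[1] - pad, yr[1] - pad, xr[2] + pad, yr[2] + pad)
}

#' Generate a synthetic multi-actor detection stream
#'
#' Every visible actor yields one detection per frame: keypoints are the
#' actor's posed skeleton plus Gaussian jitter, the box is the tight
#' keypoint bounding box padded by 10% of its diagonal, and the
#' appearance vector is the actor's identity centroid plus Gaussian
#' noise. Detections are removed during that actor's occlusion windows
#' and, elsewhere, with the configured dropout probability. Scene-change
#' frames re-randomize all actor positions. The same config and seed
#' reproduce the stream exactly.
#'
#' @param config A [scenario_config()].
#' @return List with elements `stream` (list of [frame_detections()]),
#'   `ground_truth` (data.frame frame, det_index, actor_id),
#'   `annotations` (list of [annotation_segment()] for the target), and
#'   `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_local_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(config) {
  H0 <- config$frame_size[1]; W0 <- config$frame_size[2]
  actors <- config$actors
  nA <- length(actors)
  target_idx <- which(vapply(actors, `[[`, logical(1), "is_target"))
  timeline <- script_timeline(config$action_script, config$n_frames,
                              config$fps)

  # occlusion lookup: actor -> logical per frame
  occluded <- matrix(FALSE, nrow = config$n_frames, ncol = nA)
  ids <- vapply(actors, `[[`, character(1), "actor_id")
  for (w in config$occlusion_windows) {
    ai <- match(as.character(w[[1]]), ids)
    if (is.na(ai)) stop("occlusion window refers to unknown actor '",
                        w[[1]], "'")
    occluded[(w[[2]]:w[[3]]) + 1L, ai] <- TRUE
  }

  # a scene cut moves everyone: re-randomized roots are rejected (up to
  # a bounded number of redraws) while any new root sits within a box
  # width of any pre-cut root, so no tracklet can ride across the cut
  # by landing on another actor's old position
  randomize_positions <- function(avoid_x = NULL) {
    min_gap <- 0.25 * W0
    for (try in 1:100) {
      root_x <- runif(nA, 0.2 * W0, 0.8 * W0)
      if (is.null(avoid_x) ||
          min(abs(outer(root_x, avoid_x, "-"))) >= min_gap) break
    }
    list(root_x = root_x, floor_y = runif(nA, 0.78 * H0, 0.92 * H0))
  }
  pos <- randomize_positions()
  walk_dir <- sample(c(-1, 1), 1)
  margin <- 0.12 * W0

  stream <- vector("list", config$n_frames)
  gt_frame <- integer(0); gt_det <- integer(0); gt_actor <- character(0)

  for (f in seq_len(config$n_frames) - 1L) {
    if (f %in% config$scene_changes) {
      pos <- randomize_positions(avoid_x = pos$root_x)
      walk_dir <- sample(c(-1, 1), 1)
    }
    lab <- timeline$label[f + 1L]
    # target locomotion
    if (lab == "walk") {
      sc <- actors[[target_idx]]$skeleton_scale
      step <- walk_dir * 0.6 * sc / config$fps
      nx <- pos$root_x[target_idx] + step
      if (nx < margin || nx > W0 - margin) {
        walk_dir <- -walk_dir
        nx <- pos$root_x[target_idx] + walk_dir * 0.6 * sc / config$fps
      }
      pos$root_x[target_idx] <- nx
    }
    dets <- list()
    det_i <- 0L
    for (a in seq_len(nA)) {
      spec <- actors[[a]]
      # non-target actors idle (stand) with slow positional drift
      if (a != target_idx) {
        pos$root_x[a] <- pos$root_x[a] + rnorm(1, 0, 0.5)
        kp <- pose_template("stand", 0, spec$skeleton_scale)
      } else {
        kp <- pose_template(lab, timeline$phase[f + 1L],
                            spec$skeleton_scale)
      }
      kp <- place_pose(kp, pos$root_x[a], pos$floor_y[a])
      kp[, 1:2] <- kp[, 1:2] +
        matrix(rnorm(34, 0, config$keypoint_jitter_sigma), ncol = 2)
      kp[, 3] <- runif(17, 0.55, 1)
      visible <- !occluded[f + 1L, a] &&
        !(config$detection_dropout_prob > 0 &&
          runif(1) < config$detection_dropout_prob)
      if (!visible) next
      app <- spec$identity_vector +
        rnorm(length(spec$identity_vector), 0, spec$appearance_noise_sigma)
      dets[[length(dets) + 1L]] <-
        detection(f, keypoint_box(kp), runif(1, 0.7, 1), kp,
                  appearance = app, det_index = det_i)
      gt_frame <- c(gt_frame, f); gt_det <- c(gt_det, det_i)
      gt_actor <- c(gt_actor, spec$actor_id)
      det_i <- det_i + 1L
    }
    stream[[f + 1L]] <- frame_detections(f, dets)
  }

  # target annotations from the script
  segs <- list()
  f0 <- 0L
  for (a in config$action_script) {
    len <- as.integer(round(as.numeric(a[[2]]) * config$fps))
    if (len == 0L) next
    segs[[length(segs) + 1L]] <-
      annotation_segment(actors[[target_idx]]$actor_id, f0, f0 + len - 1L,
                         a[[1]])
    f0 <- f0 + len
  }

  list(stream = stream,
       ground_truth = data.frame(frame = gt_frame, det_index = gt_det,
                                 actor_id = gt_actor,
                                 stringsAsFactors = FALSE),
       annotations = segs, config = config)
}

#' Generate a balanced labelled clip dataset
#'
#' Produces `n_per_class` single-actor keypoint sequences per action
#' class, each `clip_len_frames` long, with per-clip randomized scale,
#' placement, walking direction and keypoint jitter. Subjects are
#' assigned round-robin so that every subject contributes clips of every
#' class (needed for subject-wise splits).
#'
#' @param n_per_class Clips per class.
#' @param clip_len_frames Frames per clip.
#' @param fps Frames per second.
#' @param keypoint_jitter_sigma Gaussian jitter sigma (px).
#' @param frame_size `(H0, W0)` native frame size.
#' @param skeleton_scale Mean skeleton scale (px); per-clip scales vary
#'   by ~5%.
#' @param n_subjects Number of synthetic subject ids to cycle through.
#' @param seed RNG seed.
#' @return List of clips, each `list(clip_id, subject_id, label,
#'   keypoints)` with `keypoints` an `F x 17 x 3` array.
#' @export
generate_clip_dataset <- function(n_per_class, clip_len_frames = 60,
                                  fps = 30, keypoint_jitter_sigma = 1,
                                  frame_size = c(270, 480),
                                  skeleton_scale = 140, n_subjects = 20,
                                  seed = 1L) {
  with_local_seed(seed, {
    H0 <- frame_size[1]; W0 <- frame_size[2]
    clips <- list()
    for (lab in action_labels()) {
      for (i in seq_len(n_per_class)) {
        sc <- skeleton_scale * (1 + rnorm(1, 0, 0.05))
        floor_y <- runif(1, 0.78 * H0, 0.92 * H0)
        dir <- sample(c(-1, 1), 1)
        speed <- runif(1, 0.5, 0.7) * sc
        root_x0 <- if (lab == "walk") {
          travel <- speed * clip_len_frames / fps
          if (dir > 0) runif(1, 0.1 * W0, max(0.11 * W0, 0.85 * W0 - travel))
          else runif(1, min(0.89 * W0, 0.15 * W0 + travel), 0.9 * W0)
        } else runif(1, 0.2 * W0, 0.8 * W0)
        kparr <- array(0, dim = c(clip_len_frames, 17, 3))
        for (f in seq_len(clip_len_frames) - 1L) {
          phase <- switch(lab,
            "walk" = (f / fps * 1.5) %% 1,
            "sit-to-stand" = ,
            "stand-to-sit" = f / max(1L, clip_len_frames - 1L),
            0)
          kp <- pose_template(lab, phase, sc)
          rx <- root_x0 + if (lab == "walk") dir * speed * f / fps else 0
          kp <- place_pose(kp, rx, floor_y)
          if (keypoint_jitter_sigma > 0)
            kp[, 1:2] <- kp[, 1:2] +
              matrix(rnorm(34, 0, keypoint_jitter_sigma), ncol = 2)
          kp[, 3] <- runif(17, 0.7, 1)
          kparr[f + 1L, , ] <- kp
        }
        clips[[length(clips) + 1L]] <- list(
          clip_id = sprintf("%s_%04d", gsub("-", "", lab), i),
          subject_id = sprintf("s%02d", ((i - 1L) %% n_subjects) + 1L),
          label = lab, keypoints = kparr)
      }
    }
    clips
  })
}
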