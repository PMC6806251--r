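test_that("pose templates honour interpolation endpoints and symmetry", {
  expect_equal(pose_template("sit-to-stand", 0, 140),
               pose_template("sit", 0, 140))
  expect_equal(pose_template("sit-to-stand", 1, 140),
               pose_template("stand", 0, 140))
  for (phi in seq(0, 1, by = 0.125))
    expect_equal(pose_template("sit-to-stand", phi, 120),
                 pose_template("stand-to-sit", 1 - phi, 120))
  expect_error(pose_template("running", 0), "unknown label")
})

test_that("walking swaps left/right ankle offsets half a cycle apart", {
  base <- pose_template("stand", 0, 100)
  w0 <- pose_template("walk", 0, 100)
  w5 <- pose_template("walk", 0.5, 100)
  off0 <- w0[c("left_ankle", "right_ankle"), 1] -
    base[c("left_ankle", "right_ankle"), 1]
  off5 <- w5[c("left_ankle", "right_ankle"), 1] -
    base[c("left_ankle", "right_ankle"), 1]
  expect_gt(abs(off0[1]), 1)           # nonzero swing
  expect_equal(unname(off0), unname(rev(off5)))
  expect_equal(unname(off0[1]), -unname(off0[2]))
})

test_that("a clean single-actor scenario yields one detection per frame", {
  actors <- make_actor_specs(1, seed = 2)
  sc <- scenario_config(100, actors = actors,
                        action_script = list(list("stand", 100 / 30)),
                        keypoint_jitter_sigma = 0, seed = 3)
  scen <- generate_scenario(sc)
  expect_identical(nrow(scen$ground_truth), 100L)
  expect_true(all(vapply(scen$stream, function(f)
    length(f$detections), integer(1)) == 1L))
})

test_that("the simulator is deterministic under a fixed seed", {
  sc <- tracker_scenario(seed = 7, n_frames = 120)
  s1 <- generate_scenario(sc)
  s2 <- generate_scenario(sc)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$stream, s2$stream)
  # a different seed changes the noise realization
  sc2 <- tracker_scenario(seed = 8, n_frames = 120)
  s3 <- generate_scenario(sc2)
  expect_false(identical(s1$stream, s3$stream))
})

test_that("occlusion windows remove exactly the windowed detections", {
  actors <- make_actor_specs(2, seed = 4)
  sc <- scenario_config(100, actors = actors,
                        action_script = list(list("stand", 100 / 30)),
                        occlusion_windows = list(list("actor02", 40, 59)),
                        seed = 5)
  scen <- generate_scenario(sc)
  frames_a2 <- scen$ground_truth$frame[
    scen$ground_truth$actor_id == "actor02"]
  expect_identical(sort(frames_a2), setdiff(0:99, 40:59))
})

test_that("invalid scenario configurations are rejected", {
  actors <- make_actor_specs(2, seed = 1)
  actors[[2]]$is_target <- TRUE
  expect_error(
    scenario_config(60, actors = actors,
                    action_script = list(list("sit", 2))),
    "exactly one actor")
  actors <- make_actor_specs(1, seed = 1)
  expect_error(
    scenario_config(60, actors = actors,
                    action_script = list(list("sit", 3))),
    "durations sum")
  expect_error(
    scenario_config(60, actors = actors,
                    action_script = list(list("sit", 2)),
                    occlusion_windows = list(list("actor01", 50, 70))),
    "out of range")
})

test_that("clip datasets are balanced and seed-stable", {
  clips <- generate_clip_dataset(10, clip_len_frames = 12, seed = 9)
  expect_length(clips, 50L)
  labs <- vapply(clips, `[[`, character(1), "label")
  expect_true(all(table(labs) == 10L))

  clips2 <- generate_clip_dataset(10, clip_len_frames = 12, seed = 9)
  expect_identical(clips, clips2)
  clips3 <- generate_clip_dataset(10, clip_len_frames = 12, seed = 10)
  labs3 <- vapply(clips3, `[[`, character(1), "label")
  expect_identical(as.vector(table(labs3)), as.vector(table(labs)))
  expect_false(identical(clips[[1]]$keypoints, clips3[[1]]$keypoints))
})

test_that("noise-free kinematics: walking roots move monotonically, static poses do not", {
  clips <- generate_clip_dataset(3, clip_len_frames = 30,
                                 keypoint_jitter_sigma = 0, seed = 11)
  root_x <- function(kp) (kp[, 12, 1] + kp[, 13, 1]) / 2  # hip midpoint
  for (cl in clips) {
    rx <- root_x(cl$keypoints)
    if (cl$label == "walk") {
      expect_true(all(diff(rx) > 0) || all(diff(rx) < 0))
    } else if (cl$label %in% c("sit", "stand")) {
      expect_equal(max(rx) - min(rx), 0)
    }
  }
})

test_that("an occluded actor fragments into multiple tracklets", {
  actors <- make_actor_specs(2, seed = 6)
  sc <- scenario_config(120, actors = actors,
                        action_script = list(list("stand", 4)),
                        occlusion_windows = list(list("actor01", 50, 69)),
                        seed = 6)
  scen <- generate_scenario(sc)
  tracklets <- build_tracklets(scen$stream, 0.1)
  gt <- scen$ground_truth
  actor_of <- setNames(gt$actor_id, paste(gt$frame, gt$det_index))
  target_tr <- Filter(function(tr) {
    keys <- vapply(tr$detections, function(d)
      paste(d$frame, d$det_index), character(1))
    mean(actor_of[keys] == "actor01") > 0.5
  }, tracklets)
  expect_gte(length(target_tr), 2L)
})
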