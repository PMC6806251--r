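test_that("detection stream round-trips through JSON-lines exactly", {
  app <- list(c(0.1, -0.2, 0.3), c(0.5, 0.25, -1 / 3))
  stream <- lapply(0:2, function(f) {
    dets <- if (f == 1) list() else list(
      toy_detection(f, cx = 50 + f * pi, cy = 40 + sqrt(2),
                    appearance = app[[(f %/% 2) + 1]], det_index = 0L))
    frame_detections(f, dets)
  })
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_detections(stream, path)
  expect_length(readLines(path), 3L)
  back <- read_detections(path)
  expect_length(back, 3L)
  expect_identical(back[[1]]$detections[[1]]$keypoints,
                   unname(stream[[1]]$detections[[1]]$keypoints))
  expect_identical(back[[3]]$detections[[1]]$box,
                   stream[[3]]$detections[[1]]$box)
  expect_identical(back[[3]]$detections[[1]]$appearance,
                   stream[[3]]$detections[[1]]$appearance)
  expect_length(back[[2]]$detections, 0L)
})

test_that("empty detections file yields an empty stream", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  file.create(path)
  expect_length(read_detections(path), 0L)
})

test_that("malformed detection records are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"frame":0,"detections":[{"box":[0,0,10,10],"box_conf":0.9,"keypoints":[%s]}]}'
  kp17 <- paste(rep("[1,2,0.5]", 17), collapse = ",")
  kp16 <- paste(rep("[1,2,0.5]", 16), collapse = ",")
  writeLines(c(sprintf(good, kp17),
               sub('"frame":0', '"frame":1', sprintf(good, kp16))), path)
  expect_error(read_detections(path), "line 2.*16 keypoints")
})

test_that("non-monotone frame indices are a validation error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  kp17 <- paste(rep("[1,2,0.5]", 17), collapse = ",")
  rec <- '{"frame":%d,"detections":[{"box":[0,0,10,10],"box_conf":0.9,"keypoints":[%s]}]}'
  writeLines(c(sprintf(rec, 5, kp17), sprintf(rec, 3, kp17)), path)
  expect_error(read_detections(path), "strictly increasing")
})

test_that("mixed appearance dimensions are rejected", {
  stream <- list(
    frame_detections(0, list(toy_detection(0, appearance = c(1, 2)))),
    frame_detections(1, list(toy_detection(1, appearance = c(1, 2, 3)))))
  expect_error(validate_stream(stream), "mixed dimensions")
  path <- withr::local_tempfile(fileext = ".jsonl")
  expect_error(write_detections(stream, path), "mixed dimensions")
})

test_that("detection invariants are enforced", {
  kp <- toy_keypoints()
  expect_error(detection(0, c(10, 0, 10, 5), 0.9, kp), "degenerate")
  expect_error(detection(0, c(0, 0, 10, 10), 1.4, kp), "box_conf")
  expect_error(detection(0, c(0, 0, 10, 10), 0.9, kp[1:16, ]), "17 x 3")
  bad <- kp; bad[3, 3] <- 1.5
  expect_error(detection(0, c(0, 0, 10, 10), 0.9, bad), "confidences")
})

test_that("annotations CSV reads segments and enforces the label set", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,start_frame,end_frame,label",
               "s1,0,119,walk"), path)
  segs <- read_annotations(path)
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$end_frame - segs[[1]]$start_frame + 1L, 120L)

  writeLines(c("subject_id,start_frame,end_frame,label",
               "s1,0,119,running"), path)
  expect_error(read_annotations(path), "sit, sit-to-stand, stand, walk")

  writeLines(c("subject_id,start_frame,end_frame,label",
               "s1,0,119,walk", "s1,100,200,sit"), path)
  expect_error(read_annotations(path), "overlapping")
  # same interval for another subject is fine
  writeLines(c("subject_id,start_frame,end_frame,label",
               "s1,0,119,walk", "s2,100,200,sit"), path)
  expect_length(read_annotations(path), 2L)
})

test_that("annotations round-trip through CSV", {
  segs <- list(annotation_segment("s1", 0, 89, "sit"),
               annotation_segment("s1", 90, 150, "sit-to-stand"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(segs, path)
  expect_equal(read_annotations(path), segs, ignore_attr = TRUE)
})

test_that("config files parse and unknown keys fail fast", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("iou_threshold = 0.25", "C = 4", "# comment", ""), path)
  cfg <- read_config(path)
  expect_equal(cfg$iou_threshold, 0.25)
  expect_equal(cfg$C, 4L)
  expect_equal(cfg$fps, 30)
  writeLines("froobnicate = 1", path)
  expect_error(read_config(path), "unknown configuration key")
})

test_that("rewriting the same stream is byte-identical and metadata carries the seed", {
  stream <- toy_stream(4)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_detections(stream, p1)
  write_detections(stream, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  cfg <- pipeline_config(seed = 99L)
  meta <- write_run_metadata(p1, cfg)
  expect_identical(meta$seed, 99L)
  back <- jsonlite::read_json(paste0(p1, ".meta.json"))
  expect_identical(back$config_hash, poseaction:::config_hash(cfg))
})

test_that("pose-map container round-trips maps and labels", {
  maps <- list(a = array(runif(2 * 3 * 4), dim = c(2, 3, 4)),
               b = array(0, dim = c(2, 3, 4)))
  path <- withr::local_tempfile(fileext = ".rds")
  write_pose_maps(maps, c("sit", "walk"), path)
  back <- read_pose_maps(path)
  expect_identical(back$maps$a, maps$a)
  expect_identical(unname(back$labels), c("sit", "walk"))
})
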