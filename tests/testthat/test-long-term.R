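test_that("pruning applies the length and keypoint-quality rule", {
  trs <- list(
    make_test_tracklet(1, 0, rep(0.9, 10)),          # long, good
    make_test_tracklet(2, 20, rep(0.9, 2)),          # too short
    make_test_tracklet(3, 40, rep(0.3, 10)),         # poor keypoints
    make_test_tracklet(4, 60, c(rep(0.9, 5), rep(0.3, 5))),  # vis 0.5
    make_test_tracklet(5, 80, rep(0.55, 5)))         # boundary length
  # identity when thresholds are zero
  expect_identical(prune_tracklets(trs, 0, 0), trs)
  kept <- prune_tracklets(trs, 5, 0.5)
  expect_identical(vapply(kept, `[[`, integer(1), "id"), c(1L, 4L, 5L))
  expect_length(prune_tracklets(list(make_test_tracklet(9, 0, rep(1, 2))),
                                5, 0), 0L)
})

test_that("the representative is the highest-confidence box, earliest on ties", {
  tr <- make_test_tracklet(1, 10, rep(0.9, 3), box_confs = c(0.5, 0.9, 0.7))
  expect_identical(sample_representative(tr)$frame, 11L)
  tr_tie <- make_test_tracklet(2, 5, rep(0.9, 4), box_confs = rep(0.6, 4))
  expect_identical(sample_representative(tr_tie)$frame, 5L)
  expect_error(sample_representative(structure(list(detections = list()),
                                               class = "tracklet")),
               "empty")
  # argmax oracle on random confidences
  withr::with_seed(3, {
    for (i in 1:100) {
      confs <- runif(sample(1:8, 1))
      tr <- make_test_tracklet(i, 0, rep(0.9, length(confs)),
                               box_confs = confs)
      expect_identical(sample_representative(tr)$box_conf,
                       confs[which.max(confs)])
    }
  })
})

test_that("appearance embedders are deterministic and validated", {
  d <- toy_detection(0, appearance = c(1, 2, 3))
  expect_identical(embed_appearance(d), c(1, 2, 3))
  expect_identical(embed_appearance(d), embed_appearance(d))
  expect_error(embed_appearance(toy_detection(0)), "no appearance")

  img <- matrix(seq(0, 1, length.out = 120 * 160), 120, 160)
  e1 <- embed_patch(toy_detection(0, cx = 60, cy = 60), img, grid = 4)
  expect_length(e1, 16L)
  expect_identical(e1, embed_patch(toy_detection(0, cx = 60, cy = 60),
                                   img, grid = 4))
  flat <- matrix(0.25, 120, 160)
  expect_equal(embed_patch(toy_detection(0, cx = 60, cy = 60), flat),
               rep(0.25, 16))
})

test_that("simulated identities separate under the Gaussian appearance model", {
  withr::with_seed(17, {
    D <- 16
    a <- rnorm(D); a <- a / sqrt(sum(a^2))
    b <- rnorm(D); b <- b / sqrt(sum(b^2))
    b <- a + (b - a) / sqrt(sum((b - a)^2))  # unit separation
    n <- 1000
    intra <- inter <- numeric(n)
    for (i in seq_len(n)) {
      x1 <- a + rnorm(D, 0, 0.05); x2 <- a + rnorm(D, 0, 0.05)
      y1 <- b + rnorm(D, 0, 0.05)
      intra[i] <- affinity(x1, x2)
      inter[i] <- affinity(x1, y1)
    }
    expect_gte(mean(inter > intra), 0.99)
  })
})

test_that("affinity is the Euclidean metric", {
  expect_identical(affinity(c(1, 2), c(1, 2)), 0)
  expect_identical(affinity(c(0, 0), c(3, 4)), 5)
  expect_error(affinity(c(1, 2), c(1, 2, 3)), "dimension mismatch")
  withr::with_seed(5, {
    for (i in 1:50) {
      x <- rnorm(8); y <- rnorm(8); z <- rnorm(8)
      expect_equal(affinity(x, y), sqrt(sum((x - y)^2)),
                   tolerance = 1e-12)
      expect_identical(affinity(x, y), affinity(y, x))
      expect_lte(affinity(x, z), affinity(x, y) + affinity(y, z) + 1e-12)
    }
    expect_identical(affinity(rnorm(4), numeric(4) + Inf) > 0, TRUE)
  })
})

test_that("fusion accepts by threshold and always keeps the reference", {
  mk <- function(id, app) {
    tr <- make_test_tracklet(id, id * 10L, rep(0.9, 6))
    tr$detections <- lapply(tr$detections, function(d) {
      d$appearance <- app
      d
    })
    tr
  }
  trs <- list(mk(1, c(1, 0)), mk(2, c(1, 0)), mk(3, c(0, 1)))
  # tau = 0: only exact-duplicate embeddings merge
  track <- fuse_to_track(trs, 1L, tau = 0)
  expect_identical(track$tracklet_table$accepted, c(TRUE, TRUE, FALSE))
  # reference survives even a negative-looking threshold of 0 vs itself
  track2 <- fuse_to_track(trs, 3L, tau = 0)
  expect_true(track2$tracklet_table$accepted[3])
  expect_identical(sum(track2$tracklet_table$accepted), 1L)
  expect_error(fuse_to_track(trs, 99L, tau = 0.5), "not among")

  # accepted set grows weakly with tau
  sizes <- vapply(c(0, 0.5, 1, 1.5, 2), function(tau)
    sum(fuse_to_track(trs, 1L, tau)$tracklet_table$accepted), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("frame collisions resolve to the lower-affinity tracklet", {
  mk <- function(id, app, start, cx) {
    tr <- make_test_tracklet(id, start, rep(0.9, 6))
    tr$detections <- lapply(tr$detections, function(d) {
      d$appearance <- app
      d$det_index <- id
      d
    })
    tr
  }
  ref <- mk(1L, c(1, 0, 0), 0L, 30)
  near <- mk(2L, c(0.95, 0.3, 0), 4L, 60)   # overlaps ref on frames 4-5
  track <- fuse_to_track(list(ref, near), 1L, tau = 2)
  frames <- vapply(track$detections, `[[`, integer(1), "frame")
  expect_identical(frames, 0:9)
  src <- track$detection_tracklet
  expect_true(all(src[1:6] == 1L))  # reference wins the overlap
  expect_true(all(src[7:10] == 2L))
})

test_that("tracklet binary accuracy counts matches", {
  expect_identical(tracklet_classification_accuracy(c(TRUE, FALSE),
                                                    c(TRUE, FALSE)), 1)
  pred <- c(rep(TRUE, 3), rep(FALSE, 5), TRUE, FALSE)
  truth <- c(rep(TRUE, 3), rep(FALSE, 5), FALSE, TRUE)
  expect_identical(tracklet_classification_accuracy(pred, truth), 0.8)
  expect_error(tracklet_classification_accuracy(logical(0), logical(0)),
               "empty")
  expect_error(tracklet_classification_accuracy(TRUE, c(TRUE, FALSE)),
               "equal length")
})

test_that("fusion recovers the target's tracklets in a 3-actor scene", {
  sc <- tracker_scenario(seed = 21, n_frames = 300, dropout = 0)
  scen <- generate_scenario(sc)
  tracklets <- build_tracklets(scen$stream, 0.1)
  pruned <- prune_tracklets(tracklets, 5, 0.5)
  gt <- scen$ground_truth
  actor_of <- setNames(gt$actor_id, paste(gt$frame, gt$det_index))
  truth <- vapply(pruned, function(tr) {
    keys <- vapply(tr$detections, function(d)
      paste(d$frame, d$det_index), character(1))
    mean(actor_of[keys] == "actor01") > 0.5
  }, logical(1))
  ref <- pruned[[which(truth)[1]]]$id
  track <- fuse_to_track(pruned, ref, tau = 0.5)
  expect_identical(track$tracklet_table$accepted, truth)
})

test_that("tracker accuracy degrades when appearance noise approaches the separation", {
  accs <- function(ratio) {
    vapply(1:3, function(s) {
      scen <- generate_scenario(tracker_scenario(seed = 100 + s,
                                                 noise_ratio = ratio,
                                                 n_frames = 240))
      evaluate_tracking(scen)$tracklet_accuracy
    }, numeric(1))
  }
  low_noise <- accs(20)
  high_noise <- accs(1.6)
  expect_gt(mean(low_noise), mean(high_noise))
})
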