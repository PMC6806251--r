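test_that("keypoint reduction merges the head parts by confidence weight", {
  kp <- toy_keypoints(cx = 100, cy = 80)
  # symmetric eyes/ears about x = 100 with equal confidences
  red <- reduce_keypoints(kp)
  expect_identical(rownames(red), reduced_joint_names())
  expect_equal(unname(red["head", "x"]), 100)
  expect_equal(unname(red["head", "conf"]), 0.9)

  # only the left ear visible: head sits on the left ear
  kp2 <- kp
  kp2[c("left_eye", "right_eye", "right_ear"), 3] <- 0
  kp2["left_ear", 3] <- 1
  red2 <- reduce_keypoints(kp2)
  expect_equal(unname(red2["head", 1:2]), unname(kp2["left_ear", 1:2]))
  expect_equal(unname(red2["head", "conf"]), 0.25)

  # all head parts invisible: confidence 0
  kp3 <- kp
  kp3[c("left_eye", "right_eye", "left_ear", "right_ear"), 3] <- 0
  expect_identical(unname(reduce_keypoints(kp3)["head", "conf"]), 0)

  # random confidences against the explicit weighted mean
  withr::with_seed(8, {
    for (i in 1:20) {
      kp4 <- toy_keypoints()
      kp4[, 3] <- runif(17)
      red4 <- reduce_keypoints(kp4)
      w <- kp4[2:5, 3]
      expect_equal(unname(red4["head", "x"]),
                   sum(kp4[2:5, 1] * w) / sum(w))
      expect_equal(unname(red4["head", "conf"]), mean(w))
    }
  })
})

test_that("time encoding is a triangular partition of unity", {
  expect_equal(time_encoding(0, 1, 3), c(1, 0, 0))
  expect_equal(time_encoding(1, 1, 3), c(0, 0, 1))
  expect_equal(time_encoding(0.25, 1, 3), c(0.5, 0.5, 0))
  expect_equal(time_encoding(0.5, 1, 3), c(0, 1, 0))
  expect_error(time_encoding(1.1, 1, 3), "t must lie")
  expect_error(time_encoding(-0.1, 1, 3), "t must lie")
  expect_error(time_encoding(0.5, 1, 1), "C must be")

  ts <- seq(0, 1, length.out = 1001)
  for (C in 2:10) {
    ow <- time_encoding(ts, 1, C)
    expect_lt(max(abs(rowSums(ow) - 1)), 1e-9)
    expect_true(all(ow >= 0 & ow <= 1))
    expect_equal(ow[1, ], c(1, rep(0, C - 1)))
    expect_equal(ow[1001, ], c(rep(0, C - 1), 1))
  }
})

test_that("joint heatmaps are confidence-scaled Gaussians", {
  expect_identical(joint_heatmap(c(5, 5), 0, 10, 10), matrix(0, 10, 10))
  hm <- joint_heatmap(c(7, 4), 1, 12, 15, sigma = 2)
  expect_identical(hm[5, 8], 1)  # peak at the keypoint cell (0-based 7,4)
  expect_equal(hm[5, 10], hm[5, 6])  # radial symmetry in x
  expect_equal(hm[2, 8], hm[8, 8])   # and in y
  expect_true(max(joint_heatmap(c(7, 4), 0.6, 12, 15, 2)) <= 0.6)
  # off-grid keypoints keep their in-grid tails, no error
  expect_gt(max(joint_heatmap(c(-1, 5), 1, 10, 10, 2)), 0)
  expect_error(joint_heatmap(c(5, 5), 1, 10, 10, sigma = 0), "sigma")
})

test_that("heatmap mass matches the Gaussian integral", {
  sigma <- 2
  hm <- joint_heatmap(c(20, 20), 0.8, 41, 41, sigma)
  expect_equal(sum(hm), 0.8 * 2 * pi * sigma^2, tolerance = 0.01)
})

test_that("pose-evolution maps match the direct dense evaluation", {
  for (seed in 1:3) {
    kp <- random_kp14_clip(5, 20, 24, seed = seed)
    got <- pose_evolution_map(kp, C = 3, H = 20, W = 24, sigma = 1.5)
    want <- pose_evolution_oracle(kp, C = 3, H = 20, W = 24, sigma = 1.5)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("single-frame clips land entirely in channel 1", {
  kp <- array(0, dim = c(1, 14, 3))
  kp[1, , 1] <- 8; kp[1, , 2] <- 6; kp[1, 3, 3] <- 1
  m <- pose_evolution_map(kp, C = 3, H = 16, W = 16, sigma = 2)
  expect_identical(max(m[(3 - 1) * 3 + 1, , ]), 1)
  expect_identical(max(m[(3 - 1) * 3 + 2, , ]), 0)
  expect_identical(max(m[(3 - 1) * 3 + 3, , ]), 0)
})

test_that("static poses give identical channel slices per joint", {
  kp1 <- random_kp14_clip(1, 18, 22, seed = 4)
  kp <- array(0, dim = c(6, 14, 3))
  for (f in 1:6) kp[f, , ] <- kp1[1, , ]
  m <- pose_evolution_map(kp, C = 3, H = 18, W = 22, sigma = 2)
  for (j in 1:14) {
    expect_equal(m[(j - 1) * 3 + 1, , ], m[(j - 1) * 3 + 2, , ],
                 tolerance = 1e-6)
    expect_equal(m[(j - 1) * 3 + 2, , ], m[(j - 1) * 3 + 3, , ],
                 tolerance = 1e-6)
  }
})

test_that("all-zero clips give all-zero maps with a warning, not an error", {
  kp <- array(0, dim = c(4, 14, 3))
  expect_warning(m <- pose_evolution_map(kp, C = 3, H = 10, W = 10),
                 "all-zero")
  expect_identical(max(m), 0)
  expect_identical(dim(m), c(42L, 10L, 10L))
})

test_that("time reversal swaps channel j with channel C+1-j", {
  kp <- random_kp14_clip(7, 20, 24, seed = 12)
  C <- 3
  fwd <- pose_evolution_map(kp, C = C, H = 20, W = 24, sigma = 1.5)
  rev_kp <- kp[7:1, , , drop = FALSE]
  bwd <- pose_evolution_map(rev_kp, C = C, H = 20, W = 24, sigma = 1.5)
  for (j in 1:14)
    for (ch in 1:C)
      expect_equal(bwd[(j - 1) * C + ch, , ],
                   fwd[(j - 1) * C + (C + 1 - ch), , ],
                   tolerance = 1e-6)
})

test_that("translation moves the map without changing it (interior)", {
  kp <- random_kp14_clip(4, 30, 30, seed = 3)
  kp[, , 1:2] <- kp[, , 1:2] / 2 + 8   # keep well inside
  shifted <- kp
  shifted[, , 1] <- shifted[, , 1] + 3
  shifted[, , 2] <- shifted[, , 2] + 2
  m0 <- pose_evolution_map(kp, C = 2, H = 30, W = 30, sigma = 1.5)
  m1 <- pose_evolution_map(shifted, C = 2, H = 30, W = 30, sigma = 1.5)
  expect_equal(m1[, 3:30, 4:30], m0[, 1:28, 1:27], tolerance = 1e-4)
})

test_that("every nonzero slice is normalized to max exactly 1", {
  kp <- random_kp14_clip(6, 16, 20, seed = 6)
  m <- pose_evolution_map(kp, C = 4, H = 16, W = 20, sigma = 2)
  for (s in seq_len(dim(m)[1])) {
    mx <- max(m[s, , ])
    expect_true(mx == 1 || mx == 0)
  }
})

test_that("white-noise augmentation is seeded and moment-faithful", {
  m <- array(0.5, dim = c(6, 40, 40))
  expect_identical(augment_map(m, 0), m)
  a1 <- augment_map(m, 0.05, seed = 3)
  a2 <- augment_map(m, 0.05, seed = 3)
  expect_identical(a1, a2)
  a3 <- augment_map(m, 0.05, seed = 4)
  expect_false(identical(a1, a3))
  expect_true(all(a1 >= 0 & a1 <= 1))
  big <- array(0.5, dim = c(14, 300, 240))  # ~1e6 cells, no clipping
  noisy <- augment_map(big, 0.05, seed = 5)
  expect_equal(sd(noisy - big), 0.05, tolerance = 0.05 * 0.05)
})
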