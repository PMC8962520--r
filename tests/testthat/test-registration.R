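test_that("reference selection ranks frames by SNR with lowest-index ties", {
  ph <- tiny_phantom(seed = 1)
  # identical frames: tie broken to index 1
  stk <- frame_stack(replicate(4, ph$clean, simplify = FALSE), aligned = TRUE)
  expect_identical(select_reference(stk), 1L)
  # the clean frame among heavily noisy ones wins
  set.seed(2)
  noisy <- lapply(1:4, function(i) {
    octmf:::clamp01(ph$clean * matrix(rgamma(64 * 64, 2, 2), 64, 64))
  })
  frames <- append(noisy, list(ph$clean), after = 2)
  expect_identical(select_reference(frame_stack(frames, aligned = TRUE)), 3L)
  # a constant frame has zero background sd -> infinite SNR sentinel, maximal
  frames2 <- list(ph$clean, matrix(0.5, 64, 64))
  expect_identical(select_reference(frame_stack(frames2, aligned = TRUE)), 2L)
  expect_error(select_reference(structure(list(frames = list()),
                                          class = "frame_stack")), "empty")
})

test_that("mutual information is symmetric, maximal for self, and rejects
           constant images", {
  ph <- tiny_phantom(seed = 3)
  set.seed(4)
  x <- ph$clean
  y <- octmf:::clamp01(x + matrix(rnorm(length(x), 0, 0.1), nrow(x)))
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_gte(mutual_information(x, x), mutual_information(x, y))
  expect_lte(abs(mutual_information(x, matrix(runif(length(x)), nrow(x)))),
             0.15)  # near the independence bound on images this size
  expect_error(mutual_information(x, matrix(0.5, nrow(x), ncol(x))),
               "constant")
})

test_that("self-registration returns the identity within tolerance", {
  x <- tiny_phantom(seed = 5, h = 96, w = 96)$clean
  t <- register_rigid(x, x, reg_config(max_shift = 8, max_rot = 1))
  expect_lt(abs(t$dx), 0.1)
  expect_lt(abs(t$dy), 0.1)
  expect_lt(abs(t$theta), 0.05)
  expect_error(register_rigid(x, matrix(0.3, 96, 96)), "constant")
  expect_error(register_rigid(x, x[1:64, 1:64]), "height and width")
})

test_that("known rigid perturbations are recovered on noisy phantoms", {
  for (tr in 1:4) {
    ph <- make_phantom(128, 256, seed = 40 + tr)
    acq <- acquire_frames(ph, 2, motion_scale = c(8, 2), seed = 50 + tr)
    tru <- rigid_invert(acq$stack$true_motions[[2]])
    est <- register_rigid(acq$stack$frames[[2]], acq$stack$frames[[1]])
    expect_lt(abs(est$dx - tru$dx), 0.5)
    expect_lt(abs(est$dy - tru$dy), 0.5)
    expect_lt(abs(est$theta - tru$theta), 0.25)
  }
})

test_that("registering pure noise yields a low flagged MI", {
  ph <- make_phantom(128, 128, seed = 6)
  set.seed(7)
  noise <- matrix(runif(128 * 128), 128, 128)
  t <- register_rigid(noise, ph$clean)
  expect_lt(attr(t, "mi"), 0.2)  # near the decorrelated floor
})

test_that("the correlation rule excludes decorrelated frames only", {
  ph <- tiny_phantom(seed = 8)
  acq <- acquire_frames(ph, 5, motion_scale = c(0, 0), seed = 9)
  stk <- acq$stack
  expect_length(exclude_poor_fixation(stk, 1), 0)
  # frame identical to the reference is always retained
  stk$frames[[3]] <- stk$frames[[1]]
  expect_false(3L %in% exclude_poor_fixation(stk, 1))
  # an independent noise frame is excluded
  set.seed(10)
  stk$frames[[4]] <- matrix(runif(64 * 64), 64, 64)
  expect_identical(as.integer(exclude_poor_fixation(stk, 1)), 4L)
  # threshold 1.0 excludes every noisy non-identical frame
  excl <- exclude_poor_fixation(stk, 1, threshold_fraction = 1.0)
  expect_setequal(setdiff(2:5, 3L), excl)
  expect_false(1L %in% excl)
  expect_error(exclude_poor_fixation(stk, 99), "out of range")
})

test_that("frame averaging obeys its algebraic identities", {
  ph <- tiny_phantom(seed = 11)
  acq <- acquire_frames(ph, 3, motion_scale = c(0, 0), seed = 12)
  stk <- acq$stack
  expect_identical(average_frames(stk, 2), stk$frames[[2]])
  # two pointwise-complementary frames average to 0.5 everywhere
  x <- stk$frames[[1]]
  stk2 <- frame_stack(list(x, 1 - x), aligned = TRUE)
  expect_equal(average_frames(stk2), matrix(0.5, 64, 64), tolerance = 1e-12)
  expect_error(average_frames(stk, integer(0)), "non-empty")
  stk$excluded <- 3L
  expect_error(average_frames(stk, c(1, 3)), "excluded")
})

test_that("averaging 8 additive-noise frames attains the sigma^2/8 oracle", {
  ph <- make_phantom(96, 96, seed = 13)
  stack <- additive_noise_stack(ph, 8, 0.05, seed = 14)
  mse <- mean((average_frames(stack) - ph$clean)^2)
  expect_lt(abs(mse - 0.05^2 / 8) / (0.05^2 / 8), 0.2)
})

test_that("the full averaging pipeline handles clean and fixation-loss stacks", {
  ph <- make_phantom(64, 64, seed = 15, speckle_shape = Inf, sensor_sigma = 0)
  acq <- acquire_frames(ph, 4, motion_scale = c(0, 0), seed = 16)
  out <- enhance_by_averaging(acq$stack, k = 3)
  expect_equal(out$image, ph$clean, tolerance = 1e-12)
  # one decorrelated frame among six: exclusion removes exactly that frame
  ph2 <- tiny_phantom(seed = 17)
  acq2 <- acquire_frames(ph2, 6, motion_scale = c(0, 0), seed = 18)
  stk <- acq2$stack
  set.seed(19)
  stk$frames[[2]] <- matrix(runif(64 * 64), 64, 64)
  out2 <- enhance_by_averaging(stk, k = 5)
  expect_identical(out2$registration$excluded, 2L)
  expect_error(enhance_by_averaging(stk, k = 6), "survive")
})

test_that("averaging more frames improves SSIM on a noisy stack", {
  ph <- make_phantom(128, 128, seed = 20)
  acq <- acquire_frames(ph, 5, motion_scale = c(0, 0), seed = 21)
  s1 <- ssim(average_frames(acq$stack, 1), ph$clean)
  s5 <- ssim(average_frames(acq$stack, 1:5), ph$clean)
  expect_gt(s5, s1)
})
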