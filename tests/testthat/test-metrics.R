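# Brute-force SSIM oracle: per-pixel Gaussian-window statistics computed by
# explicit loops, independent of the matrix-filter implementation.
ssim_bruteforce <- function(x, y, window = 11, sigma = 1.5,
                            c1 = 0.01^2, c2 = 0.03^2) {
  H <- nrow(x); W <- ncol(x); r <- (window - 1) / 2
  k <- -r:r
  g <- exp(-k^2 / (2 * sigma^2))
  total <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    wi <- k + i; wj <- k + j
    oki <- wi >= 1 & wi <= H; okj <- wj >= 1 & wj <= W
    wmat <- outer(g[oki], g[okj])
    wmat <- wmat / sum(wmat)
    xs <- x[wi[oki], wj[okj]]; ys <- y[wi[oki], wj[okj]]
    ux <- sum(wmat * xs); uy <- sum(wmat * ys)
    vx <- sum(wmat * xs^2) - ux^2; vy <- sum(wmat * ys^2) - uy^2
    vxy <- sum(wmat * xs * ys) - ux * uy
    total <- total + ((2 * ux * uy + c1) * (2 * vxy + c2)) /
      ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  }
  total / (H * W)
}

test_that("ssim matches a brute-force per-window oracle", {
  set.seed(1)
  x <- matrix(runif(18 * 14, 0.1, 0.9), 18, 14)
  y <- matrix(runif(18 * 14, 0.1, 0.9), 18, 14)
  expect_equal(ssim(x, y), ssim_bruteforce(x, y), tolerance = 1e-10)
})

test_that("ssim satisfies identity, symmetry, bounds and sign properties", {
  set.seed(2)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_identical(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_true(ssim(x, y) >= -1 && ssim(x, y) <= 1)
  expect_lt(ssim(x, y), 1)
  # anti-correlated binary images have a negative structure term
  b <- matrix(rep(c(0, 1), length.out = 64 * 64), 64, 64)
  expect_lt(ssim(b, 1 - b), 0)
  # independent noise fields: SSIM near zero on average
  vals <- vapply(1:10, function(s) {
    set.seed(100 + s)
    ssim(matrix(runif(64^2), 64), matrix(runif(64^2), 64))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(ssim(x, y[1:32, ]), "height and width")
})

test_that("psnr closed forms, sentinel and monotonicity hold", {
  set.seed(3)
  ref <- matrix(runif(40 * 40, 0.2, 0.8), 40, 40)
  expect_identical(psnr(ref, ref), Inf)
  expect_equal(psnr(ref + 0.1, ref), 20)
  expect_equal(psnr(ref + 0.01, ref), 40)
  # strictly decreasing in MSE
  expect_gt(psnr(ref + 0.01, ref), psnr(ref + 0.02, ref))
  # invariant to a simultaneous spatial permutation
  p <- sample(1600)
  x <- ref + matrix(rnorm(1600, 0, 0.03), 40, 40)
  xp <- matrix(as.vector(x)[p], 40, 40)
  refp <- matrix(as.vector(ref)[p], 40, 40)
  expect_equal(psnr(x, ref), psnr(xp, refp))
})

test_that("cnr matches the hand-evaluated formula and its invariances", {
  # high ROI pixels alternate 0.79/0.81 (mean 0.8, population var 1e-4);
  # low ROI pixels alternate 0.19/0.21 (mean 0.2, population var 1e-4)
  img <- matrix(0.5, 20, 20)
  img[1:4, 1:4] <- matrix(rep(c(0.79, 0.81), 8), 4, 4)
  img[10:13, 1:4] <- matrix(rep(c(0.19, 0.21), 8), 4, 4)
  pair <- roi_pair("IPL/INL", matrix(c(1, 1), 1), matrix(c(10, 1), 1))
  res <- cnr(img, pair)
  expect_equal(res$h, 0.8)
  expect_equal(res$l, 0.2)
  expect_equal(res$cnr, 0.6 / sqrt(2e-4), tolerance = 1e-12)
  # invariant under adding a constant and under positive rescaling
  expect_equal(cnr(img + 0.05, pair)$cnr, res$cnr, tolerance = 1e-9)
  expect_equal(cnr(img * 0.37, pair)$cnr, res$cnr, tolerance = 1e-9)
  expect_equal(cnr(img * 0.5 + 0.1, pair)$cnr, res$cnr, tolerance = 1e-9)
  # degenerate ROIs (both variances zero) raise an informative error
  flat <- matrix(0.5, 20, 20)
  expect_error(cnr(flat, pair), "degenerate")
  # out-of-bounds ROI
  bad <- roi_pair("IPL/INL", matrix(c(19, 19), 1), matrix(c(1, 1), 1))
  expect_error(cnr(img, bad), "bounds")
})

test_that("auto_rois places label-pure windows at equal intervals", {
  ph <- make_phantom(128, 256, seed = 4)
  layers <- attr(ph$layer_map, "layers")
  for (pn in c("IPL/INL", "choroid/background")) {
    pr <- auto_rois(ph$layer_map, pn, n_pairs = 50, seed = 1)
    expect_equal(nrow(pr$high), 50)
    expect_equal(nrow(pr$low), 50)
    ids <- cnr_pairs()[[pn]]
    for (i in 1:50) {
      blk <- ph$layer_map[pr$high[i, 1] + 0:3, pr$high[i, 2] + 0:3]
      expect_true(all(blk == match(ids[1], layers)))
      blk <- ph$layer_map[pr$low[i, 1] + 0:3, pr$low[i, 2] + 0:3]
      expect_true(all(blk == match(ids[2], layers)))
    }
    # roughly equal horizontal spacing
    expect_gt(min(diff(sort(pr$high[, 2]))), 0)
  }
  # n_pairs = 1 picks the leftmost feasible pair
  one <- auto_rois(ph$layer_map, "IPL/INL", n_pairs = 1)
  all50 <- auto_rois(ph$layer_map, "IPL/INL", n_pairs = 50)
  expect_equal(one$high[1, 2], min(all50$high[, 2]))
  # absent/too-thin layer errors
  lm <- ph$layer_map
  lm[lm == match("ELM", layers)] <- match("ONL", layers)
  attr(lm, "layers") <- layers
  expect_error(auto_rois(lm, "ELM/ONL"), "absent")
})

test_that("all six cnr pairs are positive on the clean phantom and grow
           under averaging", {
  ph <- make_phantom(128, 256, seed = 5)
  vals <- cnr_all_pairs(ph$clean, ph$layer_map)
  expect_length(vals, 6)
  expect_true(all(vals > 0))
  acq <- acquire_frames(ph, 8, motion_scale = c(0, 0), seed = 6)
  c1 <- cnr_all_pairs(acq$stack$frames[[1]], ph$layer_map)
  c8 <- cnr_all_pairs(average_frames(acq$stack), ph$layer_map)
  expect_true(all(c8 > c1))
})

# Independent kappa oracle: explicit contingency table and weight loops.
kappa_bruteforce <- function(a, b, weighting, levels = 1:3) {
  k <- length(levels); n <- length(a)
  O <- matrix(0, k, k); Ra <- numeric(k); Rb <- numeric(k)
  for (i in seq_len(n)) {
    ia <- match(a[i], levels); ib <- match(b[i], levels)
    O[ia, ib] <- O[ia, ib] + 1
    Ra[ia] <- Ra[ia] + 1; Rb[ib] <- Rb[ib] + 1
  }
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- if (weighting == "linear") abs(i - j) else (i - j)^2
    num <- num + w * O[i, j] / n
    den <- den + w * (Ra[i] / n) * (Rb[j] / n)
  }
  if (den == 0) NA_real_ else 1 - num / den
}

test_that("weighted kappa closed forms hold", {
  expect_equal(weighted_kappa(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
  expect_equal(weighted_kappa(c(1, 1, 2, 2), c(2, 2, 1, 1), "linear"), -1)
  expect_error(weighted_kappa(1:3, 1:2), "equal length")
  expect_error(weighted_kappa(integer(0), integer(0)), "empty")
  expect_error(weighted_kappa(c(2, 2), c(2, 2)), "undefined")
  expect_error(weighted_kappa(c(1, 9), c(1, 2)), "ordinal range")
})

test_that("weighted kappa agrees exactly with the brute-force oracle", {
  # exhaustive over all 3-category score pairs of length 3
  grid <- as.matrix(expand.grid(rep(list(1:3), 3)))
  for (w in c("linear", "quadratic")) {
    for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
      a <- grid[i, ]; b <- grid[j, ]
      ref <- kappa_bruteforce(a, b, w)
      if (is.na(ref)) next
      expect_equal(weighted_kappa(a, b, w, levels = 1:3), ref,
                   tolerance = 1e-12)
    }
  }
  # random longer vectors (n = 4..6) under a fixed seed
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(4:6, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    ref <- kappa_bruteforce(a, b, "quadratic")
    if (is.na(ref)) next
    expect_equal(weighted_kappa(a, b, "quadratic", levels = 1:3), ref,
                 tolerance = 1e-12)
  }
})

test_that("kappa of independent uniform scores is near zero and the panel
           summary averages rater pairs", {
  set.seed(9)
  vals <- vapply(1:20, function(i) {
    a <- sample(1:5, 400, replace = TRUE)
    weighted_kappa(a, sample(a), "quadratic")
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.03)
  scores <- cbind(sample(1:5, 60, TRUE), sample(1:5, 60, TRUE),
                  sample(1:5, 60, TRUE))
  pan <- weighted_kappa_panel(scores)
  expect_equal(nrow(pan$pairwise), 3)
  expect_equal(unname(pan$mean_kappa["quadratic"]),
               mean(pan$pairwise$kappa_quadratic))
})
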