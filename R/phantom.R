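# Synthetic layered-retina phantom: ground-truth scene, layer labels, and
# emulated multi-frame acquisition (rigid eye motion, multiplicative speckle,
# additive sensor noise, occasional fixation loss).

#' Tissue classes of the phantom
#'
#' Returns the ten tissue classes used by the phantom, ordered top to bottom
#' as they appear in a B-scan (background above the tissue band, choroid
#' below the outer RPE, background again below the choroid).
#'
#' @return Character vector of the ten class names.
#' @export
#' @examples
#' oct_layers()
oct_layers <- function() {
  c("background", "IPL", "INL", "OPL", "ONL", "ELM", "IS-OS",
    "Inner-RPE", "Outer-RPE", "choroid")
}

#' High- and low-reflection tissue classes
#'
#' The high-reflection classes are IPL, OPL, ELM, IS-OS, Outer-RPE and
#' choroid; the low-reflection classes are INL, ONL, Inner-RPE and background.
#' Together they partition the label set.
#'
#' @return A list with components `high` and `low`.
#' @export
reflection_classes <- function() {
  list(high = c("IPL", "OPL", "ELM", "IS-OS", "Outer-RPE", "choroid"),
       low  = c("INL", "ONL", "Inner-RPE", "background"))
}

#' The six assessed layer pairs
#'
#' Contrast-to-noise ratio is reported for six high/low layer pairs.
#'
#' @return Named list mapping pair name to `c(high, low)` layer names.
#' @export
cnr_pairs <- function() {
  list("IPL/INL"             = c("IPL", "INL"),
       "OPL/ONL"             = c("OPL", "ONL"),
       "ELM/ONL"             = c("ELM", "ONL"),
       "IS-OS/Inner-RPE"     = c("IS-OS", "Inner-RPE"),
       "Outer-RPE/Inner-RPE" = c("Outer-RPE", "Inner-RPE"),
       "choroid/background"  = c("choroid", "background"))
}

# Mean reflectivity per class.  Chosen so that every high-reflection class
# exceeds its paired low-reflection class by a wide margin, so all six CNR
# pairs are well-defined and positive on the clean image; kept within
# [0.10, 0.85] so additive sensor noise rarely clips at [0, 1].
layer_reflectivity <- function() {
  c("background" = 0.10, "IPL" = 0.60, "INL" = 0.30, "OPL" = 0.62,
    "ONL" = 0.22, "ELM" = 0.66, "IS-OS" = 0.78, "Inner-RPE" = 0.38,
    "Outer-RPE" = 0.85, "choroid" = 0.52)
}

# Layer thickness as a fraction of image height (tissue band only; the
# remainder above/below is background).  ELM and the photoreceptor bands are
# kept >= 4 px at the default 128-px height so 4x4 ROIs always fit.
layer_thickness_fractions <- function() {
  c("IPL" = 0.08, "INL" = 0.06, "OPL" = 0.06, "ONL" = 0.09, "ELM" = 0.05,
    "IS-OS" = 0.05, "Inner-RPE" = 0.05, "Outer-RPE" = 0.06, "choroid" = 0.13)
}

# Separable Gaussian blur used to band-limit the clean scene (smooth layer
# edges help subpixel registration and avoid aliasing under bilinear warps).
gaussian_filter_matrix <- function(n, sigma, radius = ceiling(3 * sigma)) {
  idx <- seq_len(n)
  G <- matrix(0, n, n)
  k <- (-radius):radius
  w <- exp(-k^2 / (2 * sigma^2))
  for (j in seq_along(k)) {
    src <- idx + k[j]
    ok <- src >= 1 & src <= n
    G[cbind(idx[ok], src[ok])] <- G[cbind(idx[ok], src[ok])] + w[j]
  }
  G / rowSums(G)
}

blur2 <- function(img, sigma) {
  Gr <- gaussian_filter_matrix(nrow(img), sigma)
  Gc <- gaussian_filter_matrix(ncol(img), sigma)
  Gr %*% img %*% t(Gc)
}

#' Generate a layered-retina phantom with ground truth
#'
#' Builds a noise-free B-scan of a ten-class layered retina with smooth
#' (low-order polynomial) layer boundaries, a foveal dip, vessel shadows and
#' choroidal texture, plus the per-pixel layer-label map.  Optional lesions
#' (hypo-reflective fluid ellipses or hyper-reflective foci) modify
#' reflectivity inside the tissue band only.
#'
#' @param height,width Image size in pixels; both must be at least 64.
#' @param lesion_spec Optional list of lesions; each lesion is a list with
#'   fields `type` ("fluid" or "focus"), `center` (c(row, col)), `axes`
#'   (c(semi-height, semi-width) in px) and `offset` (reflectivity change,
#'   negative for fluid, positive for a focus).
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative speckle
#'   used at acquisition (`Inf` disables speckle).
#' @param sensor_sigma Standard deviation of additive Gaussian sensor noise.
#' @return An object of class `phantom_truth` with fields `clean` (matrix in
#'   `[0,1]`), `layer_map` (integer matrix with a `layers` attribute),
#'   `motions` (filled by [acquire_frames()]), `speckle_shape`,
#'   `sensor_sigma` and `lesion_spec`.
#' @export
#' @examples
#' ph <- make_phantom(64, 64, seed = 1)
#' range(ph$clean)
make_phantom <- function(height, width, lesion_spec = NULL, seed = 1,
                         speckle_shape = 8, sensor_sigma = 0.02) {
  if (!is.numeric(height) || !is.numeric(width) || height < 64 || width < 64) {
    stop("phantom size must be at least 64 x 64 pixels", call. = FALSE)
  }
  height <- as.integer(height); width <- as.integer(width)
  refl <- layer_reflectivity()
  layers <- oct_layers()
  with_seed(seed, {
    x <- seq(0, 1, length.out = width)
    # top of the tissue band: gentle random tilt/curvature + foveal dip
    tilt <- stats::rnorm(1, 0, 0.02)
    curv <- stats::rnorm(1, 0, 0.03)
    fovea_depth <- stats::runif(1, 0.04, 0.07)
    fovea_width <- stats::runif(1, 0.08, 0.14)
    top_frac <- 0.18 + tilt * (x - 0.5) + curv * (x - 0.5)^2 +
      fovea_depth * exp(-(x - 0.5)^2 / (2 * fovea_width^2))
    thick <- layer_thickness_fractions()
    # small smooth per-layer thickness undulation (gives horizontal structure)
    und <- lapply(seq_along(thick), function(i) {
      a <- stats::runif(1, 0, 0.012); ph <- stats::runif(1, 0, 2 * pi)
      f <- stats::runif(1, 1, 3)
      a * sin(2 * pi * f * x + ph)
    })
    bounds <- matrix(0, length(thick) + 1, width)  # row i: top of layer i
    bounds[1, ] <- top_frac * height
    for (i in seq_along(thick)) {
      bounds[i + 1, ] <- bounds[i, ] + (thick[i] + und[[i]]) * height
    }
    # inner layers thin towards the fovea (dip pinches IPL..ONL)
    pinch <- 0.5 * exp(-(x - 0.5)^2 / (2 * fovea_width^2))
    for (i in 2:5) {
      bounds[i, ] <- bounds[1, ] + (bounds[i, ] - bounds[1, ]) * (1 - 0.35 * pinch)
    }

    lab <- matrix(1L, height, width)  # 1 = background
    rowidx <- seq_len(height)
    band_names <- names(thick)
    for (cix in seq_len(width)) {
      for (i in seq_along(band_names)) {
        r0 <- bounds[i, cix]; r1 <- bounds[i + 1, cix]
        inside <- rowidx > r0 & rowidx <= r1
        lab[inside, cix] <- match(band_names[i], layers)
      }
    }

    clean <- matrix(refl[layers][lab], height, width)
    # low-frequency 2-D reflectivity texture inside the tissue band
    # (illumination variation and tissue inhomogeneity); gives the rigid
    # registration genuine horizontal as well as vertical structure
    yy <- seq(0, 1, length.out = height)
    tex <- matrix(0, height, width)
    for (s in 1:3) {
      fx <- stats::runif(1, 1, 4); fy <- stats::runif(1, 0.5, 2)
      phs <- stats::runif(1, 0, 2 * pi)
      tex <- tex + 0.04 * sin(2 * pi * (outer(yy * fy, x * fx, `+`)) + phs)
    }
    band <- lab != 1L
    clean[band] <- (clean * (1 + tex))[band]
    # choroidal vessels: dark blobs inside the choroid
    cho <- match("choroid", layers)
    n_ves <- 8L
    ves_cols <- stats::runif(n_ves, 0.05, 0.95) * width
    for (v in seq_len(n_ves)) {
      ccol <- ves_cols[v]
      rows_v <- which(lab[, max(1L, min(width, round(ccol)))] == cho)
      if (!length(rows_v)) next
      crow <- stats::runif(1, min(rows_v), max(rows_v))
      a <- stats::runif(1, 2.5, 5); b <- stats::runif(1, 4, 9)
      rr <- matrix(rowidx, height, width)
      cc <- matrix(seq_len(width), height, width, byrow = TRUE)
      inside <- ((rr - crow) / a)^2 + ((cc - ccol) / b)^2 <= 1 & lab == cho
      clean[inside] <- clean[inside] * 0.45
    }
    # vessel shadows: vertical attenuation bands through the outer retina
    n_sh <- 5L
    for (s in seq_len(n_sh)) {
      c0 <- stats::runif(1, 0.1, 0.9) * width
      wdt <- stats::runif(1, 2, 6)
      att <- 1 - stats::runif(1, 0.25, 0.45) *
        exp(-(seq_len(width) - c0)^2 / (2 * wdt^2))
      shade <- sweep(matrix(1, height, width), 2, att, `*`)
      deep <- lab %in% match(c("ONL", "ELM", "IS-OS", "Inner-RPE",
                               "Outer-RPE", "choroid"), layers)
      deep <- matrix(deep, height, width)
      clean[deep] <- (clean * shade)[deep]
    }

    # lesions: reflectivity change inside the tissue band only
    if (!is.null(lesion_spec)) {
      band <- lab != 1L
      for (les in lesion_spec) {
        ctr <- les$center; ax <- les$axes
        if (ctr[1] < 1 || ctr[1] > height || ctr[2] < 1 || ctr[2] > width) {
          stop("lesion center outside image bounds", call. = FALSE)
        }
        rr <- matrix(rowidx, height, width)
        cc <- matrix(seq_len(width), height, width, byrow = TRUE)
        inside <- ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
        off <- if (!is.null(les$offset)) les$offset
               else if (identical(les$type, "fluid")) -0.35 else 0.25
        clean[inside & band] <- clean[inside & band] + off
      }
    }

    clean <- clamp01(blur2(clean, sigma = 1.0))
    structure(list(clean = clean,
                   layer_map = structure(lab, layers = layers),
                   motions = NULL,
                   reference_index = NA_integer_,
                   fixation_loss = integer(0),
                   speckle_shape = speckle_shape,
                   sensor_sigma = sensor_sigma,
                   lesion_spec = lesion_spec,
                   seed = as.integer(seed)),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth %d x %d px, speckle shape %s, sensor sigma %.3f>\n",
              nrow(x$clean), ncol(x$clean),
              format(x$speckle_shape), x$sensor_sigma))
  invisible(x)
}

#' Construct a frame stack
#'
#' @param frames List of same-sized numeric matrices in `[0,1]`.
#' @param aligned Logical; `TRUE` when frames share the reference geometry.
#' @param reference_index Index of the reference frame.
#' @param excluded Integer vector of excluded frame indices.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, aligned = FALSE, reference_index = 1L,
                        excluded = integer(0)) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!all(dim(f) == d)) stop("all frames must share height/width", call. = FALSE)
  }
  if (reference_index %in% excluded) {
    stop("the reference frame cannot be excluded", call. = FALSE)
  }
  structure(list(frames = frames, aligned = aligned,
                 reference_index = as.integer(reference_index),
                 excluded = as.integer(excluded),
                 true_motions = NULL, fixation_loss = integer(0)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack %d frames of %d x %d px, %s, ref %d, %d excluded>\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              if (x$aligned) "aligned" else "unaligned",
              x$reference_index, length(x$excluded)))
  invisible(x)
}

#' Emulate a repeated B-scan acquisition
#'
#' Produces `n_frames` frames of the phantom scene: each frame is the clean
#' image warped by a per-frame rigid motion (drawn uniformly within
#' `motion_scale`; the reference frame keeps the identity), multiplied by
#' i.i.d. unit-mean Gamma speckle with shape `truth$speckle_shape`, plus
#' additive Gaussian sensor noise of sd `truth$sensor_sigma`, clipped to
#' `[0,1]`.  With probability `p_fixation_loss` a non-reference frame is
#' replaced by a decorrelated pure-noise frame (fixation loss).  The true
#' motions and loss indices are recorded on the returned stack and on the
#' returned copy of the truth object.
#'
#' @param truth A `phantom_truth` from [make_phantom()].
#' @param n_frames Number of frames (>= 1); the emulated scanner collects up
#'   to 50 frames per location.
#' @param motion_scale Length-2 vector `c(max_shift_px, max_rotation_deg)`.
#' @param p_fixation_loss Probability in `[0, 1)` that a frame is a fixation
#'   loss.
#' @param seed Integer seed; acquisition is deterministic given
#'   `(truth, arguments, seed)`.
#' @return A list with components `stack` (a `frame_stack` carrying
#'   `true_motions` and `fixation_loss`) and `truth` (the input truth with the
#'   same bookkeeping filled in).
#' @export
#' @examples
#' ph <- make_phantom(64, 64, seed = 1, speckle_shape = Inf, sensor_sigma = 0)
#' acq <- acquire_frames(ph, 3, motion_scale = c(0, 0), seed = 1)
#' identical(acq$stack$frames[[2]], ph$clean)
acquire_frames <- function(truth, n_frames, motion_scale = c(4, 1),
                           p_fixation_loss = 0, seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (any(motion_scale < 0)) stop("motion_scale must be non-negative", call. = FALSE)
  if (p_fixation_loss < 0 || p_fixation_loss >= 1) {
    stop("p_fixation_loss must lie in [0, 1)", call. = FALSE)
  }
  clean <- truth$clean
  H <- nrow(clean); W <- ncol(clean)
  bg <- layer_reflectivity()[["background"]]
  ref <- 1L
  with_seed(seed, {
    motions <- vector("list", n_frames)
    frames <- vector("list", n_frames)
    loss <- logical(n_frames)
    for (i in seq_len(n_frames)) {
      if (i == ref) {
        motions[[i]] <- rigid_transform(0, 0, 0)
      } else {
        motions[[i]] <- rigid_transform(
          stats::runif(1, -motion_scale[1], motion_scale[1]),
          stats::runif(1, -motion_scale[1], motion_scale[1]),
          stats::runif(1, -motion_scale[2], motion_scale[2]))
        loss[i] <- stats::runif(1) < p_fixation_loss
      }
      base <- warp_rigid(clean, motions[[i]], fill = bg)$img
      if (loss[i]) {
        # decorrelated frame: speckled flat field at the scene's mean level
        base <- matrix(mean(clean), H, W)
      }
      if (is.finite(truth$speckle_shape)) {
        sp <- matrix(stats::rgamma(H * W, shape = truth$speckle_shape,
                                   rate = truth$speckle_shape), H, W)
        base <- base * sp
      }
      if (truth$sensor_sigma > 0) {
        base <- base + matrix(stats::rnorm(H * W, 0, truth$sensor_sigma), H, W)
      }
      frames[[i]] <- clamp01(base)
    }
    stk <- frame_stack(frames, aligned = all(motion_scale == 0) && !any(loss),
                       reference_index = ref)
    stk$true_motions <- motions
    stk$fixation_loss <- which(loss)
    truth$motions <- motions
    truth$reference_index <- ref
    truth$fixation_loss <- which(loss)
    list(stack = stk, truth = truth)
  })
}
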