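# Traditional enhancement path: SNR-based reference selection, rigid
# registration by mutual-information maximization, correlation-based
# exclusion of poorly fixated frames, and pixel-wise averaging.

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram of `[0,1]`
#' intensities; used to split tissue from background for SNR estimation.
#'
#' @param img Numeric matrix in `[0,1]`.
#' @param bins Number of histogram bins.
#' @return The threshold (bin upper edge) as a scalar.
#' @export
otsu_threshold <- function(img, bins = 256) {
  stopifnot_bscan(img)
  v <- as.vector(img)
  h <- tabulate(pmin(pmax(floor(v * bins) + 1L, 1L), bins), nbins = bins)
  p <- h / sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)
  mids[which.max(bcv)] + 0.5 / bins
}

# SNR estimate: mean tissue intensity / sd of background intensity, with the
# tissue/background split by Otsu thresholding of the frame itself.
frame_snr <- function(img) {
  thr <- otsu_threshold(img)
  tissue <- img[img >= thr]
  bg <- img[img < thr]
  if (length(bg) < 2 || stats::sd(bg) == 0) return(Inf)
  if (!length(tissue)) return(0)
  mean(tissue) / stats::sd(bg)
}

#' Select the reference frame by signal-to-noise ratio
#'
#' The frame with the strongest SNR estimate — mean tissue intensity over the
#' standard deviation of background intensity, with tissue and background
#' split by Otsu thresholding — is selected as the registration reference.
#' Ties (including multiple infinite-SNR frames) break to the lowest index.
#'
#' @param stack A `frame_stack`.
#' @return Integer index of the reference frame.
#' @export
select_reference <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!length(stack$frames)) stop("empty frame stack", call. = FALSE)
  snr <- vapply(stack$frames, frame_snr, numeric(1))
  which.max(snr)  # which.max returns the first maximum (lowest index)
}

#' Mutual information between two images
#'
#' Shannon mutual information (nats) of the joint intensity histogram over
#' `bins` equal-width bins on `[0,1]`, restricted to pixels where `valid` is
#' `TRUE`.
#'
#' @param x,y Numeric matrices in `[0,1]` of equal size.
#' @param bins Number of histogram bins per axis.
#' @param valid Optional logical matrix restricting the histogram.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = 32, valid = NULL) {
  same_shape(x, y)
  vx <- as.vector(x); vy <- as.vector(y)
  if (!is.null(valid)) {
    vx <- vx[valid]; vy <- vy[valid]
  }
  if (!length(vx)) stop("no valid pixels for mutual information", call. = FALSE)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stop("mutual information undefined for a constant image", call. = FALSE)
  }
  ix <- pmin(pmax(floor(vx * bins) + 1L, 1L), bins)
  iy <- pmin(pmax(floor(vy * bins) + 1L, 1L), bins)
  pxy <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins)
  pxy <- pxy / sum(pxy)
  px <- rowSums(matrix(pxy, bins, bins))
  py <- colSums(matrix(pxy, bins, bins))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(px) + ent(py) - ent(pxy)
}

# Vertex offset of the parabola through similarity values at -1, 0, +1 grid
# steps; clipped to one step.
parabolic_peak <- function(ym, y0, yp) {
  d <- ym - 2 * y0 + yp
  if (!is.finite(d) || d >= 0) return(0)
  max(-1, min(1, 0.5 * (ym - yp) / d))
}

#' Registration settings
#'
#' @param bins Joint-histogram bin count for mutual information.
#' @param max_shift Translation search bound in pixels (exhaustive grid).
#' @param max_rot Rotation search bound in degrees.
#' @param rot_step Rotation grid step (degrees) for the coarse stage.
#' @param fine_rot_step Rotation step (degrees) for the local refinement.
#' @param shift_step Translation grid step (pixels) for the coarse stage.
#' @param smooth_sigma Gaussian pre-smoothing (pixels) applied to both images
#'   before the similarity is evaluated; suppresses the speckle-induced
#'   preference for half-pixel (maximally interpolating) shifts.
#' @param fill Fill value for out-of-bounds pixels when warping.
#' @return A list of settings for [register_rigid()].
#' @export
reg_config <- function(bins = 32, max_shift = 12, max_rot = 3,
                       rot_step = 0.75, fine_rot_step = 0.1, shift_step = 2,
                       smooth_sigma = 1, fill = 0.10) {
  list(bins = bins, max_shift = max_shift, max_rot = max_rot,
       rot_step = rot_step, fine_rot_step = fine_rot_step,
       shift_step = shift_step, smooth_sigma = smooth_sigma, fill = fill)
}

#' Rigid registration by mutual-information maximization
#'
#' Finds the rigid transform that, applied to `moving`, maximizes the mutual
#' information with `reference`.  Both images are Gaussian pre-smoothed;
#' the similarity is always evaluated on a fixed central window (margin
#' `max_shift + 1`), so every candidate pose is scored on the same number of
#' pixels and the small-sample bias of the histogram MI estimate cannot tilt
#' the search.  The search is an exhaustive integer-translation grid per
#' coarse rotation, a fine rotation scan, and parabolic sub-pixel /
#' sub-degree peak interpolation on the lattice — which avoids the
#' interpolation-smoothing artifacts that plague optimizing histogram MI over
#' continuously warped speckle images.  Deterministic given the config.
#'
#' @param moving,reference Numeric matrices in `[0,1]` of equal size.
#' @param config Settings from [reg_config()].
#' @return A `rigid_transform` with attributes `mi` (final mutual
#'   information, nats) and `mi_independent` (MI at a large decorrelating
#'   offset, a floor for flagging failed alignments).
#' @export
register_rigid <- function(moving, reference, config = reg_config()) {
  stopifnot_bscan(moving); stopifnot_bscan(reference)
  same_shape(moving, reference)
  if (stats::sd(moving) == 0) {
    stop("moving image is constant; mutual information undefined", call. = FALSE)
  }
  if (stats::sd(reference) == 0) {
    stop("reference image is constant; mutual information undefined", call. = FALSE)
  }
  H <- nrow(reference); W <- ncol(reference)
  bins <- config$bins
  R <- as.integer(config$max_shift) + 1L
  if (H - 2L * R < 8 || W - 2L * R < 8) {
    stop("image too small for the configured max_shift", call. = FALSE)
  }
  movb <- if (config$smooth_sigma > 0) blur2(moving, config$smooth_sigma) else moving
  refb <- if (config$smooth_sigma > 0) blur2(reference, config$smooth_sigma) else reference
  rows <- (R + 1L):(H - R); cols <- (R + 1L):(W - R)
  refw <- refb[rows, cols]
  rows2 <- rows[seq(1L, length(rows), 2L)]
  cols2 <- cols[seq(1L, length(cols), 2L)]
  refw2 <- refb[rows2, cols2]
  mi_at <- function(m, dx, dy, coarse = FALSE) {
    val <- try(if (coarse) {
      mutual_information(m[rows2 - dy, cols2 - dx], refw2, bins = bins)
    } else {
      mutual_information(m[rows - dy, cols - dx], refw, bins = bins)
    }, silent = TRUE)
    if (inherits(val, "try-error")) -Inf else val
  }
  rot_img <- function(th) {
    if (th == 0) movb else
      warp_rigid(movb, rigid_transform(0, 0, th), fill = config$fill)$img
  }
  shifts <- unique(as.integer(round(
    seq(-config$max_shift, config$max_shift, by = config$shift_step))))
  rots <- if (config$max_rot > 0) {
    seq(-config$max_rot, config$max_rot, by = config$rot_step)
  } else 0
  mis_th <- rep(-Inf, length(rots))
  best <- list(ti = 1L, sh = c(0L, 0L)); best_mi <- -Inf
  for (ti in seq_along(rots)) {
    mth <- rot_img(rots[ti])
    b <- c(0L, 0L); bm <- -Inf
    for (dx in shifts) for (dy in shifts) {
      mi <- mi_at(mth, dx, dy, coarse = TRUE)
      if (mi > bm) { bm <- mi; b <- c(dx, dy) }
    }
    for (dx in (b[1] - 1L):(b[1] + 1L)) for (dy in (b[2] - 1L):(b[2] + 1L)) {
      if (max(abs(c(dx, dy))) > config$max_shift) next
      mi <- mi_at(mth, dx, dy)
      if (mi > bm) { bm <- mi; b <- c(dx, dy) }
    }
    mis_th[ti] <- bm
    if (bm > best_mi) { best_mi <- bm; best <- list(ti = ti, sh = b) }
  }
  th0 <- rots[best$ti]
  b <- best$sh
  # fine rotation scan around the coarse winner, translation held fixed
  th_star <- th0
  if (length(rots) > 1) {
    fine <- seq(th0 - config$rot_step, th0 + config$rot_step,
                by = config$fine_rot_step)
    mif <- vapply(fine, function(th) mi_at(rot_img(th), b[1], b[2]), numeric(1))
    i0 <- which.max(mif)
    th_star <- fine[i0]
    if (i0 > 1 && i0 < length(fine)) {
      th_star <- th_star +
        parabolic_peak(mif[i0 - 1], mif[i0], mif[i0 + 1]) * config$fine_rot_step
    }
  }
  mth <- rot_img(th_star)
  bm <- -Inf; bb <- b
  for (dx in (b[1] - 2L):(b[1] + 2L)) for (dy in (b[2] - 2L):(b[2] + 2L)) {
    if (max(abs(c(dx, dy))) > config$max_shift) next
    mi <- mi_at(mth, dx, dy)
    if (mi > bm) { bm <- mi; bb <- c(dx, dy) }
  }
  gx <- vapply(-1:1, function(d) mi_at(mth, bb[1] + d, bb[2]), numeric(1))
  gy <- vapply(-1:1, function(d) mi_at(mth, bb[1], bb[2] + d), numeric(1))
  out <- rigid_transform(bb[1] + parabolic_peak(gx[1], gx[2], gx[3]),
                         bb[2] + parabolic_peak(gy[1], gy[2], gy[3]),
                         th_star)
  attr(out, "mi") <- bm
  # MI floor: decorrelate by a large diagonal offset inside the search range
  off <- as.integer(config$max_shift)
  attr(out, "mi_independent") <- mi_at(movb, off, off)
  out
}

#' Exclude poorly fixated frames
#'
#' A registered frame is excluded when its normalized cross-correlation with
#' the reference falls below `threshold_fraction` of the reference's zero-lag
#' normalized autocorrelation (which is 1), i.e. below 0.70 by default.  The
#' reference frame is never excluded.
#'
#' @param aligned A `frame_stack` with `aligned = TRUE`.
#' @param reference_index Index of the reference frame.
#' @param threshold_fraction Fraction of the reference autocorrelation below
#'   which a frame is excluded; in `(0, 1]`.
#' @return Integer vector of excluded frame indices (with the per-frame
#'   correlations as a `correlations` attribute).
#' @export
exclude_poor_fixation <- function(aligned, reference_index,
                                  threshold_fraction = 0.70) {
  stopifnot(inherits(aligned, "frame_stack"))
  n <- length(aligned$frames)
  if (reference_index < 1 || reference_index > n) {
    stop("reference index out of range", call. = FALSE)
  }
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("threshold_fraction must lie in (0, 1]", call. = FALSE)
  }
  ref <- aligned$frames[[reference_index]]
  cors <- vapply(seq_len(n), function(i) {
    if (i == reference_index) return(1)
    f <- aligned$frames[[i]]
    if (stats::sd(f) == 0 || stats::sd(ref) == 0) return(0)
    stats::cor(as.vector(f), as.vector(ref))
  }, numeric(1))
  excl <- setdiff(which(cors < threshold_fraction - 1e-12), reference_index)
  structure(as.integer(excl), correlations = cors)
}

#' Average aligned frames
#'
#' Pixel-wise arithmetic mean of the selected aligned frames.
#'
#' @param aligned A `frame_stack` with `aligned = TRUE`.
#' @param subset Indices of the frames to average; must be non-empty and must
#'   not contain excluded frames.
#' @return The averaged B-scan (matrix in `[0,1]`).
#' @export
average_frames <- function(aligned, subset = seq_along(aligned$frames)) {
  stopifnot(inherits(aligned, "frame_stack"))
  if (!length(subset)) stop("subset must be non-empty", call. = FALSE)
  if (any(subset < 1 | subset > length(aligned$frames))) {
    stop("subset index out of range", call. = FALSE)
  }
  if (length(intersect(subset, aligned$excluded))) {
    stop("subset contains excluded frames", call. = FALSE)
  }
  acc <- aligned$frames[[subset[1]]]
  if (length(subset) > 1) {
    for (i in subset[-1]) acc <- acc + aligned$frames[[i]]
  }
  clamp01(acc / length(subset))
}

#' Traditional multi-frame enhancement (Avg-k)
#'
#' Composes the traditional path: reference selection by SNR, rigid
#' mutual-information registration of every frame to the reference,
#' exclusion of poorly fixated frames by the correlation rule, and pixel-wise
#' averaging of the first `k` surviving frames in acquisition order.
#'
#' @param stack A `frame_stack` (aligned or not).
#' @param k Number of frames to average.
#' @param config Settings from [reg_config()].
#' @param threshold_fraction Exclusion threshold (see
#'   [exclude_poor_fixation()]).
#' @return A list with `image` (the Avg-k B-scan), `registration` (a
#'   `registration_result` with per-frame transforms, MI values, correlations
#'   and exclusions) and `aligned` (the registered `frame_stack`).  The
#'   enhanced image lives in the geometry of the selected reference frame.
#' @export
enhance_by_averaging <- function(stack, k, config = reg_config(),
                                 threshold_fraction = 0.70) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ref_idx <- select_reference(stack)
  transforms <- vector("list", n)
  mi_values <- rep(NA_real_, n)
  if (stack$aligned) {
    for (i in seq_len(n)) transforms[[i]] <- rigid_transform(0, 0, 0)
    aligned <- stack
    aligned$reference_index <- ref_idx
  } else {
    ref <- stack$frames[[ref_idx]]
    frames <- stack$frames
    for (i in seq_len(n)) {
      if (i == ref_idx) {
        transforms[[i]] <- rigid_transform(0, 0, 0)
        mi_values[i] <- mutual_information(ref, ref, bins = config$bins)
        next
      }
      tf <- register_rigid(stack$frames[[i]], ref, config)
      transforms[[i]] <- tf
      mi_values[i] <- attr(tf, "mi")
      frames[[i]] <- warp_rigid(stack$frames[[i]], tf, fill = config$fill)$img
    }
    aligned <- frame_stack(frames, aligned = TRUE, reference_index = ref_idx)
    aligned$true_motions <- stack$true_motions
    aligned$fixation_loss <- stack$fixation_loss
  }
  excl <- exclude_poor_fixation(aligned, ref_idx, threshold_fraction)
  aligned$excluded <- as.integer(excl)
  survivors <- setdiff(seq_len(n), excl)
  if (length(survivors) < k) {
    stop(sprintf("only %d frames survive exclusion; %d requested",
                 length(survivors), k), call. = FALSE)
  }
  img <- average_frames(aligned, survivors[seq_len(k)])
  reg <- structure(list(transforms = transforms, mi_values = mi_values,
                        correlations = attr(excl, "correlations"),
                        excluded = as.integer(excl),
                        reference_index = ref_idx),
                   class = "registration_result")
  list(image = img, registration = reg, aligned = aligned)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result %d frames, ref %d, %d excluded>\n",
              length(x$transforms), x$reference_index, length(x$excluded)))
  invisible(x)
}
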