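# Quantitative assessment: SSIM, PSNR, paired-ROI CNR over the six layer
# pairs, and weighted Cohen's kappa for rater agreement.

# Cache of Gaussian filter matrices keyed by "n|window|sigma".
.filter_cache <- new.env(parent = emptyenv())

ssim_filter <- function(n, window = 11, sigma = 1.5) {
  key <- paste(n, window, sigma, sep = "|")
  got <- .filter_cache[[key]]
  if (!is.null(got)) return(got)
  radius <- (window - 1) / 2
  G <- gaussian_filter_matrix(n, sigma, radius = radius)
  .filter_cache[[key]] <- G
  G
}

# Separable Gaussian filtering with border renormalization; `adjoint = TRUE`
# applies the transpose operator (needed for the SSIM gradient).
ssim_smooth <- function(X, window, sigma, adjoint = FALSE) {
  Gr <- ssim_filter(nrow(X), window, sigma)
  Gc <- ssim_filter(ncol(X), window, sigma)
  if (adjoint) t(Gr) %*% X %*% Gc else Gr %*% X %*% t(Gc)
}

# Core SSIM computation; returns the SSIM map and, if `grad`, the gradient of
# mean(SSIM) with respect to x.  Local statistics use a Gaussian-weighted
# window (renormalized at borders) on data range 1.
ssim_internal <- function(x, y, window, sigma, c1, c2, grad = FALSE) {
  sm <- function(z) ssim_smooth(z, window, sigma)
  ux <- sm(x); uy <- sm(y)
  vx <- sm(x * x); vy <- sm(y * y); vxy <- sm(x * y)
  sx2 <- vx - ux * ux
  sy2 <- vy - uy * uy
  sxy <- vxy - ux * uy
  A1 <- 2 * ux * uy + c1; A2 <- 2 * sxy + c2
  B1 <- ux * ux + uy * uy + c1; B2 <- sx2 + sy2 + c2
  S <- (A1 * A2) / (B1 * B2)
  if (!grad) return(list(value = mean(S), map = S))
  N <- length(x)
  # partials of S wrt the intermediate maps (ux, vx, vxy)
  dS_dsx2 <- -S / B2
  dS_dsxy <- 2 * A1 / (B1 * B2)
  dS_dux <- 2 * (uy * B1 - ux * A1) * A2 / (B1 * B1 * B2) -
    2 * ux * dS_dsx2 - uy * dS_dsxy
  adj <- function(z) ssim_smooth(z, window, sigma, adjoint = TRUE)
  gx <- (adj(dS_dux) + 2 * x * adj(dS_dsx2) + y * adj(dS_dsxy)) / N
  list(value = mean(S), map = S, grad = gx)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over Gaussian-weighted sliding windows, with the standard
#' luminance/contrast/structure form and stabilizers `c1`, `c2` on data
#' range 1.  Border windows are renormalized rather than cropped, so every
#' pixel contributes.
#'
#' @param x,y Numeric matrices in `[0,1]` of equal size.
#' @param window Window width in pixels (odd).
#' @param sigma Gaussian window standard deviation in pixels.
#' @param c1,c2 Stabilizing constants (defaults `(0.01)^2` and `(0.03)^2`).
#' @return SSIM in `[-1, 1]`; exactly 1 iff `x == y`.
#' @export
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' ssim(x, x)
ssim <- function(x, y, window = 11, sigma = 1.5, c1 = 0.01^2, c2 = 0.03^2) {
  stopifnot_bscan(x); stopifnot_bscan(y)
  same_shape(x, y)
  ssim_internal(x, y, window, sigma, c1, c2)$value
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `10 * log10(1 / MSE)` on data range 1; identical images yield the `Inf`
#' sentinel.
#'
#' @param x,ref Numeric matrices in `[0,1]` of equal size.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(x, ref) {
  stopifnot_bscan(x); stopifnot_bscan(ref)
  same_shape(x, ref)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Build an ROI pair object
#'
#' @param pair_name One of the six pair names of [cnr_pairs()].
#' @param high,low Integer matrices with columns `(row, col)` giving the
#'   top-left corner of each square window.
#' @param window Window side length in pixels.
#' @return An object of class `roi_pair`.
#' @export
roi_pair <- function(pair_name, high, low, window = 4) {
  stopifnot(pair_name %in% names(cnr_pairs()))
  structure(list(pair_name = pair_name, high = high, low = low,
                 window = as.integer(window)), class = "roi_pair")
}

roi_pixels <- function(image, corners, window) {
  H <- nrow(image); W <- ncol(image)
  out <- vector("list", nrow(corners))
  for (i in seq_len(nrow(corners))) {
    r0 <- corners[i, 1]; c0 <- corners[i, 2]
    if (r0 < 1 || c0 < 1 || r0 + window - 1 > H || c0 + window - 1 > W) {
      stop("ROI window outside image bounds", call. = FALSE)
    }
    out[[i]] <- image[r0:(r0 + window - 1), c0:(c0 + window - 1)]
  }
  unlist(out)
}

#' Contrast-to-noise ratio over paired ROIs
#'
#' Computes `CNR = (h - l) / sqrt(var_h + var_l)` where `h`, `l` are the mean
#' intensities over all pixels of the high- and low-reflection ROI windows
#' and `var_h`, `var_l` their (population) variances.  The statistic is
#' invariant to positive affine intensity maps `a * I + b` of the whole
#' image.
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param pair An `roi_pair` (e.g. from [auto_rois()]).
#' @return An object of class `cnr_result` with fields `h`, `l`, `var_h`,
#'   `var_l`, `cnr` and `pair_name`.
#' @export
cnr <- function(image, pair) {
  stopifnot_bscan(image)
  stopifnot(inherits(pair, "roi_pair"))
  hp <- roi_pixels(image, pair$high, pair$window)
  lp <- roi_pixels(image, pair$low, pair$window)
  h <- mean(hp); l <- mean(lp)
  var_h <- mean((hp - h)^2); var_l <- mean((lp - l)^2)
  if (var_h + var_l == 0) {
    stop(sprintf("degenerate ROIs for pair '%s': both variances are zero",
                 pair$pair_name), call. = FALSE)
  }
  structure(list(pair_name = pair$pair_name, h = h, l = l,
                 var_h = var_h, var_l = var_l,
                 cnr = (h - l) / sqrt(var_h + var_l)),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr %s: h=%.3f l=%.3f cnr=%.3f>\n", x$pair_name, x$h, x$l, x$cnr))
  invisible(x)
}

#' Place paired ROIs automatically from a label map
#'
#' Places `n_pairs` label-pure square windows per layer at approximately
#' equal horizontal intervals — an automated stand-in for manual ROI marking,
#' possible on phantoms because the true layer geometry is known.  Windows
#' are centered vertically in the layer band at each column.
#'
#' @param layer_map Integer label matrix with a `layers` attribute (from
#'   [make_phantom()]).
#' @param pair_name One of the six pair names of [cnr_pairs()].
#' @param n_pairs Number of window pairs.
#' @param window Window side length in pixels.
#' @param seed Integer seed (vertical jitter within the feasible band).
#' @return An `roi_pair`.
#' @export
auto_rois <- function(layer_map, pair_name, n_pairs = 50, window = 4, seed = 1) {
  stopifnot(pair_name %in% names(cnr_pairs()))
  layers <- attr(layer_map, "layers")
  if (is.null(layers)) layers <- oct_layers()
  pr <- cnr_pairs()[[pair_name]]
  place <- function(layer_name) {
    id <- match(layer_name, layers)
    W <- ncol(layer_map); H <- nrow(layer_map)
    if (!any(layer_map == id)) {
      stop(sprintf("layer '%s' absent from the label map", layer_name),
           call. = FALSE)
    }
    # per column: the longest contiguous run of the layer (background shows
    # up both above and below the tissue band, so runs must be respected)
    top <- rep(NA_integer_, W); bot <- rep(NA_integer_, W)
    for (cix in seq_len(W)) {
      r <- rle(layer_map[, cix] == id)
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values)
      best <- hit[which.max(r$lengths[hit])]
      top[cix] <- starts[best]; bot[cix] <- ends[best]
    }
    # feasibility of a window whose columns are cix..cix+window-1
    feas_top <- rep(NA_integer_, W - window + 1)
    feas_bot <- rep(NA_integer_, W - window + 1)
    for (cix in seq_len(W - window + 1)) {
      cols <- cix:(cix + window - 1)
      if (anyNA(top[cols])) next
      t0 <- max(top[cols]); b0 <- min(bot[cols])
      if (b0 - t0 + 1 >= window) { feas_top[cix] <- t0; feas_bot[cix] <- b0 }
    }
    ok <- which(!is.na(feas_top))
    if (length(ok) < n_pairs) {
      stop(sprintf(paste0("layer '%s' too thin for %d windows of %d px; ",
                          "use a larger phantom"),
                   layer_name, n_pairs, window), call. = FALSE)
    }
    targets <- if (n_pairs == 1) ok[1] else
      round(seq(ok[1], ok[length(ok)], length.out = n_pairs))
    corners <- matrix(0L, n_pairs, 2)
    for (i in seq_len(n_pairs)) {
      cix <- ok[which.min(abs(ok - targets[i]))]
      t0 <- feas_top[cix]; b0 <- feas_bot[cix]
      slack <- (b0 - t0 + 1) - window
      jit <- if (slack > 0) sample.int(slack + 1, 1) - 1 else 0
      r0 <- t0 + max(0, floor(slack / 2))
      if (slack > 0) r0 <- t0 + jit
      corners[i, ] <- c(r0, cix)
    }
    corners
  }
  with_seed(seed, {
    hi <- place(pr[1])
    lo <- place(pr[2])
    roi_pair(pair_name, hi, lo, window = window)
  })
}

#' CNR over all six layer pairs
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param layer_map Label map from [make_phantom()].
#' @param n_pairs,window,seed Passed to [auto_rois()].
#' @return Named numeric vector of CNR values, one per pair.
#' @export
cnr_all_pairs <- function(image, layer_map, n_pairs = 50, window = 4, seed = 1) {
  vapply(names(cnr_pairs()), function(pn) {
    cnr(image, auto_rois(layer_map, pn, n_pairs, window, seed))$cnr
  }, numeric(1))
}

#' Weighted Cohen's kappa for two ordinal raters
#'
#' Chance-corrected agreement `1 - sum(w * O) / sum(w * E)` over the
#' contingency table `O` of two score vectors, with linear
#' (`|i - j|`) or quadratic (`(i - j)^2`) disagreement weights and the
#' independence table `E` from the marginals.
#'
#' @param scores_a,scores_b Integer vectors of ordinal scores.
#' @param weighting `"quadratic"` (default) or `"linear"`.
#' @param levels Ordinal category levels (default `1:5`, the 5-point quality
#'   scale).
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' weighted_kappa(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
weighted_kappa <- function(scores_a, scores_b,
                           weighting = c("quadratic", "linear"),
                           levels = 1:5) {
  weighting <- match.arg(weighting)
  if (!length(scores_a)) stop("empty score vectors", call. = FALSE)
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  if (!all(scores_a %in% levels) || !all(scores_b %in% levels)) {
    stop("scores outside the declared ordinal range", call. = FALSE)
  }
  k <- length(levels)
  O <- table(factor(scores_a, levels = levels),
             factor(scores_b, levels = levels))
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(k)
  Wm <- if (weighting == "linear") abs(outer(idx, idx, `-`)) else
    outer(idx, idx, `-`)^2
  denom <- sum(Wm * E)
  if (denom == 0) {
    stop("expected disagreement is zero (all scores in one category); kappa undefined",
         call. = FALSE)
  }
  1 - sum(Wm * O) / denom
}

#' Panel summary of weighted kappa over more than two raters
#'
#' Averages the pairwise weighted kappas over all rater pairs, for both
#' weighting schemes.
#'
#' @param scores Matrix of ordinal scores, rows = items, columns = raters.
#' @param levels Ordinal category levels.
#' @return A list with `pairwise` (data frame of rater pairs and kappas) and
#'   `mean_kappa` (named vector, one entry per weighting scheme).
#' @export
weighted_kappa_panel <- function(scores, levels = 1:5) {
  stopifnot(is.matrix(scores), ncol(scores) >= 2)
  prs <- utils::combn(ncol(scores), 2)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    data.frame(rater_a = a, rater_b = b,
               kappa_quadratic = weighted_kappa(scores[, a], scores[, b],
                                                "quadratic", levels),
               kappa_linear = weighted_kappa(scores[, a], scores[, b],
                                             "linear", levels))
  })
  pairwise <- do.call(rbind, rows)
  list(pairwise = pairwise,
       mean_kappa = c(quadratic = mean(pairwise$kappa_quadratic),
                      linear = mean(pairwise$kappa_linear)))
}

#' Full metrics report for one enhanced image
#'
#' @param image Enhanced B-scan.
#' @param reference Gold-standard B-scan.
#' @param layer_map Optional label map for CNR.
#' @param n_pairs,roi_seed Passed to [auto_rois()].
#' @return A list with `ssim`, `psnr` and (when a label map is given)
#'   `cnr_by_pair`.
#' @export
metrics_report <- function(image, reference, layer_map = NULL,
                           n_pairs = 50, roi_seed = 1) {
  out <- list(ssim = ssim(image, reference), psnr = psnr(image, reference))
  if (!is.null(layer_map)) {
    out$cnr_by_pair <- cnr_all_pairs(image, layer_map, n_pairs = n_pairs,
                                     seed = roi_seed)
  }
  out
}
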