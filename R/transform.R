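# Rigid in-plane transforms and bilinear warping of B-scans.
#
# Convention: a transform t = (dx, dy, theta) maps a source pixel to
# destination coordinates by rotating by theta (degrees, counter-clockwise in
# (x = column, y = row) coordinates) about the image center and then
# translating by (dx, dy) pixels.  Warping resamples by inverse mapping with
# bilinear interpolation.

#' Create a rigid transform
#'
#' @param dx,dy Translation in pixels (columns, rows).
#' @param theta Rotation in degrees about the image center.
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' rigid_transform(2, -1, 0.5)
rigid_transform <- function(dx = 0, dy = 0, theta = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(theta))
  structure(list(dx = dx, dy = dy, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform dx=%.3f px, dy=%.3f px, theta=%.3f deg>\n",
              x$dx, x$dy, x$theta))
  invisible(x)
}

is_identity_transform <- function(t, tol = 0) {
  abs(t$dx) <= tol && abs(t$dy) <= tol && abs(t$theta) <= tol
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Compose two rigid transforms
#'
#' `rigid_compose(b, a)` is the transform that applies `a` first, then `b`.
#'
#' @param b,a Objects of class `rigid_transform`.
#' @return A `rigid_transform`.
#' @export
rigid_compose <- function(b, a) {
  R <- rot2(b$theta)
  t <- R %*% c(a$dx, a$dy) + c(b$dx, b$dy)
  rigid_transform(t[1], t[2], a$theta + b$theta)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rigid_invert <- function(t) {
  R <- rot2(-t$theta)
  ti <- -(R %*% c(t$dx, t$dy))
  rigid_transform(ti[1], ti[2], -t$theta)
}

# Inverse-map output pixel grid through t and sample img bilinearly.
# Returns list(img = warped matrix, valid = logical matrix of in-bounds
# samples).  Out-of-bounds samples are filled with `fill`.
warp_rigid <- function(img, t, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  if (is_identity_transform(t)) {
    return(list(img = img, valid = matrix(TRUE, H, W)))
  }
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  Ri <- rot2(-t$theta)
  xp <- rep(seq_len(W), each = H) - cx - t$dx
  yp <- rep(seq_len(H), times = W) - cy - t$dy
  xs <- Ri[1, 1] * xp + Ri[1, 2] * yp + cx
  ys <- Ri[2, 1] * xp + Ri[2, 2] * yp + cy

  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0;  fy <- ys - y0
  valid <- x0 >= 1 & x0 <= W - 1 & y0 >= 1 & y0 <= H - 1
  # exact grid hits on the last row/column are still valid
  hit_x <- x0 == W & fx == 0; hit_y <- y0 == H & fy == 0
  valid <- valid | (hit_x & y0 >= 1 & (y0 <= H - 1 | hit_y)) |
    (hit_y & x0 >= 1 & (x0 <= W - 1 | hit_x))
  x0c <- pmin(pmax(x0, 1), W - 1); y0c <- pmin(pmax(y0, 1), H - 1)

  i00 <- y0c + (x0c - 1) * H
  v <- (1 - fx) * ((1 - fy) * img[i00] + fy * img[i00 + 1]) +
    fx * ((1 - fy) * img[i00 + H] + fy * img[i00 + H + 1])
  v[!valid] <- fill
  list(img = matrix(v, H, W), valid = matrix(valid, H, W))
}

#' Warp a B-scan by a rigid transform
#'
#' Resamples `img` under the transform `t` (bilinear interpolation, inverse
#' mapping).  Pixels that map outside the source are filled with `fill`.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param t A `rigid_transform`.
#' @param fill Fill value for out-of-bounds pixels (default: background
#'   reflectivity of the default phantom).
#' @return A numeric matrix of the same size.
#' @export
warp_bscan <- function(img, t, fill = 0.10) {
  stopifnot_bscan(img)
  warp_rigid(img, t, fill = fill)$img
}
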