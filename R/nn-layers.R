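# Convolutional layer primitives for the enhancement network.
#
# Feature maps are stored as (H*W) x C matrices in column-major pixel order
# (pixel index p = (col-1)*H + row).  3x3 convolutions are evaluated as a
# single GEMM against an im2col matrix built from nine precomputed spatial
# shifts; backward passes reuse the same index sets.  All index sets are
# cached per image geometry.

.geom_cache <- new.env(parent = emptyenv())

# Index sets for an H x W grid: `conv` maps each output pixel to its nine
# 3x3 neighbors (zero-padded via a sentinel row HW+1), `pool` maps each
# pooled pixel to its 2x2 children, `up` maps each fine pixel to its parent.
nn_geometry <- function(H, W) {
  key <- paste(H, W, sep = "x")
  got <- .geom_cache[[key]]
  if (!is.null(got)) return(got)
  HW <- H * W
  rows <- rep(seq_len(H), times = W)
  cols <- rep(seq_len(W), each = H)
  conv <- vector("list", 9)
  o <- 1L
  for (dc in -1:1) for (dr in -1:1) {
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    idx <- rep.int(HW + 1L, HW)
    idx[ok] <- r2[ok] + (c2[ok] - 1L) * H
    conv[[o]] <- idx
    o <- o + 1L
  }
  geom <- list(H = H, W = W, HW = HW, conv = conv,
               conv_all = unlist(conv, use.names = FALSE))
  if (H %% 2 == 0 && W %% 2 == 0) {
    h2 <- H %/% 2L; w2 <- W %/% 2L
    pr <- rep(seq_len(h2), times = w2)
    pc <- rep(seq_len(w2), each = h2)
    base_r <- 2L * pr - 1L; base_c <- 2L * pc - 1L
    child <- function(dr, dc) (base_r + dr) + (base_c + dc - 1L) * H
    geom$pool <- list(child(0L, 0L), child(1L, 0L), child(0L, 1L), child(1L, 1L))
    # parent index for each fine pixel (nearest-neighbor upsampling source)
    par_r <- (rows + 1L) %/% 2L
    par_c <- (cols + 1L) %/% 2L
    geom$up <- par_r + (par_c - 1L) * h2
  }
  .geom_cache[[key]] <- geom
  geom
}

# im2col: (HW x C) -> (HW x 9C), column blocks ordered by offset (channel
# fastest within each block).  One gather through the sentinel-padded matrix
# followed by an axis permutation.
im2col3 <- function(X, geom) {
  C <- ncol(X)
  Xa <- rbind(X, 0)  # sentinel zero row
  A <- Xa[geom$conv_all, , drop = FALSE]   # (9*HW) x C, offset-major rows
  dim(A) <- c(geom$HW, 9L, C)
  A <- aperm(A, c(1L, 3L, 2L))             # (HW, C, offset)
  dim(A) <- c(geom$HW, 9L * C)
  A
}

# Reorder a (9*Cin x Cout) kernel into the (9*Cout x Cin) kernel of the
# adjoint convolution (offsets negated, channels transposed): zero-padded
# conv backward is itself a 3x3 conv of dY with this flipped kernel.
flip_kernel <- function(Wt) {
  Cout <- ncol(Wt); Cin <- nrow(Wt) %/% 9L
  A <- Wt
  dim(A) <- c(Cin, 9L, Cout)
  A <- aperm(A[, 9:1, , drop = FALSE], c(3L, 2L, 1L))  # (Cout, offset, Cin)
  dim(A) <- c(9L * Cout, Cin)
  A
}

conv3_fwd <- function(X, Wt, b, geom) {
  Xcol <- im2col3(X, geom)
  Y <- Xcol %*% Wt
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, Xcol = Xcol)
}

conv3_bwd <- function(dY, Xcol, Wt, geom, need_dX = TRUE) {
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dX) {
    dX <- im2col3(dY, geom) %*% flip_kernel(Wt)
  }
  list(dW = dW, db = db, dX = dX)
}

relu_fwd <- function(Y) Y * (Y > 0)
relu_bwd <- function(dA, Y) dA * (Y > 0)

pool2_fwd <- function(X, geom) {
  p <- geom$pool
  (X[p[[1]], , drop = FALSE] + X[p[[2]], , drop = FALSE] +
     X[p[[3]], , drop = FALSE] + X[p[[4]], , drop = FALSE]) / 4
}

pool2_bwd <- function(dY, geom) {
  p <- geom$pool
  out <- matrix(0, geom$HW, ncol(dY))
  q <- dY / 4
  out[p[[1]], ] <- q; out[p[[2]], ] <- q
  out[p[[3]], ] <- q; out[p[[4]], ] <- q
  out
}

up2_fwd <- function(X, geom_fine) X[geom_fine$up, , drop = FALSE]

up2_bwd <- function(dY, geom_fine) {
  p <- geom_fine$pool
  dY[p[[1]], , drop = FALSE] + dY[p[[2]], , drop = FALSE] +
    dY[p[[3]], , drop = FALSE] + dY[p[[4]], , drop = FALSE]
}

sigmoid <- function(z) 1 / (1 + exp(-z))
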