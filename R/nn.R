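# Multi-frame enhancement network: a compact U-net-style encoder/decoder
# with a high-resolution representation stage (parallel multi-resolution
# branches with repeated cross-resolution fusion), a side path concatenating
# decoder features across resolutions, and a residual weighted-sum output
# y = w * mean(frames) + (1 - w) * decoded.  Implemented directly on BLAS
# matrix products (see nn-layers.R) with hand-derived backpropagation, Adam
# optimization and Xavier initialization.

#' Network configuration
#'
#' @param n_input_frames Number of input frames (channels), in `[1, 20]`.
#' @param base_channels Channel width of the first encoder block (>= 4).
#' @param n_hr_branches Parallel resolution branches in the high-resolution
#'   stage (1 or 2).
#' @param n_hr_fusions Cross-resolution fusion steps (>= 1).
#' @param weighted_sum_mode `"learnable-scalar"` (residual weight
#'   `w = sigmoid(a)` learned, initialized at 0.5) or `"fixed"`.
#' @param w_fixed Residual weight used when `weighted_sum_mode = "fixed"`.
#' @param seed Seed for Xavier weight initialization.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_input_frames = 5, base_channels = 8,
                       n_hr_branches = 2, n_hr_fusions = 2,
                       weighted_sum_mode = c("learnable-scalar", "fixed"),
                       w_fixed = 0.5, seed = 1) {
  weighted_sum_mode <- match.arg(weighted_sum_mode)
  if (n_input_frames < 1 || n_input_frames > 20) {
    stop("n_input_frames must lie in [1, 20]", call. = FALSE)
  }
  if (base_channels < 4) stop("base_channels must be >= 4", call. = FALSE)
  if (!n_hr_branches %in% c(1, 2)) {
    stop("n_hr_branches must be 1 or 2", call. = FALSE)
  }
  if (n_hr_fusions < 1) stop("n_hr_fusions must be >= 1", call. = FALSE)
  structure(list(n_input_frames = as.integer(n_input_frames),
                 base_channels = as.integer(base_channels),
                 n_hr_branches = as.integer(n_hr_branches),
                 n_hr_fusions = as.integer(n_hr_fusions),
                 weighted_sum_mode = weighted_sum_mode,
                 w_fixed = w_fixed, seed = as.integer(seed)),
            class = "net_config")
}

#' Training configuration
#'
#' @param lr_init Initial Adam learning rate (default 0.001).
#' @param decay_factor Multiplicative learning-rate decay (default 0.9),
#'   applied when the monitored training loss fails to decrease for
#'   `patience_epochs` epochs.
#' @param patience_epochs Plateau patience in epochs (default 10).
#' @param loss_weights Length-2 vector `c(w_ce, w_ssim)` mixing binary
#'   cross-entropy and `1 - SSIM` (default `c(1, 1)`).
#' @param batch_size Minibatch size (gradients averaged over the batch).
#' @param max_epochs Maximum training epochs.
#' @param augmentation_draws Random frame-subsets drawn per stack (offline
#'   augmentation).
#' @param seed Seed controlling augmentation draws and sample order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr_init = 0.001, decay_factor = 0.9,
                         patience_epochs = 10, loss_weights = c(1, 1),
                         batch_size = 2, max_epochs = 30,
                         augmentation_draws = 2, seed = 1) {
  if (decay_factor <= 0 || decay_factor >= 1) {
    stop("decay_factor must lie in (0, 1)", call. = FALSE)
  }
  if (any(loss_weights < 0) || all(loss_weights == 0)) {
    stop("loss weights must be non-negative and not both zero", call. = FALSE)
  }
  structure(list(lr_init = lr_init, decay_factor = decay_factor,
                 patience_epochs = as.integer(patience_epochs),
                 loss_weights = loss_weights,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 augmentation_draws = as.integer(augmentation_draws),
                 seed = as.integer(seed)),
            class = "train_config")
}

xavier <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}

#' Build an (untrained) enhancement network
#'
#' Constructs the parameter set: two contracting encoder blocks, the
#' high-resolution representation stage, two expanding decoder blocks, the
#' side-path projection head, and the residual mixing scalar.  Weights are
#' initialized by the Xavier scheme under `config$seed`; biases start at 0
#' and the residual weight at 0.5.
#'
#' @param config A [net_config()].
#' @return An object of class `oct_model`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "net_config"))
  k <- config$n_input_frames; C <- config$base_channels
  C2 <- 2L * C; nf <- config$n_hr_fusions
  with_seed(config$seed, {
    p <- list()
    p[["enc1a.W"]] <- xavier(9 * k, C);   p[["enc1a.b"]] <- numeric(C)
    p[["enc1b.W"]] <- xavier(9 * C, C);   p[["enc1b.b"]] <- numeric(C)
    p[["enc2.W"]]  <- xavier(9 * C, C2);  p[["enc2.b"]]  <- numeric(C2)
    if (config$n_hr_branches == 2) {
      p[["hrinit.W"]] <- xavier(9 * C2, C2); p[["hrinit.b"]] <- numeric(C2)
    }
    for (i in seq_len(nf)) {
      p[[sprintf("fus%d.A.W", i)]] <- xavier(9 * C2, C2)
      p[[sprintf("fus%d.A.b", i)]] <- numeric(C2)
      if (config$n_hr_branches == 2) {
        p[[sprintf("fus%d.AB.W", i)]] <- xavier(9 * C2, C2)
        p[[sprintf("fus%d.AB.b", i)]] <- numeric(C2)
        if (i < nf) {  # the final fusion only feeds the high-res branch
          p[[sprintf("fus%d.B.W", i)]] <- xavier(9 * C2, C2)
          p[[sprintf("fus%d.B.b", i)]] <- numeric(C2)
          p[[sprintf("fus%d.BA.W", i)]] <- xavier(9 * C2, C2)
          p[[sprintf("fus%d.BA.b", i)]] <- numeric(C2)
        }
      }
    }
    p[["dec1.W"]] <- xavier(9 * C2, C); p[["dec1.b"]] <- numeric(C)
    p[["dec2.W"]] <- xavier(9 * C, C);  p[["dec2.b"]] <- numeric(C)
    p[["final.W"]] <- xavier(9 * C2, 1); p[["final.b"]] <- numeric(1)
    if (config$weighted_sum_mode == "learnable-scalar") {
      p[["mix.a"]] <- 0  # sigmoid(0) = 0.5
    }
    structure(list(config = config, params = p, training_history = NULL),
              class = "oct_model")
  })
}

#' @export
print.oct_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<oct_model k=%d, C=%d, %d HR fusion(s), %s params, %s>\n",
              x$config$n_input_frames, x$config$base_channels,
              x$config$n_hr_fusions, format(np, big.mark = ","),
              if (is.null(x$training_history)) "untrained" else
                sprintf("trained %d epochs", nrow(x$training_history))))
  invisible(x)
}

residual_weight <- function(model) {
  if (model$config$weighted_sum_mode == "fixed") model$config$w_fixed
  else sigmoid(model$params[["mix.a"]])
}

net_geoms <- function(H, W, branches) {
  div <- if (branches == 2) 8L else 4L
  if (H %% div != 0 || W %% div != 0) {
    stop(sprintf("image height and width must be multiples of %d", div),
         call. = FALSE)
  }
  list(g1 = nn_geometry(H, W), g2 = nn_geometry(H %/% 2L, W %/% 2L),
       g4 = nn_geometry(H %/% 4L, W %/% 4L),
       g8 = if (branches == 2) nn_geometry(H %/% 8L, W %/% 8L) else NULL)
}

# Forward pass.  Xin: (HW x k) matrix of frames; returns the output vector y
# and (optionally) every intermediate needed by net_backward.
net_forward <- function(model, Xin, H, W, keep = FALSE) {
  p <- model$params; cfg <- model$config
  C <- cfg$base_channels; nf <- cfg$n_hr_fusions
  two <- cfg$n_hr_branches == 2
  g <- net_geoms(H, W, cfg$n_hr_branches)
  m <- rowMeans(Xin)

  c1a <- conv3_fwd(Xin, p[["enc1a.W"]], p[["enc1a.b"]], g$g1)
  A1 <- relu_fwd(c1a$Y)
  c1b <- conv3_fwd(A1, p[["enc1b.W"]], p[["enc1b.b"]], g$g1)
  A2 <- relu_fwd(c1b$Y)
  P1 <- pool2_fwd(A2, g$g1)
  c2 <- conv3_fwd(P1, p[["enc2.W"]], p[["enc2.b"]], g$g2)
  A3 <- relu_fwd(c2$Y)
  A <- pool2_fwd(A3, g$g2)

  B <- NULL; cB <- NULL
  if (two) {
    PB <- pool2_fwd(A, g$g4)
    cB <- conv3_fwd(PB, p[["hrinit.W"]], p[["hrinit.b"]], g$g8)
    B <- relu_fwd(cB$Y)
  }
  fus <- vector("list", nf)
  for (i in seq_len(nf)) {
    st <- list()
    ca <- conv3_fwd(A, p[[sprintf("fus%d.A.W", i)]],
                    p[[sprintf("fus%d.A.b", i)]], g$g4)
    sA <- ca$Y
    if (two) {
      cab <- conv3_fwd(B, p[[sprintf("fus%d.AB.W", i)]],
                       p[[sprintf("fus%d.AB.b", i)]], g$g8)
      sA <- sA + up2_fwd(cab$Y, g$g4)
      st$cab <- cab
    }
    Anew <- relu_fwd(sA)
    st$ca <- ca; st$sA <- sA
    if (two && i < nf) {
      cb <- conv3_fwd(B, p[[sprintf("fus%d.B.W", i)]],
                      p[[sprintf("fus%d.B.b", i)]], g$g8)
      PA <- pool2_fwd(A, g$g4)
      cba <- conv3_fwd(PA, p[[sprintf("fus%d.BA.W", i)]],
                       p[[sprintf("fus%d.BA.b", i)]], g$g8)
      sB <- cb$Y + cba$Y
      Bnew <- relu_fwd(sB)
      st$cb <- cb; st$cba <- cba; st$sB <- sB
      B <- Bnew
    }
    st$A_in <- A
    fus[[i]] <- st
    A <- Anew
  }

  U1 <- up2_fwd(A, g$g2)
  d1 <- conv3_fwd(U1, p[["dec1.W"]], p[["dec1.b"]], g$g2)
  D1 <- relu_fwd(d1$Y)
  U2 <- up2_fwd(D1, g$g1)
  d2 <- conv3_fwd(U2, p[["dec2.W"]], p[["dec2.b"]], g$g1)
  D2 <- relu_fwd(d2$Y)
  side <- up2_fwd(D1, g$g1)
  S <- cbind(D2, side)
  fc <- conv3_fwd(S, p[["final.W"]], p[["final.b"]], g$g1)
  r <- sigmoid(as.vector(fc$Y))
  w <- residual_weight(model)
  y <- w * m + (1 - w) * r
  out <- list(y = y, r = r, m = m, w = w)
  if (keep) {
    out$cache <- list(g = g, c1a = c1a, A1 = A1, c1b = c1b, A2 = A2,
                      c2 = c2, A3 = A3, cB = cB, B = B, fus = fus,
                      d1 = d1, D1 = D1, d2 = d2, D2 = D2, fc = fc)
  }
  out
}

# Backward pass: gradient of the scalar loss with respect to every parameter
# given dL/dy.  Mirrors net_forward exactly.
net_backward <- function(model, fwd, dy) {
  p <- model$params; cfg <- model$config
  C <- cfg$base_channels; nf <- cfg$n_hr_fusions
  two <- cfg$n_hr_branches == 2
  ch <- fwd$cache; g <- ch$g
  gr <- list()

  w <- fwd$w; r <- fwd$r
  if (cfg$weighted_sum_mode == "learnable-scalar") {
    gr[["mix.a"]] <- sum(dy * (fwd$m - r)) * w * (1 - w)
  }
  dZ <- matrix(dy * (1 - w) * r * (1 - r), ncol = 1)

  bw <- conv3_bwd(dZ, ch$fc$Xcol, p[["final.W"]], g$g1)
  gr[["final.W"]] <- bw$dW; gr[["final.b"]] <- bw$db
  dD2 <- bw$dX[, seq_len(C), drop = FALSE]
  dside <- bw$dX[, C + seq_len(C), drop = FALSE]

  dD1 <- up2_bwd(dside, g$g1)
  dpre <- relu_bwd(dD2, ch$d2$Y)
  bw <- conv3_bwd(dpre, ch$d2$Xcol, p[["dec2.W"]], g$g1)
  gr[["dec2.W"]] <- bw$dW; gr[["dec2.b"]] <- bw$db
  dD1 <- dD1 + up2_bwd(bw$dX, g$g1)

  dpre <- relu_bwd(dD1, ch$d1$Y)
  bw <- conv3_bwd(dpre, ch$d1$Xcol, p[["dec1.W"]], g$g2)
  gr[["dec1.W"]] <- bw$dW; gr[["dec1.b"]] <- bw$db
  dA <- up2_bwd(bw$dX, g$g2)

  dB <- NULL
  for (i in rev(seq_len(nf))) {
    st <- ch$fus[[i]]
    dsA <- relu_bwd(dA, st$sA)
    bw <- conv3_bwd(dsA, st$ca$Xcol, p[[sprintf("fus%d.A.W", i)]], g$g4)
    gr[[sprintf("fus%d.A.W", i)]] <- bw$dW
    gr[[sprintf("fus%d.A.b", i)]] <- bw$db
    dA_new <- bw$dX
    dB_new <- NULL
    if (two) {
      dup <- up2_bwd(dsA, g$g4)
      bw <- conv3_bwd(dup, st$cab$Xcol, p[[sprintf("fus%d.AB.W", i)]], g$g8)
      gr[[sprintf("fus%d.AB.W", i)]] <- bw$dW
      gr[[sprintf("fus%d.AB.b", i)]] <- bw$db
      dB_new <- bw$dX
    }
    if (two && i < nf && !is.null(dB)) {
      dsB <- relu_bwd(dB, st$sB)
      bw <- conv3_bwd(dsB, st$cb$Xcol, p[[sprintf("fus%d.B.W", i)]], g$g8)
      gr[[sprintf("fus%d.B.W", i)]] <- bw$dW
      gr[[sprintf("fus%d.B.b", i)]] <- bw$db
      dB_new <- dB_new + bw$dX
      bw <- conv3_bwd(dsB, st$cba$Xcol, p[[sprintf("fus%d.BA.W", i)]], g$g8)
      gr[[sprintf("fus%d.BA.W", i)]] <- bw$dW
      gr[[sprintf("fus%d.BA.b", i)]] <- bw$db
      dA_new <- dA_new + pool2_bwd(bw$dX, g$g4)
    }
    dA <- dA_new; dB <- dB_new
  }
  if (two && !is.null(dB)) {
    dpre <- relu_bwd(dB, ch$cB$Y)
    bw <- conv3_bwd(dpre, ch$cB$Xcol, p[["hrinit.W"]], g$g8)
    gr[["hrinit.W"]] <- bw$dW; gr[["hrinit.b"]] <- bw$db
    dA <- dA + pool2_bwd(bw$dX, g$g4)
  }

  dA3 <- pool2_bwd(dA, g$g2)
  dpre <- relu_bwd(dA3, ch$c2$Y)
  bw <- conv3_bwd(dpre, ch$c2$Xcol, p[["enc2.W"]], g$g2)
  gr[["enc2.W"]] <- bw$dW; gr[["enc2.b"]] <- bw$db
  dA2 <- pool2_bwd(bw$dX, g$g1)
  dpre <- relu_bwd(dA2, ch$c1b$Y)
  bw <- conv3_bwd(dpre, ch$c1b$Xcol, p[["enc1b.W"]], g$g1)
  gr[["enc1b.W"]] <- bw$dW; gr[["enc1b.b"]] <- bw$db
  dA1 <- bw$dX
  dpre <- relu_bwd(dA1, ch$c1a$Y)
  bw <- conv3_bwd(dpre, ch$c1a$Xcol, p[["enc1a.W"]], g$g1, need_dX = FALSE)
  gr[["enc1a.W"]] <- bw$dW; gr[["enc1a.b"]] <- bw$db
  gr
}

bce_loss <- function(prediction, target, eps = 1e-7) {
  p <- pmin(pmax(prediction, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_grad <- function(prediction, target, eps = 1e-7) {
  p <- pmin(pmax(prediction, eps), 1 - eps)
  (p - target) / (p * (1 - p)) / length(p)
}

#' Combined cross-entropy + SSIM training loss
#'
#' `w_ce * BCE(prediction, target) + w_ssim * (1 - SSIM(prediction,
#' target))`, with pixel-wise binary cross-entropy over `[0, 1]` intensities
#' and the same SSIM as [ssim()].  Reduces exactly to BCE at weights
#' `(1, 0)` and to `1 - SSIM` at `(0, 1)`.
#'
#' @param prediction,target Numeric matrices in `[0, 1]` of equal size.
#' @param weights Length-2 vector `c(w_ce, w_ssim)`.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' x <- matrix(0.5, 16, 16)
#' combined_loss(x, x, c(1, 0))  # the BCE entropy floor log(2)
combined_loss <- function(prediction, target, weights = c(1, 1)) {
  stopifnot_bscan(prediction); stopifnot_bscan(target)
  same_shape(prediction, target)
  if (min(prediction) < 0 || max(prediction) > 1 ||
      min(target) < 0 || max(target) > 1) {
    stop("prediction and target must lie in [0, 1]", call. = FALSE)
  }
  loss <- 0
  if (weights[1] > 0) loss <- loss + weights[1] * bce_loss(prediction, target)
  if (weights[2] > 0) loss <- loss + weights[2] * (1 - ssim(prediction, target))
  loss
}

# Loss + gradient wrt prediction (matrices H x W).
combined_loss_grad <- function(prediction, target, weights) {
  loss <- 0; grad <- matrix(0, nrow(prediction), ncol(prediction))
  if (weights[1] > 0) {
    loss <- loss + weights[1] * bce_loss(prediction, target)
    grad <- grad + weights[1] * bce_grad(prediction, target)
  }
  if (weights[2] > 0) {
    s <- ssim_internal(prediction, target, 11, 1.5, 0.01^2, 0.03^2, grad = TRUE)
    loss <- loss + weights[2] * (1 - s$value)
    grad <- grad - weights[2] * s$grad
  }
  list(loss = loss, grad = grad)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gradn <- grads[[nm]]
    if (is.null(gradn)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gradn
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gradn^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

stack_input_matrix <- function(stack, idx) {
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  X <- matrix(0, H * W, length(idx))
  for (j in seq_along(idx)) X[, j] <- as.vector(stack$frames[[idx[j]]])
  X
}

surviving_frames <- function(stack) {
  setdiff(seq_along(stack$frames), stack$excluded)
}

#' Train the enhancement network
#'
#' Offline augmentation draws `augmentation_draws` random
#' `n_input_frames`-subsets from each stack's surviving frames; the model is
#' then optimized with Adam on the combined BCE + SSIM loss.  When the
#' monitored (training) loss fails to decrease for `patience_epochs` epochs
#' the learning rate is multiplied by `decay_factor`.  Deterministic given
#' the configuration seeds.
#'
#' @param model An `oct_model` from [build_network()].
#' @param dataset List of training cases, each a list with fields `stack` (a
#'   `frame_stack`, aligned) and `target` (gold-standard matrix in `[0,1]`).
#' @param tc A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return The trained `oct_model`, with `training_history` (data frame of
#'   epoch, loss, lr) attached.
#' @export
train_network <- function(model, dataset, tc = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "oct_model"), inherits(tc, "train_config"))
  if (!length(dataset)) stop("empty training dataset", call. = FALSE)
  k <- model$config$n_input_frames
  for (d in dataset) {
    if (length(surviving_frames(d$stack)) < k) {
      stop("a training stack has fewer surviving frames than n_input_frames",
           call. = FALSE)
    }
    same_shape(d$stack$frames[[1]], d$target)
  }
  H <- nrow(dataset[[1]]$target); W <- ncol(dataset[[1]]$target)

  with_seed(tc$seed, {
    samples <- list()
    for (d in dataset) {
      surv <- surviving_frames(d$stack)
      tvec <- d$target
      for (j in seq_len(tc$augmentation_draws)) {
        idx <- if (length(surv) == k) surv else sort(sample(surv, k))
        samples[[length(samples) + 1L]] <-
          list(X = stack_input_matrix(d$stack, idx), target = tvec)
      }
    }
    n <- length(samples)
    params <- model$params
    state <- adam_init(params)
    lr <- tc$lr_init
    best <- Inf; stall <- 0L
    hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))

    for (ep in seq_len(tc$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      b <- 1L
      while (b <= n) {
        bidx <- ord[b:min(n, b + tc$batch_size - 1L)]
        acc <- NULL
        for (si in bidx) {
          sm <- samples[[si]]
          model$params <- params
          fwd <- net_forward(model, sm$X, H, W, keep = TRUE)
          pred <- matrix(fwd$y, H, W)
          lg <- combined_loss_grad(pred, sm$target, tc$loss_weights)
          ep_loss <- ep_loss + lg$loss
          gr <- net_backward(model, fwd, as.vector(lg$grad))
          if (is.null(acc)) acc <- gr
          else for (nm in names(gr)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(bidx)
        upd <- adam_step(params, acc, state, lr)
        params <- upd$params; state <- upd$state
        b <- b + tc$batch_size
      }
      ep_loss <- ep_loss / n
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss, lr = lr))
      if (verbose) message(sprintf("epoch %d  loss %.5f  lr %.2e", ep, ep_loss, lr))
      if (ep_loss < best - 1e-9) {
        best <- ep_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$patience_epochs) {
          lr <- lr * tc$decay_factor
          stall <- 0L
        }
      }
    }
    model$params <- params
    model$training_history <- hist
    model
  })
}

#' Enhance a frame stack with a trained model
#'
#' Feeds the first `n_input_frames` surviving frames (acquisition order) to
#' the network and returns the enhanced B-scan.
#'
#' @param model An `oct_model`.
#' @param stack An aligned `frame_stack` with at least `n_input_frames`
#'   surviving frames.
#' @return Enhanced B-scan matrix in `[0,1]`.
#' @export
enhance <- function(model, stack) {
  stopifnot(inherits(model, "oct_model"), inherits(stack, "frame_stack"))
  k <- model$config$n_input_frames
  surv <- surviving_frames(stack)
  if (length(surv) < k) {
    stop(sprintf("stack has %d surviving frames; %d required",
                 length(surv), k), call. = FALSE)
  }
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  X <- stack_input_matrix(stack, surv[seq_len(k)])
  fwd <- net_forward(model, X, H, W)
  clamp01(matrix(fwd$y, H, W))
}
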