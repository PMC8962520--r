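# Experiment drivers: frame-count sweeps (SSIM/PSNR vs k for averaging and
# the network) and the paired DL-k vs Avg-k comparison on phantom replicates.

#' Default experiment configuration
#'
#' Desk-scale study conditions: 128 x 256 phantoms, training stacks of 8
#' aligned frames, 100 training phantoms, two augmentation draws per stack,
#' and the clean phantom image as the training target (a config switch
#' selects an Avg-50 target to mimic a clinical gold standard instead).
#'
#' @param height,width Phantom size in pixels.
#' @param speckle_shape,sensor_sigma Phantom noise parameters.
#' @param n_train Number of training phantoms.
#' @param train_frames Frames per training stack.
#' @param test_frames Frames per test stack.
#' @param target `"clean"` (phantom ground truth) or `"avg50"` (average of a
#'   50-frame acquisition, the clinical-style gold standard).
#' @param base_channels,n_hr_fusions Network size.
#' @param max_epochs,augmentation_draws,batch_size Training schedule.
#' @return A list of settings consumed by [run_sweep()] and
#'   [head_to_head()].
#' @export
experiment_config <- function(height = 128, width = 256, speckle_shape = 8,
                              sensor_sigma = 0.02, n_train = 100,
                              train_frames = 8, test_frames = 20,
                              target = c("clean", "avg50"),
                              base_channels = 8, n_hr_fusions = 2,
                              max_epochs = 8, augmentation_draws = 1,
                              batch_size = 2) {
  target <- match.arg(target)
  list(height = height, width = width, speckle_shape = speckle_shape,
       sensor_sigma = sensor_sigma, n_train = n_train,
       train_frames = train_frames, test_frames = test_frames,
       target = target, base_channels = base_channels,
       n_hr_fusions = n_hr_fusions, max_epochs = max_epochs,
       augmentation_draws = augmentation_draws, batch_size = batch_size)
}

# Generate one aligned phantom acquisition (training/test replicate).
phantom_case <- function(cfg, n_frames, seed) {
  truth <- make_phantom(cfg$height, cfg$width, seed = seed,
                        speckle_shape = cfg$speckle_shape,
                        sensor_sigma = cfg$sensor_sigma)
  acq <- acquire_frames(truth, n_frames, motion_scale = c(0, 0),
                        p_fixation_loss = 0, seed = child_seed(seed, 1))
  target <- if (identical(cfg$target, "avg50")) {
    gold <- acquire_frames(truth, 50, motion_scale = c(0, 0),
                           p_fixation_loss = 0, seed = child_seed(seed, 2))
    average_frames(gold$stack)
  } else {
    truth$clean
  }
  list(stack = acq$stack, truth = acq$truth, target = target)
}

#' Train an enhancement model for a given frame count
#'
#' Generates `cfg$n_train` aligned phantom stacks and trains one network for
#' frame count `k` (the architecture fixes the input channel count, so each
#' `k` gets its own model).
#'
#' @param k Frame count (network input channels).
#' @param cfg From [experiment_config()].
#' @param seed Integer seed (phantom generation, initialization, training).
#' @param verbose Print per-epoch loss.
#' @return A trained `oct_model`.
#' @export
train_for_k <- function(k, cfg = experiment_config(), seed = 1,
                        verbose = FALSE) {
  n_frames <- max(cfg$train_frames, k)
  dataset <- lapply(seq_len(cfg$n_train), function(i) {
    cs <- phantom_case(cfg, n_frames, child_seed(seed, 10000 + i))
    list(stack = cs$stack, target = cs$target)
  })
  model <- build_network(net_config(n_input_frames = k,
                                    base_channels = cfg$base_channels,
                                    n_hr_fusions = cfg$n_hr_fusions,
                                    seed = child_seed(seed, 7)))
  tc <- train_config(max_epochs = cfg$max_epochs,
                     augmentation_draws = cfg$augmentation_draws,
                     batch_size = cfg$batch_size,
                     seed = child_seed(seed, 8))
  train_network(model, dataset, tc, verbose = verbose)
}

#' Frame-count sweep
#'
#' For each method and frame count `k`, enhances `n_phantoms` held-out
#' phantom stacks and aggregates SSIM and PSNR against the clean ground
#' truth.  Deep-learning models are trained once per `k` on a disjoint
#' training split (different phantom seeds).
#'
#' @param k_values Frame counts, each in `[1, 20]`.
#' @param n_phantoms Number of test phantoms (>= 2).
#' @param methods Subset of `c("averaging", "deep-learning")`.
#' @param cfg From [experiment_config()].
#' @param seed Integer seed.
#' @param models Optional named list of pre-trained models (names =
#'   `as.character(k)`), bypassing training.
#' @param verbose Print progress.
#' @return Data frame with one row per (method, k): mean/sd SSIM and PSNR
#'   and `n_replicates`.
#' @export
run_sweep <- function(k_values, n_phantoms = 20,
                      methods = c("averaging", "deep-learning"),
                      cfg = experiment_config(), seed = 1, models = NULL,
                      verbose = FALSE) {
  stopifnot(all(k_values >= 1), all(k_values <= 20), n_phantoms >= 2)
  methods <- match.arg(methods, several.ok = TRUE)
  n_frames <- max(cfg$test_frames, max(k_values))
  cases <- lapply(seq_len(n_phantoms), function(i) {
    phantom_case(cfg, n_frames, child_seed(seed, 20000 + i))
  })
  if ("deep-learning" %in% methods && is.null(models)) {
    models <- list()
    for (k in k_values) {
      if (verbose) message(sprintf("training model for k = %d", k))
      models[[as.character(k)]] <- train_for_k(k, cfg, seed = child_seed(seed, k))
    }
  }
  rows <- list()
  for (method in methods) {
    for (k in k_values) {
      ssims <- numeric(n_phantoms); psnrs <- numeric(n_phantoms)
      for (i in seq_len(n_phantoms)) {
        cs <- cases[[i]]
        img <- if (method == "averaging") {
          average_frames(cs$stack, seq_len(k))
        } else {
          enhance(models[[as.character(k)]], cs$stack)
        }
        ssims[i] <- ssim(img, cs$truth$clean)
        psnrs[i] <- psnr(img, cs$truth$clean)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, k = k,
        mean_ssim = mean(ssims), sd_ssim = stats::sd(ssims),
        mean_psnr = mean(psnrs), sd_psnr = stats::sd(psnrs),
        n_replicates = n_phantoms)
    }
  }
  structure(do.call(rbind, rows), models = models)
}

#' Paired DL-k vs Avg-k comparison
#'
#' Enhances `n_phantoms` held-out stacks with both methods at the same frame
#' count, reports per-phantom paired SSIM/PSNR differences with a paired
#' t-test, and the six layer-pair CNR values for the single frame, Avg-k and
#' DL-k.
#'
#' @param k Frame count.
#' @param n_phantoms Number of test phantoms.
#' @param cfg From [experiment_config()].
#' @param seed Integer seed.
#' @param model Optional pre-trained `oct_model` for `k`.
#' @param outdir Optional directory; when given, writes `head_to_head.csv`
#'   (per-phantom metrics) and `head_to_head.json` (summary).
#' @param verbose Print progress.
#' @return A list of class `head_to_head` with `per_phantom` (data frame),
#'   `summary` (means, sds, paired differences, t-test p-values) and
#'   `cnr` (matrix pair x method of mean CNR).
#' @export
head_to_head <- function(k = 5, n_phantoms = 20, cfg = experiment_config(),
                         seed = 1, model = NULL, outdir = NULL,
                         verbose = FALSE) {
  if (is.null(model)) {
    if (verbose) message(sprintf("training model for k = %d", k))
    model <- train_for_k(k, cfg, seed = child_seed(seed, k))
  }
  n_frames <- max(cfg$test_frames, k)
  per <- list()
  cnr_acc <- matrix(0, length(cnr_pairs()), 3,
                    dimnames = list(names(cnr_pairs()),
                                    c("single", "avg", "dl")))
  for (i in seq_len(n_phantoms)) {
    cs <- phantom_case(cfg, n_frames, child_seed(seed, 30000 + i))
    avg <- average_frames(cs$stack, seq_len(k))
    dl <- enhance(model, cs$stack)
    single <- cs$stack$frames[[1]]
    lm <- cs$truth$layer_map
    cnr_acc[, "single"] <- cnr_acc[, "single"] + cnr_all_pairs(single, lm)
    cnr_acc[, "avg"] <- cnr_acc[, "avg"] + cnr_all_pairs(avg, lm)
    cnr_acc[, "dl"] <- cnr_acc[, "dl"] + cnr_all_pairs(dl, lm)
    per[[i]] <- data.frame(
      phantom = i,
      ssim_avg = ssim(avg, cs$truth$clean),
      ssim_dl = ssim(dl, cs$truth$clean),
      psnr_avg = psnr(avg, cs$truth$clean),
      psnr_dl = psnr(dl, cs$truth$clean))
  }
  per <- do.call(rbind, per)
  cnr_mean <- cnr_acc / n_phantoms
  d_ssim <- per$ssim_dl - per$ssim_avg
  d_psnr <- per$psnr_dl - per$psnr_avg
  tt <- function(d) {
    if (length(d) < 2 || stats::sd(d) == 0) return(NA_real_)
    stats::t.test(d)$p.value
  }
  summary <- list(
    k = k, n_phantoms = n_phantoms,
    mean_ssim_avg = mean(per$ssim_avg), sd_ssim_avg = stats::sd(per$ssim_avg),
    mean_ssim_dl = mean(per$ssim_dl), sd_ssim_dl = stats::sd(per$ssim_dl),
    mean_psnr_avg = mean(per$psnr_avg), sd_psnr_avg = stats::sd(per$psnr_avg),
    mean_psnr_dl = mean(per$psnr_dl), sd_psnr_dl = stats::sd(per$psnr_dl),
    mean_delta_ssim = mean(d_ssim), mean_delta_psnr = mean(d_psnr),
    frac_ssim_dl_wins = mean(d_ssim > 0),
    p_ssim = tt(d_ssim), p_psnr = tt(d_psnr))
  out <- structure(list(per_phantom = per, summary = summary,
                        cnr = cnr_mean, model = model),
                   class = "head_to_head")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per, file.path(outdir, "head_to_head.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary,
                              cnr = as.data.frame(cnr_mean)),
                         file.path(outdir, "head_to_head.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.head_to_head <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<head_to_head k=%d, n=%d>\n", s$k, s$n_phantoms))
  cat(sprintf("  SSIM  Avg-%d %.4f +/- %.4f | DL-%d %.4f +/- %.4f (p=%.3g)\n",
              s$k, s$mean_ssim_avg, s$sd_ssim_avg,
              s$k, s$mean_ssim_dl, s$sd_ssim_dl, s$p_ssim))
  cat(sprintf("  PSNR  Avg-%d %.2f +/- %.2f dB | DL-%d %.2f +/- %.2f dB (p=%.3g)\n",
              s$k, s$mean_psnr_avg, s$sd_psnr_avg,
              s$k, s$mean_psnr_dl, s$sd_psnr_dl, s$p_psnr))
  invisible(x)
}
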