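# Reading and writing B-scans and stack containers.

#' Write a B-scan to PNG or 16-bit TIFF
#'
#' @param img Numeric matrix in `[0,1]`.
#' @param path Output path; format chosen by extension (`.png` or
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_bscan <- function(img, path) {
  stopifnot_bscan(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(clamp01(img), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(clamp01(img), path, bits.per.sample = 16L)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a B-scan from PNG or TIFF
#'
#' Multi-channel images are converted to grayscale by channel averaging.
#'
#' @param path Image path.
#' @return Numeric matrix in `[0,1]`.
#' @export
read_bscan <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  clamp01(img)
}

#' Write a stack container
#'
#' Serializes the frame stack (plus, optionally, the phantom truth) to a
#' single array-container file, with a JSON sidecar recording all
#' parameters.
#'
#' @param stack A `frame_stack`.
#' @param path Output path (conventionally `.rds`).
#' @param truth Optional `phantom_truth`.
#' @param params Optional named list of acquisition parameters for the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL, params = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  saveRDS(list(stack = stack, truth = truth), path)
  meta <- c(list(n_frames = length(stack$frames),
                 height = nrow(stack$frames[[1]]),
                 width = ncol(stack$frames[[1]]),
                 aligned = stack$aligned,
                 reference_index = stack$reference_index,
                 fixation_loss = stack$fixation_loss),
            params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stack container
#'
#' @param path Path written by [write_stack()].
#' @return A list with `stack` and (possibly `NULL`) `truth`.
#' @export
read_stack <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$stack, "frame_stack"))
  obj
}
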