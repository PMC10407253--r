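#' Read and write image stacks and run configurations
#'
#' Thin I/O layer: one single- or multi-page grayscale TIFF per channel
#' (frame-major), and YAML run configurations whose keys mirror the
#' pipeline parameter names. Both require the suggested packages
#' \pkg{tiff} and \pkg{yaml}.
#'
#' @param path file path.
#' @return `read_stack_tiff()`: an H x W x T numeric array.
#' @export
read_stack_tiff <- function(path) {
  need_pkg("tiff")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]   # drop colour channels
    f
  })
  array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}

#' @rdname read_stack_tiff
#' @param stack H x W or H x W x T numeric array, values in `[0, 1]`.
#' @param bits_per_sample TIFF bit depth (default 16).
#' @export
write_stack_tiff <- function(stack, path, bits_per_sample = 16) {
  need_pkg("tiff")
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    pmin(pmax(stack[, , f], 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' @rdname read_stack_tiff
#' @export
read_run_config <- function(path) {
  need_pkg("yaml")
  yaml::read_yaml(path)
}

#' @rdname read_stack_tiff
#' @param config named list of parameters.
#' @export
write_run_config <- function(config, path) {
  need_pkg("yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this operation", call. = FALSE)
  }
}
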