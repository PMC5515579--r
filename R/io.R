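#' Read and write MS2 movies as multi-page TIFF
#'
#' Movies are stored one page per time point (maximum-projected frames).
#' Intensities are scaled to 16-bit on write (`counts = sample * 65535`)
#' and rescaled back on read with the `scale` argument.
#'
#' @param movie an [ms2_movie()].
#' @param path TIFF file path.
#' @param scale full-scale intensity in counts mapped to the 16-bit
#'   maximum (default 65535, i.e. counts stored verbatim).
#' @return `write_ms2_tiff` invisibly returns `path`; `read_ms2_tiff`
#'   returns an [ms2_movie()].
#' @export
write_ms2_tiff <- function(movie, path, scale = 65535) {
  stopifnot(inherits(movie, "ms2_movie"))
  d <- dim(movie$frames)
  pages <- lapply(seq_len(d[3]),
                  function(f) pmin(movie$frames[, , f] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_ms2_tiff
#' @param frame_interval,pixel_size,ap_intercept,ap_slope movie metadata
#'   (TIFF pages carry none), as for [ms2_movie()].
#' @export
read_ms2_tiff <- function(path, scale = 65535, frame_interval = 40,
                          pixel_size = 409, ap_intercept = 100,
                          ap_slope = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * scale
  if (is.null(ap_slope)) ap_slope <- -60 / dim(frames)[2]
  ms2_movie(frames, frame_interval = frame_interval, pixel_size = pixel_size,
            ap_intercept = ap_intercept, ap_slope = ap_slope)
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a `height x width x n_z` stack (or a list of such stacks per
#' time point) to one projected frame per time point, the preprocessing
#' step applied to every imaging stack before quantification.
#'
#' @param stack array `height x width x n_z`, or list of such arrays.
#' @return a matrix (single stack) or `height x width x n_time` array
#'   (list input).
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    frames <- vapply(stack, max_project,
                     matrix(0, dim(stack[[1]])[1], dim(stack[[1]])[2]))
    return(frames)
  }
  if (length(dim(stack)) == 2L) return(stack)
  apply(stack, c(1, 2), max)
}
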