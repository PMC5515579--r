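#' MS2 movie container
#'
#' A maximum-projected time-lapse movie of nascent transcription spots.
#' Frames are `height x width` intensity matrices (row = y, column = x).
#' The AP calibration maps pixel column x to %EL linearly
#' (`el = ap_intercept + ap_slope * x`); the anterior pole is at 100 %EL.
#'
#' @param frames numeric array `height x width x n_frames`, intensities
#'   >= 0.
#' @param frame_interval time between frames in seconds (imaging used 40 s
#'   or 30 s).
#' @param pixel_size pixel size in nanometres (default 409).
#' @param ap_intercept,ap_slope linear pixel-to-%EL calibration.
#' @return object of class `ms2_movie`.
#' @export
ms2_movie <- function(frames, frame_interval = 40, pixel_size = 409,
                      ap_intercept = 100, ap_slope = -60 / dim(frames)[2]) {
  frames <- as.array(frames)
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stop_invalid("frames must be height x width x time")
  if (any(frames < 0) || any(!is.finite(frames)))
    stop_invalid("frame intensities must be finite and >= 0")
  if (!is_scalar_number(frame_interval) || frame_interval <= 0)
    stop_invalid("frame_interval must be > 0 s")
  if (ap_slope == 0) stop_invalid("ap_slope must be non-zero (monotone calibration)")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 ap_intercept = ap_intercept, ap_slope = ap_slope),
            class = "ms2_movie")
}

#' @export
print.ms2_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ms2_movie> %d frames of %d x %d px, dt = %g s, pixel %g nm\n",
              d[3], d[1], d[2], x$frame_interval, x$pixel_size))
  invisible(x)
}

pixel_to_el <- function(movie, x_px) movie$ap_intercept + movie$ap_slope * x_px
el_to_pixel <- function(movie, el) (el - movie$ap_intercept) / movie$ap_slope

#' Spot detection and tracking configuration
#'
#' The four manually measured detection parameters plus the persistence
#' cutoff: the lowest intensity counted as signal, the spot size (an odd
#' `N x N` pixel matrix), the maximum displacement between consecutive
#' frames, the minimum intensity contrast between an MS2 dot and its
#' surrounding background, and the minimum track duration (160 s by
#' default, the length of one complete hb transcription event).
#'
#' @param intensity_threshold lowest intensity value (counts).
#' @param spot_size_N odd spot matrix size N (pixels).
#' @param max_displacement maximum spot displacement between consecutive
#'   frames (pixels).
#' @param contrast_threshold minimum spot-minus-surround intensity
#'   difference (counts).
#' @param min_duration persistence cutoff in seconds (default 160).
#' @param duration_convention "frames" (duration = n_spots * frame
#'   interval, the default) or "span" (`(n_spots - 1) *` interval).
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(intensity_threshold = 100, spot_size_N = 3,
                            max_displacement = 5, contrast_threshold = 50,
                            min_duration = 160,
                            duration_convention = c("frames", "span")) {
  if (!is_scalar_number(spot_size_N) || spot_size_N < 1 || spot_size_N %% 2 != 1)
    stop_invalid("spot_size_N must be an odd integer >= 1")
  for (v in c(intensity_threshold, max_displacement, contrast_threshold, min_duration))
    if (!is_scalar_number(v) || v < 0) stop_invalid("thresholds must be >= 0")
  structure(list(intensity_threshold = intensity_threshold,
                 spot_size_N = as.integer(spot_size_N),
                 max_displacement = max_displacement,
                 contrast_threshold = contrast_threshold,
                 min_duration = min_duration,
                 duration_convention = match.arg(duration_convention)),
            class = "tracking_config")
}

#' Trace the embryo mask from a projected frame
#'
#' Intensity-based stand-in for boundary tracing: pixels above a quantile
#' threshold are kept and the largest 8-connected bright region (with a
#' morphological closing by a square) becomes the mask. Synthetic fixtures
#' usually supply their mask directly instead.
#'
#' @param frame height x width intensity matrix.
#' @param quantile intensity quantile separating embryo from background.
#' @return logical height x width matrix.
#' @export
embryo_mask <- function(frame, quantile = 0.5) {
  thr <- stats::quantile(frame, quantile)
  bw <- frame >= thr
  lab <- label_components(bw)
  if (max(lab) == 0L) return(bw)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# 8-connectivity labelling of a logical matrix via flood fill with a
# preallocated stack.
label_components <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(bw)
  if (!length(idx)) return(lab)
  stack <- integer(length(idx))
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    stack[1L] <- p; top <- 1L
    while (top > 0L) {
      q <- stack[top]; top <- top - 1L
      y <- (q - 1L) %% h + 1L; x <- (q - 1L) %/% h + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1L || yy > h || xx < 1L || xx > w) next
        qq <- (xx - 1L) * h + yy
        if (bw[qq] && lab[qq] == 0L) {
          lab[qq] <- cur
          top <- top + 1L; stack[top] <- qq
        }
      }
    }
  }
  lab
}

#' Select candidate spot pixels in one frame
#'
#' The pixel-level stage of [detect_spots()]: a pixel is selected iff it
#' (a) reaches the intensity threshold, (b) lies inside the embryo mask,
#' and (c) exceeds the mean of its surrounding pixels - the ring of the
#' `(N+2) x (N+2)` window around it, excluding the central `N x N` block -
#' by at least the contrast threshold. Pixels whose window leaves the
#' frame are skipped and counted in the `skipped_border` attribute.
#'
#' @param frame height x width intensity matrix.
#' @param config a [tracking_config()].
#' @param mask logical matrix of the same size (TRUE = inside embryo).
#' @return logical matrix of selected pixels with attribute
#'   `skipped_border`.
#' @export
select_spot_pixels <- function(frame, config, mask = NULL) {
  stopifnot(inherits(config, "tracking_config"))
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!is.logical(mask) || !all(dim(mask) == c(h, w)))
    stop_invalid("mask must be a logical height x width matrix")
  r <- (config$spot_size_N + 1L) %/% 2L  # Chebyshev radius of the surround ring
  ring <- expand.grid(dy = -r:r, dx = -r:r)
  ring <- ring[pmax(abs(ring$dy), abs(ring$dx)) == r, ]
  sel <- frame >= config$intensity_threshold & mask
  # border pixels whose (N+2) window leaves the frame are skipped
  border <- matrix(FALSE, h, w)
  border[c(seq_len(r), h - seq_len(r) + 1L), ] <- TRUE
  border[, c(seq_len(r), w - seq_len(r) + 1L)] <- TRUE
  skipped <- sum(sel & border)
  sel <- sel & !border
  if (any(sel)) {
    # mean of the surround ring, accumulated over shifted copies
    acc <- matrix(0, h, w)
    ys <- (r + 1L):(h - r); xs <- (r + 1L):(w - r)
    for (k in seq_len(nrow(ring)))
      acc[ys, xs] <- acc[ys, xs] + frame[ys + ring$dy[k], xs + ring$dx[k]]
    sel <- sel & (frame - acc / nrow(ring) >= config$contrast_threshold)
  }
  attr(sel, "skipped_border") <- skipped
  sel
}

#' Detect MS2 transcription spots
#'
#' Per-frame spot detection on maximum-projected movies, following the
#' thresholding scheme of the quantification pipeline: (a) pixels at or
#' above the intensity threshold are selected; (b) pixels outside the
#' embryo mask are excluded; (c) a regional contrast test compares each
#' remaining pixel with the mean of its surrounding pixels in an
#' `(N+2) x (N+2)` window (the ring left after removing the central
#' `N x N` block) and requires the difference to reach the contrast
#' threshold. Surviving pixels are merged by 8-connectivity into spots
#' with intensity-weighted centroids; central coordinates, averaged
#' intensity and AP position are recorded. Pixels whose surround window
#' would leave the frame are skipped and counted in the `skipped_border`
#' attribute.
#'
#' @param movie an [ms2_movie()].
#' @param config a [tracking_config()].
#' @param mask logical embryo mask (same height/width as the frames);
#'   defaults to all-inside.
#' @return data frame of spot candidates with columns `frame`, `x`, `y`
#'   (px, intensity-weighted centroid), `intensity` (mean of member
#'   pixels), `n_px` and `el` (%EL); attribute `skipped_border` counts the
#'   border pixels excluded per frame.
#' @export
detect_spots <- function(movie, config, mask = NULL) {
  stopifnot(inherits(movie, "ms2_movie"), inherits(config, "tracking_config"))
  d <- dim(movie$frames); h <- d[1]; w <- d[2]; nt <- d[3]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!is.logical(mask) || !all(dim(mask) == c(h, w)))
    stop_invalid("mask must be a logical height x width matrix")
  out <- vector("list", nt)
  skipped <- integer(nt)
  for (f in seq_len(nt)) {
    fr <- movie$frames[, , f]
    sel <- select_spot_pixels(fr, config, mask)
    skipped[f] <- attr(sel, "skipped_border")
    if (!any(sel)) { out[[f]] <- NULL; next }
    lab <- label_components(sel)
    spots <- lapply(seq_len(max(lab)), function(i) {
      px <- which(lab == i)
      y <- (px - 1L) %% h + 1L; x <- (px - 1L) %/% h + 1L
      wgt <- fr[px]
      cx <- sum(x * wgt) / sum(wgt)
      data.frame(frame = f, x = cx, y = sum(y * wgt) / sum(wgt),
                 intensity = mean(wgt), n_px = length(px),
                 el = pixel_to_el(movie, cx))
    })
    out[[f]] <- do.call(rbind, spots)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      intensity = numeric(), n_px = integer(), el = numeric())
  attr(res, "skipped_border") <- skipped
  res
}
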