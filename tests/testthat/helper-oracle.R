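# Brute-force, per-pixel re-implementation of the spot pixel-selection
# rule, kept deliberately naive and independent of the package's shifted-
# matrix implementation: for every pixel it extracts the (N+2) x (N+2)
# window, removes the central N x N block and compares against the ring
# mean directly.
brute_force_pixels <- function(frame, config, mask = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  r <- (config$spot_size_N + 1) / 2
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      if (frame[y, x] < config$intensity_threshold) next
      if (!mask[y, x]) next
      if (y - r < 1 || y + r > h || x - r < 1 || x + r > w) next  # border skip
      win <- frame[(y - r):(y + r), (x - r):(x + r)]
      inner_n <- config$spot_size_N
      keep <- matrix(TRUE, nrow(win), ncol(win))
      mid <- r + 1
      half_in <- (inner_n - 1) / 2
      keep[(mid - half_in):(mid + half_in), (mid - half_in):(mid + half_in)] <- FALSE
      ring_mean <- mean(win[keep])
      if (frame[y, x] - ring_mean >= config$contrast_threshold)
        out[y, x] <- TRUE
    }
  }
  out
}

# random test frame: noisy background plus a few bright blobs
random_test_frame <- function(h = 64, w = 64, n_blobs = 6) {
  fr <- matrix(stats::rnorm(h * w, 100, 15), h, w)
  for (i in seq_len(n_blobs)) {
    cy <- sample.int(h, 1); cx <- sample.int(w, 1)
    amp <- stats::runif(1, 100, 900)
    sig <- stats::runif(1, 0.8, 2)
    ys <- max(1, cy - 4):min(h, cy + 4)
    xs <- max(1, cx - 4):min(w, cx + 4)
    fr[ys, xs] <- fr[ys, xs] + amp * outer(exp(-(ys - cy)^2 / (2 * sig^2)),
                                           exp(-(xs - cx)^2 / (2 * sig^2)))
  }
  pmax(fr, 0)
}
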