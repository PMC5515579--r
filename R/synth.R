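#' Reference gap-gene circuit parameter set
#'
#' The shipped, version-pinned parameter set used as the reference fixture
#' throughout the package. It was calibrated so that the dark-control
#' simulation on the default grid reproduces the printed wild-type domain
#' extents - Kr half-maximum boundaries at 58 and 45 %EL and the posterior
#' Kni domain at 45-37 %EL - together with an anterior Hb domain and
#' anterior Gt expression, and so that switching Bcd off from n.c. 13
#' onward shifts the Kr boundaries and the Kni anterior boundary towards
#' the anterior.
#'
#' The wiring follows the qualitative gap-gene network: Hb is a
#' slowly-decaying Bcd readout; Gt's anterior domain is Bcd-driven and
#' repressed by Kr; Kr reads the graded Hb flank incoherently (activated
#' by the monomer, repressed by the dimer) and is closed posteriorly by
#' Cad, Kni and Tll; Kni is driven by Cad and repressed by the Hb dimer
#' anteriorly and Tll posteriorly.
#'
#' @param seed ignored (the set is deterministic); accepted so all
#'   generators share a signature.
#' @return a [circuit_params()] object with id `"reference-v1"`.
#' @export
make_reference_circuit <- function(seed = NULL) {
  T <- matrix(0, 4, 5, dimnames = list(GENES, REGULATORS))
  M <- matrix(0, 4, 4, dimnames = list(GENES, MATERNALS))
  #          hb_m  hb_d   gt    kr   kni
  T["gt", ]  <- c(  0,    0,    0,  -6,    0)
  T["kr", ]  <- c( 40,  -45,    0,   0,   -8)
  T["kni", ] <- c(  0,  -80,    0,  -2,    0)
  #           bcd   cad  tll  hkb
  M["hb", ]  <- c(16.9,  0,    0,   0)
  M["gt", ]  <- c(60,    0,    0,  -5)
  M["kr", ]  <- c( 3,  -1.2, -10,  -5)
  M["kni", ] <- c( 2,   10,  -18,  -5)
  h <- c(hb = -1.12, gt = -4, kr = -0.8, kni = 1.6)
  circuit_params(
    T = T, M = M, h = h,
    R   = c(hb = 0.0075, gt = 0.12, kr = 0.12, kni = 0.12),
    lam = c(hb = 0.0075, gt = 0.12, kr = 0.12, kni = 0.12),
    D   = c(hb = 0.02,  gt = 0.1,  kr = 0.1,  kni = 0.1),
    K_hb = 0.25,
    id = "reference-v1"
  )
}

#' Emulated parameter ensemble
#'
#' Generates an ensemble of circuit parameter sets around a reference by
#' sign-preserving lognormal perturbation of every scalar parameter
#' (zero entries stay zero). The first member is the unchanged reference.
#' Stands in for the 21 externally fitted parameter sets in ensemble
#' scoring and z-score analyses.
#'
#' @param reference a [circuit_params()] object.
#' @param n ensemble size (default 21).
#' @param jitter relative log-scale standard deviation (>= 0).
#' @param seed RNG seed fixing the ensemble.
#' @return named list of `circuit_params` ("set01".."setNN").
#' @export
make_param_ensemble <- function(reference = make_reference_circuit(), n = 21,
                                jitter = 0.15, seed = 1) {
  stopifnot(inherits(reference, "circuit_params"))
  if (!is_scalar_number(n) || n < 1) stop_invalid("n must be >= 1")
  if (!is_scalar_number(jitter) || jitter < 0) stop_invalid("jitter must be >= 0")
  set.seed(seed)
  perturb <- function(x) x * exp(stats::rnorm(length(x), 0, jitter))
  out <- vector("list", n)
  out[[1]] <- reference
  for (i in seq_len(n)[-1]) {
    out[[i]] <- circuit_params(
      T = matrix(perturb(reference$T), 4, 5),
      M = matrix(perturb(reference$M), 4, 4),
      h = perturb(reference$h),
      R = perturb(reference$R),
      lam = perturb(reference$lam),
      D = perturb(reference$D),
      K_hb = perturb(reference$K_hb),
      id = sprintf("set%02d", i))
  }
  names(out) <- sprintf("set%02d", seq_len(n))
  out[[1]]$id <- "set01"
  out
}

#' Synthetic MS2 movie configuration
#'
#' Parameters of the synthetic transcription-spot movie generator. Spot
#' on-durations are drawn from a truncated normal persistence distribution
#' (mean and sd in minutes, floored at zero; "exponential" is selectable),
#' matching how persistence is reported for hb transcription (e.g. 7.1
#' +/- 3.2 min in unperturbed n.c. 13 anterior domains). Frames default to
#' a desk-scale 256 x 128 px field at 40 s resolution.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames (default 40).
#' @param n_nuclei number of transcription sites.
#' @param spot_prob probability that a nucleus fires at all.
#' @param persistence_mean,persistence_sd on-duration distribution,
#'   minutes.
#' @param persistence_dist "truncnorm" (default) or "exponential".
#' @param spot_amplitude peak intensity of a rendered spot (counts).
#' @param spot_sigma Gaussian spot radius in pixels.
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param poisson_noise also apply Poisson resampling of intensities.
#' @param drift deterministic spot drift, px/frame (length 2: x, y).
#' @param jitter_px random per-frame centroid jitter sd (px).
#' @param min_separation minimum distance between nuclei (px).
#' @param ap_el %EL at the left and right frame edges (anterior = 100).
#' @param seed RNG seed; fixes the full output.
#' @return a list of class `synth_movie_config`.
#' @export
synth_movie_config <- function(width = 256, height = 128, n_frames = 30,
                               frame_interval = 40, n_nuclei = 12,
                               spot_prob = 0.8, persistence_mean = 7.1,
                               persistence_sd = 3.2,
                               persistence_dist = c("truncnorm", "exponential"),
                               spot_amplitude = 800, spot_sigma = 1.2,
                               noise_sd = 10, poisson_noise = FALSE,
                               drift = c(0, 0), jitter_px = 0.3,
                               min_separation = 20,
                               ap_el = c(90, 40), seed = 1) {
  if (width < 8 || height < 8 || n_frames < 1 || n_nuclei < 0)
    stop_invalid("movie dimensions must be positive")
  if (persistence_mean <= 0) stop_invalid("persistence_mean must be > 0")
  structure(list(width = width, height = height, n_frames = n_frames,
                 frame_interval = frame_interval, n_nuclei = n_nuclei,
                 spot_prob = spot_prob, persistence_mean = persistence_mean,
                 persistence_sd = persistence_sd,
                 persistence_dist = match.arg(persistence_dist),
                 spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
                 noise_sd = noise_sd, poisson_noise = poisson_noise,
                 drift = drift, jitter_px = jitter_px,
                 min_separation = min_separation, ap_el = ap_el, seed = seed),
            class = "synth_movie_config")
}

# truncated-normal persistence draw (minutes), floored at `floor`
draw_persistence <- function(n, config, floor = 0) {
  if (config$persistence_dist == "exponential")
    return(stats::rexp(n, 1 / config$persistence_mean))
  x <- stats::rnorm(n, config$persistence_mean, config$persistence_sd)
  while (any(x <= floor))
    x[x <= floor] <- stats::rnorm(sum(x <= floor), config$persistence_mean,
                                  config$persistence_sd)
  x
}

#' Render noiseless frames from ground-truth spot positions
#'
#' Spots are 2-D Gaussian bumps of the configured amplitude and width.
#' Used by the generator itself and exposed so data/ground-truth
#' consistency can be verified by re-rendering.
#'
#' @param truth_tracks data frame with columns `nucleus`, `frame`, `x`,
#'   `y` (one row per spot per frame it is on).
#' @param config a [synth_movie_config()].
#' @return `height x width x n_frames` array without noise.
#' @export
render_ms2_frames <- function(truth_tracks, config) {
  frames <- array(0, c(config$height, config$width, config$n_frames))
  if (nrow(truth_tracks)) {
    half <- ceiling(4 * config$spot_sigma)
    for (i in seq_len(nrow(truth_tracks))) {
      cx <- truth_tracks$x[i]; cy <- truth_tracks$y[i]
      f <- truth_tracks$frame[i]
      xs <- max(1, floor(cx - half)):min(config$width, ceiling(cx + half))
      ys <- max(1, floor(cy - half)):min(config$height, ceiling(cy + half))
      g <- config$spot_amplitude *
        outer(exp(-(ys - cy)^2 / (2 * config$spot_sigma^2)),
              exp(-(xs - cx)^2 / (2 * config$spot_sigma^2)))
      frames[ys, xs, f] <- frames[ys, xs, f] + g
    }
  }
  frames
}

#' Generate a synthetic MS2 movie with ground truth
#'
#' Places well-separated transcription sites, draws an on-interval per
#' firing site from the persistence distribution, renders spots as 2-D
#' Gaussian bumps (with optional drift and centroid jitter), and applies
#' noise after rendering. The returned ground truth lists every emitted
#' spot and per-site on-intervals, so detection/tracking/persistence
#' recovery can be tested exactly.
#'
#' @param config a [synth_movie_config()].
#' @return list with `movie` (an [ms2_movie()]), and `truth`: list with
#'   `tracks` (nucleus, frame, x, y per on-frame), `summary` (per firing
#'   nucleus: start/end frame, n_frames, duration_s, mean_el) and
#'   `crowded` flag (TRUE if nucleus placement could not honour the
#'   minimum separation).
#' @export
make_ms2_movie <- function(config = synth_movie_config()) {
  stopifnot(inherits(config, "synth_movie_config"))
  set.seed(config$seed)
  margin <- 6
  # rejection-sample nucleus positions with a minimum separation
  pos <- matrix(numeric(0), 0, 2)
  crowded <- FALSE
  tries <- 0
  while (nrow(pos) < config$n_nuclei) {
    cand <- c(stats::runif(1, margin, config$width - margin),
              stats::runif(1, margin, config$height - margin))
    ok <- !nrow(pos) ||
      min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
        config$min_separation
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1
    if (tries > 200 * max(1, config$n_nuclei)) { crowded <- TRUE; break }
  }
  n_placed <- nrow(pos)
  fires <- stats::runif(n_placed) < config$spot_prob
  dur_min <- draw_persistence(n_placed, config)
  dur_frames <- pmax(1L, as.integer(round(dur_min * 60 / config$frame_interval)))
  dur_frames <- pmin(dur_frames, config$n_frames)
  starts <- vapply(dur_frames, function(d)
    sample.int(config$n_frames - d + 1L, 1L), integer(1))
  rows <- list()
  for (i in seq_len(n_placed)) {
    if (!fires[i]) next
    fr <- starts[i]:(starts[i] + dur_frames[i] - 1L)
    k <- seq_along(fr) - 1L
    jx <- stats::rnorm(length(fr), 0, config$jitter_px)
    jy <- stats::rnorm(length(fr), 0, config$jitter_px)
    rows[[length(rows) + 1L]] <- data.frame(
      nucleus = i, frame = fr,
      x = pos[i, 1] + k * config$drift[1] + jx,
      y = pos[i, 2] + k * config$drift[2] + jy)
  }
  tracks <- if (length(rows)) do.call(rbind, rows)
            else data.frame(nucleus = integer(), frame = integer(),
                            x = numeric(), y = numeric())
  frames <- render_ms2_frames(tracks, config)
  if (config$noise_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames), 0, config$noise_sd),
                             dim(frames))
  if (config$poisson_noise)
    frames <- array(stats::rpois(length(frames), pmax(frames, 0)), dim(frames))
  frames <- pmax(frames, 0)
  slope <- (config$ap_el[2] - config$ap_el[1]) / config$width
  movie <- ms2_movie(frames, frame_interval = config$frame_interval,
                     ap_intercept = config$ap_el[1], ap_slope = slope)
  summary <- if (nrow(tracks)) {
    sp <- split(tracks, tracks$nucleus)
    do.call(rbind, lapply(sp, function(tt) data.frame(
      nucleus = tt$nucleus[1], start_frame = min(tt$frame),
      end_frame = max(tt$frame), n_frames = nrow(tt),
      duration_s = nrow(tt) * config$frame_interval,
      mean_el = mean(pixel_to_el(movie, tt$x)))))
  } else data.frame(nucleus = integer(), start_frame = integer(),
                    end_frame = integer(), n_frames = integer(),
                    duration_s = numeric(), mean_el = numeric())
  rownames(summary) <- NULL
  list(movie = movie,
       truth = list(tracks = tracks, summary = summary, crowded = crowded,
                    config = config))
}

#' Generate synthetic nuclear gradient records
#'
#' Nuclei uniformly spread along the AP axis with intensities from the
#' exponential gradient model times multiplicative Gaussian noise,
#' emulating nuclear Bcd quantification data.
#'
#' @param n_nuclei number of nuclei (default 500).
#' @param true_params list with `amplitude`, `length_scale` (um),
#'   `offset`.
#' @param noise_sd multiplicative noise sd (e.g. 0.05 for 5%).
#' @param seed RNG seed.
#' @param embryo_length egg length in micrometres.
#' @return list with `nuclei` (data frame `embryo_id`, `position_um`,
#'   `el`, `intensity`) and `truth` (the generating parameters).
#' @export
make_gradient_nuclei <- function(n_nuclei = 500,
                                 true_params = list(amplitude = 1000,
                                                    length_scale = 80,
                                                    offset = 50),
                                 noise_sd = 0.05, seed = 1,
                                 embryo_length = 500) {
  if (true_params$length_scale <= 0) stop_invalid("length_scale must be > 0")
  set.seed(seed)
  el <- stats::runif(n_nuclei, 0, 100)
  d <- anterior_distance_um(el, embryo_length)
  model <- true_params$amplitude * exp(-d / true_params$length_scale) +
    true_params$offset
  intensity <- model * (1 + stats::rnorm(n_nuclei, 0, noise_sd))
  list(nuclei = data.frame(embryo_id = 1L,
                           position_um = el / 100 * embryo_length,
                           el = el, intensity = intensity),
       truth = true_params)
}
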