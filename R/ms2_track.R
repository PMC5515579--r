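#' Link spots into tracks frame by frame
#'
#' Greedy one-to-one nearest-neighbour linking: for each consecutive frame
#' pair, candidate links (pairs closer than the maximum displacement) are
#' sorted by ascending distance - ties broken by the smaller (y, x)
#' centroid of the later spot, then of the earlier spot - and accepted
#' greedily, each spot joining at most one link per frame pair. Unlinked
#' spots start new tracks. There is no gap closing: a track covers
#' strictly consecutive frames.
#'
#' @param spots spot data frame from [detect_spots()] (columns `frame`,
#'   `x`, `y`, `intensity`, `el`).
#' @param config a [tracking_config()].
#' @param frame_interval seconds between frames (used downstream for
#'   durations); stored as an attribute.
#' @return the spot data frame with an added `track_id` column, class
#'   `ms2_tracks`, attribute `frame_interval`.
#' @export
link_tracks <- function(spots, config, frame_interval = 40) {
  stopifnot(inherits(config, "tracking_config"))
  spots <- as.data.frame(spots)
  if (!nrow(spots)) {
    spots$track_id <- integer(0)
    return(structure(spots, frame_interval = frame_interval,
                     duration_convention = config$duration_convention,
                     class = c("ms2_tracks", "data.frame")))
  }
  spots <- spots[order(spots$frame, spots$y, spots$x), , drop = FALSE]
  rownames(spots) <- NULL
  spots$track_id <- NA_integer_
  next_id <- 0L
  # iterate every frame index: an empty frame breaks all chains (no gap
  # closing), so links only ever join consecutive frames
  frames <- seq(min(spots$frame), max(spots$frame))
  prev_rows <- integer(0)
  for (f in frames) {
    cur_rows <- which(spots$frame == f)
    linked_cur <- rep(FALSE, length(cur_rows))
    if (length(prev_rows)) {
      # all candidate pairs within the displacement range
      dx <- outer(spots$x[prev_rows], spots$x[cur_rows], `-`)
      dy <- outer(spots$y[prev_rows], spots$y[cur_rows], `-`)
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= config$max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(dist[cand],
                   spots$y[cur_rows][cand[, 2L]], spots$x[cur_rows][cand[, 2L]],
                   spots$y[prev_rows][cand[, 1L]], spots$x[prev_rows][cand[, 1L]])
        cand <- cand[o, , drop = FALSE]
        used_prev <- rep(FALSE, length(prev_rows))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1L]; j <- cand[k, 2L]
          if (used_prev[i] || linked_cur[j]) next
          used_prev[i] <- TRUE; linked_cur[j] <- TRUE
          spots$track_id[cur_rows[j]] <- spots$track_id[prev_rows[i]]
        }
      }
    }
    for (j in which(!linked_cur)) {
      next_id <- next_id + 1L
      spots$track_id[cur_rows[j]] <- next_id
    }
    prev_rows <- cur_rows
  }
  # tracks must span consecutive frames; a skipped frame breaks the chain
  structure(spots, frame_interval = frame_interval,
            duration_convention = config$duration_convention,
            class = c("ms2_tracks", "data.frame"))
}

track_duration_s <- function(n_spots, frame_interval,
                             convention = c("frames", "span")) {
  convention <- match.arg(convention)
  if (convention == "frames") n_spots * frame_interval
  else (n_spots - 1) * frame_interval
}

#' Summarise tracks
#'
#' @param tracks an `ms2_tracks` data frame from [link_tracks()].
#' @return data frame with one row per track: `track_id`, `start_frame`,
#'   `end_frame`, `n_spots`, `duration_s` and `mean_el`.
#' @export
track_summary <- function(tracks) {
  stopifnot(inherits(tracks, "ms2_tracks"))
  fi <- attr(tracks, "frame_interval")
  conv <- attr(tracks, "duration_convention") %||% "frames"
  if (!nrow(tracks))
    return(data.frame(track_id = integer(), start_frame = integer(),
                      end_frame = integer(), n_spots = integer(),
                      duration_s = numeric(), mean_el = numeric()))
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  out <- do.call(rbind, lapply(sp, function(ix) {
    data.frame(track_id = tracks$track_id[ix[1]],
               start_frame = min(tracks$frame[ix]),
               end_frame = max(tracks$frame[ix]),
               n_spots = length(ix),
               duration_s = track_duration_s(length(ix), fi, conv),
               mean_el = mean(tracks$el[ix]))
  }))
  rownames(out) <- NULL
  out[order(out$track_id), , drop = FALSE]
}

#' Persistence filter
#'
#' Discards tracks lasting less than the minimum duration (160 s by
#' default - shorter than one complete hb transcription event). A track of
#' exactly the cutoff duration is retained. Idempotent.
#'
#' @param tracks an `ms2_tracks` object.
#' @param config a [tracking_config()] carrying `min_duration`.
#' @return filtered `ms2_tracks` object.
#' @export
filter_tracks <- function(tracks, config) {
  stopifnot(inherits(tracks, "ms2_tracks"), inherits(config, "tracking_config"))
  if (!nrow(tracks)) return(tracks)
  ts <- track_summary(tracks)
  keep_ids <- ts$track_id[ts$duration_s >= config$min_duration]
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, frame_interval = attr(tracks, "frame_interval"),
            duration_convention = attr(tracks, "duration_convention"),
            class = class(tracks))
}

#' Default AP regions for persistence statistics
#'
#' The five anterior subdivisions (100-75, 75-70, 70-65, 65-60 and
#' 60-40 %EL) plus the posterior hb domain. Regions are half-open
#' `[lo, hi)` except the most anterior, which includes 100 %EL.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
default_regions <- function() {
  list("100-75" = c(75, 100), "75-70" = c(70, 75), "70-65" = c(65, 70),
       "65-60" = c(60, 65), "60-40" = c(40, 60), "posterior" = c(0, 40))
}

assign_region <- function(el, regions) {
  his <- vapply(regions, `[`, numeric(1), 2L)
  top <- names(regions)[which.max(his)]
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (el >= r[1] && (el < r[2] || (nm == top && el <= r[2]))) return(nm)
  }
  NA_character_
}

#' Regional persistence statistics
#'
#' Assigns each track to the AP region containing its mean position and
#' summarises per-region persistence: a probability histogram over
#' duration (mass sums to 1 in non-empty regions) plus mean and standard
#' deviation in minutes. Tracks falling outside every region are collected
#' in an "unassigned" bucket with a warning.
#'
#' @param tracks an `ms2_tracks` object (typically after
#'   [filter_tracks()]).
#' @param regions named list of %EL intervals, see [default_regions()].
#' @param breaks_min histogram breaks in minutes (default 1-min bins up to
#'   the longest track).
#' @return object of class `persistence_stats`: named list per region with
#'   `n`, `mean_min`, `sd_min` and `histogram` (data frame `mid_min`,
#'   `prob`).
#' @export
persistence_stats <- function(tracks, regions = default_regions(),
                              breaks_min = NULL) {
  stopifnot(inherits(tracks, "ms2_tracks"))
  ts <- track_summary(tracks)
  dur_min <- ts$duration_s / 60
  reg <- vapply(ts$mean_el, assign_region, character(1), regions = regions)
  if (any(is.na(reg))) {
    warning(sprintf("%d track(s) outside all regions; counted as 'unassigned'",
                    sum(is.na(reg))))
    reg[is.na(reg)] <- "unassigned"
  }
  if (is.null(breaks_min))
    breaks_min <- seq(0, max(c(dur_min, 1)) + 1, by = 1)
  out <- lapply(c(names(regions),
                  if (any(reg == "unassigned")) "unassigned"), function(nm) {
    d <- dur_min[reg == nm]
    if (!length(d))
      return(list(n = 0L, mean_min = NA_real_, sd_min = NA_real_,
                  histogram = data.frame(mid_min = numeric(), prob = numeric())))
    hh <- graphics::hist(d, breaks = breaks_min, plot = FALSE)
    list(n = length(d), mean_min = mean(d), sd_min = stats::sd(d),
         histogram = data.frame(mid_min = hh$mids, prob = hh$counts / length(d)))
  })
  names(out) <- c(names(regions), if (any(reg == "unassigned")) "unassigned")
  structure(out, class = "persistence_stats")
}

#' @export
print.persistence_stats <- function(x, ...) {
  cat("<persistence_stats> per AP region (minutes):\n")
  for (nm in names(x))
    cat(sprintf("  %-10s n = %3d  mean = %s  sd = %s\n", nm, x[[nm]]$n,
                formatC(x[[nm]]$mean_min, digits = 3),
                formatC(x[[nm]]$sd_min, digits = 3)))
  invisible(x)
}

#' Spot density time series
#'
#' Average density of fluorescent spots inside an AP domain, per frame, in
#' spots per 100 x 100 px^2 of domain area.
#'
#' @param spots spot data frame ([detect_spots()] output).
#' @param movie the [ms2_movie()] the spots came from (provides the
#'   calibration and frame geometry).
#' @param domain `c(lo, hi)` %EL interval.
#' @return data frame with `frame` and `density` (zero for empty frames).
#' @export
spot_density <- function(spots, movie, domain) {
  stopifnot(inherits(movie, "ms2_movie"))
  d <- dim(movie$frames)
  # nominal domain width under the linear calibration (px)
  width_px <- abs(diff(el_to_pixel(movie, domain)))
  if (width_px <= 0) stop_invalid("domain maps to zero pixel area")
  area_units <- width_px * d[1] / 1e4  # units of 100 x 100 px^2
  counts <- integer(d[3])
  if (nrow(spots)) {
    inside <- spots$el >= domain[1] & spots$el <= domain[2]
    tab <- table(factor(spots$frame[inside], levels = seq_len(d[3])))
    counts <- as.integer(tab)
  }
  data.frame(frame = seq_len(d[3]), density = counts / area_units)
}

#' Residual elongation window of the MS2 reporter
#'
#' Time for RNA polymerase II to traverse the reporter gene, truncated to
#' whole minutes: with the 6.4 kb MS2-yellow reporter and a measured
#' elongation rate of 1.54 kb/min this is 4 min - the window during which
#' reporter signal persists after transcription initiation stops.
#'
#' @param reporter_kb reporter length in kb (default 6.4).
#' @param rate_kb_per_min Pol II elongation rate (default 1.54).
#' @return whole minutes (numeric).
#' @export
#' @examples
#' elongation_clearance_min()  # 4
elongation_clearance_min <- function(reporter_kb = 6.4, rate_kb_per_min = 1.54) {
  if (!is_scalar_number(reporter_kb) || reporter_kb <= 0 ||
      !is_scalar_number(rate_kb_per_min) || rate_kb_per_min <= 0)
    stop_invalid("lengths and rates must be > 0")
  floor(reporter_kb / rate_kb_per_min)
}

#' Write spot and track tables as CSV
#'
#' @param tracks an `ms2_tracks` object.
#' @param path output file; units are embedded in the header names.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- as.data.frame(tracks)
  names(df) <- c("frame", "x_px", "y_px", "intensity_counts", "n_px",
                 "el_percent", "track_id")[seq_along(names(df))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
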