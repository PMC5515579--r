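#' Run a named pipeline command
#'
#' Thin programmatic entry point mirroring the command-line interface.
#' Every run writes its outputs into `out_dir` together with exactly one
#' `manifest.json` tying the outputs to the configuration hash, seed and
#' package version.
#'
#' Commands:
#' \describe{
#'   \item{synth}{generate a synthetic MS2 movie (TIFF + ground-truth CSVs)
#'     and synthetic gradient nuclei (CSV).}
#'   \item{simulate}{dark-control circuit simulation of the reference
#'     fixture; trajectory CSV.}
#'   \item{perturb}{run the scenario battery; one trajectory CSV per
#'     scenario plus a criterion report CSV.}
#'   \item{score}{generate a parameter ensemble, score every member on the
#'     criteria scenario, select the subset and write z-scores.}
#'   \item{track}{generate (or read) a movie and run
#'     detection/linking/filtering/statistics; spots, tracks and
#'     per-region CSVs.}
#'   \item{profile}{bin nuclei (from `input` CSV or the synthetic
#'     generator), fit the exponential gradient, call boundaries.}
#'   \item{chip}{percent-input normalisation of a qPCR Ct table (`input`
#'     CSV with columns `target`, `condition`, `ct_ip`, `ct_input`).}
#' }
#'
#' @param name one of `synth`, `simulate`, `perturb`, `score`, `track`,
#'   `profile`, `chip`.
#' @param config configuration list from [load_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for every stochastic stage.
#' @param input optional input file (TIFF for `track`, CSV for
#'   `profile`/`chip`).
#' @return invisibly, the manifest list.
#' @export
run_command <- function(name, config = load_config(), out_dir = ".",
                        seed = 1, input = NULL) {
  name <- match.arg(name, c("synth", "simulate", "perturb", "score",
                            "track", "profile", "chip"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(name,
    synth    = cmd_synth(config, out_dir, seed),
    simulate = cmd_simulate(config, out_dir),
    perturb  = cmd_perturb(config, out_dir),
    score    = cmd_score(config, out_dir, seed),
    track    = cmd_track(config, out_dir, seed, input),
    profile  = cmd_profile(config, out_dir, seed, input),
    chip     = cmd_chip(config, out_dir, input))
  manifest <- list(command = name, config_hash = config_hash(config),
                   seed = seed, input = input %||% NA,
                   outputs = outputs,
                   package_version = as.character(utils::packageVersion("bcdecode")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

circuit_world <- function(config) {
  grid <- axis_grid(config$circuit$n_bins,
                    embryo_length = config$circuit$embryo_length)
  list(grid = grid,
       maternal = make_maternal_inputs(grid, config$circuit$bcd_length_scale),
       params = make_reference_circuit())
}

config_scenarios <- function(config) {
  ids <- config$scenarios$battery
  sc <- default_scenarios(ids)
  for (id in names(config$scenarios$windows %||% list())) {
    wins <- lapply(config$scenarios$windows[[id]], as.numeric)
    sc[[id]] <- illumination_scenario(id, wins)
  }
  sc
}

cmd_synth <- function(config, out_dir, seed) {
  sy <- config$synth
  mc <- synth_movie_config(width = sy$width, height = sy$height,
                           n_frames = sy$n_frames,
                           frame_interval = sy$frame_interval,
                           n_nuclei = sy$n_nuclei, spot_prob = sy$spot_prob,
                           persistence_mean = sy$persistence_mean,
                           persistence_sd = sy$persistence_sd,
                           persistence_dist = sy$persistence_dist,
                           spot_amplitude = sy$spot_amplitude,
                           spot_sigma = sy$spot_sigma, noise_sd = sy$noise_sd,
                           poisson_noise = sy$poisson_noise, drift = sy$drift,
                           jitter_px = sy$jitter_px,
                           min_separation = sy$min_separation,
                           ap_el = sy$ap_el, seed = seed)
  mv <- make_ms2_movie(mc)
  grad <- make_gradient_nuclei(sy$n_gradient_nuclei,
                               noise_sd = sy$gradient_noise_sd, seed = seed,
                               embryo_length = config$circuit$embryo_length)
  paths <- c(movie = file.path(out_dir, "movie.tif"),
             truth_tracks = file.path(out_dir, "truth_tracks.csv"),
             truth_summary = file.path(out_dir, "truth_summary.csv"),
             nuclei = file.path(out_dir, "nuclei.csv"))
  write_ms2_tiff(mv$movie, paths["movie"])
  utils::write.csv(mv$truth$tracks, paths["truth_tracks"], row.names = FALSE)
  utils::write.csv(mv$truth$summary, paths["truth_summary"], row.names = FALSE)
  utils::write.csv(grad$nuclei, paths["nuclei"], row.names = FALSE)
  as.list(paths)
}

cmd_simulate <- function(config, out_dir) {
  w <- circuit_world(config)
  tr <- simulate_circuit(w$params, w$maternal, grid = w$grid,
                         t_start = config$circuit$t_start,
                         t_end = config$circuit$t_end, dt = config$circuit$dt)
  p <- file.path(out_dir, "trajectory_dark.csv")
  write_trajectory_csv(tr, p)
  list(trajectory = p)
}

cmd_perturb <- function(config, out_dir) {
  w <- circuit_world(config)
  trs <- run_scenarios(w$params, w$maternal, config_scenarios(config),
                       grid = w$grid, t_start = config$circuit$t_start,
                       t_end = config$circuit$t_end, dt = config$circuit$dt)
  paths <- character(0)
  for (id in names(trs)) {
    p <- file.path(out_dir, sprintf("trajectory_scenario%s.csv", id))
    write_trajectory_csv(trs[[id]], p)
    paths[sprintf("trajectory_%s", id)] <- p
  }
  dark <- end_state(trs[[1]])
  reports <- lapply(names(trs)[-1], function(id)
    score_criteria(dark, end_state(trs[[id]]), w$grid,
                   thresholds = config$criteria,
                   domains = config$profile$domains, scenario_id = id))
  p <- file.path(out_dir, "criterion_report.csv")
  utils::write.csv(criteria_table(reports), p, row.names = FALSE)
  paths["criterion_report"] <- p
  as.list(paths)
}

cmd_score <- function(config, out_dir, seed) {
  w <- circuit_world(config)
  ens <- make_param_ensemble(w$params, n = config$ensemble$n,
                             jitter = config$ensemble$jitter, seed = seed)
  sc5 <- config_scenarios(config)[[config$scenarios$criteria_scenario]]
  rows <- lapply(names(ens), function(id) {
    trs <- run_scenarios(ens[[id]], w$maternal,
                         list(illumination_scenario("1", list()), sc5),
                         grid = w$grid, t_start = config$circuit$t_start,
                         t_end = config$circuit$t_end, dt = config$circuit$dt)
    rep <- tryCatch(
      score_criteria(end_state(trs[[1]]), end_state(trs[[2]]), w$grid,
                     thresholds = config$criteria,
                     domains = config$profile$domains, scenario_id = sc5$id),
      bcdecode_domain_error = function(e) NULL)
    # a member whose control has no scorable domain meets no criteria
    data.frame(id = id, n_met = if (is.null(rep)) 0L else rep$n_met)
  })
  scores <- do.call(rbind, rows)
  subset_ids <- select_subset(scores, config$criteria$min_criteria)
  paths <- list(scores = file.path(out_dir, "ensemble_scores.csv"),
                zscores = file.path(out_dir, "param_zscores.csv"),
                zmatrix = file.path(out_dir, "zscore_matrix.csv"))
  utils::write.csv(scores, paths$scores, row.names = FALSE)
  if (length(subset_ids)) {
    z <- param_zscore(ens, subset_ids,
                      denominator = config$ensemble$zscore_denominator)
    utils::write.csv(z, paths$zscores, row.names = FALSE)
    utils::write.csv(as.data.frame(zscore_matrix(z)), paths$zmatrix)
  } else {
    paths$zscores <- NULL; paths$zmatrix <- NULL
  }
  paths$subset <- file.path(out_dir, "subset_ids.csv")
  utils::write.csv(data.frame(id = subset_ids), paths$subset, row.names = FALSE)
  paths
}

cmd_track <- function(config, out_dir, seed, input) {
  tk <- config$tracking
  tc <- tracking_config(tk$intensity_threshold, tk$spot_size_N,
                        tk$max_displacement, tk$contrast_threshold,
                        tk$min_duration, tk$duration_convention)
  movie <- if (is.null(input)) {
    sy <- config$synth
    make_ms2_movie(synth_movie_config(width = sy$width, height = sy$height,
                                      n_frames = sy$n_frames,
                                      frame_interval = tk$frame_interval,
                                      n_nuclei = sy$n_nuclei,
                                      spot_prob = sy$spot_prob,
                                      persistence_mean = sy$persistence_mean,
                                      persistence_sd = sy$persistence_sd,
                                      noise_sd = sy$noise_sd,
                                      min_separation = sy$min_separation,
                                      ap_el = sy$ap_el, seed = seed))$movie
  } else read_ms2_tiff(input, frame_interval = tk$frame_interval)
  spots <- detect_spots(movie, tc)
  tracks <- filter_tracks(link_tracks(spots, tc, movie$frame_interval), tc)
  stats <- persistence_stats(tracks)
  paths <- list(spots = file.path(out_dir, "spots.csv"),
                tracks = file.path(out_dir, "tracks.csv"),
                track_summary = file.path(out_dir, "track_summary.csv"),
                region_stats = file.path(out_dir, "region_stats.csv"))
  utils::write.csv(spots, paths$spots, row.names = FALSE)
  write_tracks_csv(tracks, paths$tracks)
  utils::write.csv(track_summary(tracks), paths$track_summary,
                   row.names = FALSE)
  st <- do.call(rbind, lapply(names(stats), function(nm) data.frame(
    region = nm, n = stats[[nm]]$n, mean_min = stats[[nm]]$mean_min,
    sd_min = stats[[nm]]$sd_min)))
  utils::write.csv(st, paths$region_stats, row.names = FALSE)
  paths
}

cmd_profile <- function(config, out_dir, seed, input) {
  nuclei <- if (is.null(input)) {
    make_gradient_nuclei(config$synth$n_gradient_nuclei,
                         noise_sd = config$synth$gradient_noise_sd,
                         seed = seed,
                         embryo_length = config$circuit$embryo_length)$nuclei
  } else utils::read.csv(input)
  prof <- extract_profile(nuclei, config$profile$bin_width_um,
                          config$circuit$embryo_length,
                          config$profile$background)
  fit <- fit_exponential(prof, config$circuit$embryo_length,
                         config$profile$include_offset)
  paths <- list(profile = file.path(out_dir, "profile.csv"),
                fit = file.path(out_dir, "gradient_fit.json"))
  utils::write.csv(data.frame(el_percent = prof$positions,
                              intensity = prof$values),
                   paths$profile, row.names = FALSE)
  jsonlite::write_json(unclass(fit), paths$fit, auto_unbox = TRUE, digits = NA)
  paths
}

cmd_chip <- function(config, out_dir, input) {
  if (is.null(input)) stop_invalid("chip command needs an input Ct table")
  ct <- utils::read.csv(input)
  need <- c("target", "condition", "ct_ip", "ct_input")
  if (!all(need %in% names(ct)))
    stop_invalid("Ct table needs columns: %s", paste(need, collapse = ", "))
  ct$percent_input <- percent_input(
    ct$ct_ip, adjusted_input_ct(ct$ct_input, config$chip$input_percent))
  # relative % input of illuminated vs dark, per target
  rel <- NULL
  if (all(c("light", "dark") %in% ct$condition)) {
    wide <- merge(ct[ct$condition == "light", c("target", "percent_input")],
                  ct[ct$condition == "dark", c("target", "percent_input")],
                  by = "target", suffixes = c("_light", "_dark"))
    wide$relative_percent_input <- relative_percent_input(
      wide$percent_input_light, wide$percent_input_dark)
    rel <- wide
  }
  paths <- list(percent_input = file.path(out_dir, "percent_input.csv"))
  utils::write.csv(ct, paths$percent_input, row.names = FALSE)
  if (!is.null(rel)) {
    paths$relative <- file.path(out_dir, "relative_percent_input.csv")
    utils::write.csv(rel, paths$relative, row.names = FALSE)
  }
  paths
}
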