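#' Default shared configuration
#'
#' One nested schema shared by all pipeline stages. Time is always minutes
#' on the gastrulation clock, positions always %EL with anterior = 100.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    circuit = list(
      n_bins = 100L, embryo_length = 500, bcd_length_scale = 80,
      t_start = -90, t_end = 0, dt = 0.01
    ),
    scenarios = list(
      battery = as.character(1:6),
      windows = NULL,            # optional list(id = list(c(start, end), ...))
      criteria_scenario = "5"
    ),
    criteria = list(
      shift_el = 1, level_drop = 0.10, min_criteria = 3L
    ),
    ensemble = list(n = 21L, jitter = 0.15, zscore_denominator = "sqrt_n"),
    tracking = list(
      intensity_threshold = 100, spot_size_N = 3L, max_displacement = 5,
      contrast_threshold = 50, min_duration = 160,
      duration_convention = "frames", frame_interval = 40
    ),
    profile = list(
      bin_width_um = 5, background = 0, include_offset = TRUE,
      domains = default_domains()
    ),
    chip = list(input_percent = 2),
    synth = list(
      width = 256L, height = 128L, n_frames = 30L, frame_interval = 40,
      n_nuclei = 12L, spot_prob = 0.8, persistence_mean = 7.1,
      persistence_sd = 3.2, persistence_dist = "truncnorm",
      spot_amplitude = 800, spot_sigma = 1.2, noise_sd = 10,
      poisson_noise = FALSE, drift = c(0, 0), jitter_px = 0.3,
      min_separation = 20, ap_el = c(90, 40),
      n_gradient_nuclei = 500L, gradient_noise_sd = 0.05
    )
  )
}

# recursively merge user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_config("unknown configuration key: %s",
                paste(c(path, unknown[1]), collapse = "."))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
                          !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    else user[[nm]]
  }
  defaults
}

validate_config <- function(cfg) {
  ck <- function(cond, msg, ...) if (!cond) stop_config(msg, ...)
  ck(cfg$circuit$n_bins >= 10, "circuit.n_bins must be >= 10")
  ck(cfg$circuit$dt > 0, "circuit.dt must be > 0")
  ck(cfg$circuit$t_start < cfg$circuit$t_end && cfg$circuit$t_end <= 0,
     "circuit.t_start/t_end must satisfy t_start < t_end <= 0")
  ck(cfg$circuit$embryo_length > 0, "circuit.embryo_length must be > 0")
  ck(cfg$circuit$bcd_length_scale > 0, "circuit.bcd_length_scale must be > 0")
  ck(cfg$tracking$min_duration >= 0, "tracking.min_duration must be >= 0")
  ck(cfg$tracking$spot_size_N %% 2 == 1 && cfg$tracking$spot_size_N >= 1,
     "tracking.spot_size_N must be odd and >= 1")
  ck(all(c(cfg$tracking$intensity_threshold, cfg$tracking$contrast_threshold,
           cfg$tracking$max_displacement) >= 0),
     "tracking thresholds must be >= 0")
  ck(cfg$tracking$frame_interval > 0, "tracking.frame_interval must be > 0")
  ck(cfg$profile$bin_width_um > 0, "profile.bin_width_um must be > 0")
  ck(cfg$criteria$shift_el >= 0 && cfg$criteria$level_drop >= 0,
     "criteria thresholds must be >= 0")
  ck(cfg$ensemble$n >= 1, "ensemble.n must be >= 1")
  ck(cfg$ensemble$zscore_denominator %in% c("sqrt_n", "n"),
     "ensemble.zscore_denominator must be 'sqrt_n' or 'n'")
  ck(cfg$synth$persistence_mean > 0, "synth.persistence_mean must be > 0")
  ck(cfg$chip$input_percent > 0 && cfg$chip$input_percent <= 100,
     "chip.input_percent must be in (0, 100]")
  invisible(cfg)
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON configuration (chosen by extension), checks every
#' key against the schema of [default_config()] (unknown keys are
#' rejected, naming the offending key), injects defaults for everything
#' omitted and validates module-level invariants. An empty or missing-body
#' file yields all defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or NULL for pure
#'   defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(validate_config(default_config()))
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  user <- tryCatch({
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else stop_config("unsupported config format: .%s", ext)
  }, error = function(e) stop_config("failed to parse %s: %s", path,
                                     conditionMessage(e)))
  validate_config(merge_config(default_config(), user))
}

#' Save a configuration
#'
#' @param cfg configuration list.
#' @param path output `.yaml` or `.json` path.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

# reproducible hash of a configuration (canonical JSON -> md5)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
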