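#' Maternal input profiles on an AP grid
#'
#' Container for the four maternal regulator profiles (Bcd, Cad, Tll, Hkb)
#' sampled on an [axis_grid()]. Profiles are static in time by default; a
#' time-varying field can be supplied as a function of time (minutes on the
#' gastrulation clock) returning the 4 x n_bins matrix.
#'
#' @param grid an [axis_grid()].
#' @param profiles 4 x n_bins numeric matrix with rows `bcd, cad, tll, hkb`
#'   (all values >= 0), or a `function(t)` returning such a matrix.
#' @return an object of class `maternal_field`.
#' @export
maternal_field <- function(grid, profiles) {
  stopifnot(inherits(grid, "axis_grid"))
  if (!is.function(profiles)) {
    profiles <- as.matrix(profiles)
    if (!all(dim(profiles) == c(4L, grid$n_bins)))
      stop_invalid("profiles must be 4 x n_bins (got %d x %d)",
                   nrow(profiles), ncol(profiles))
    if (any(!is.finite(profiles)) || any(profiles < 0))
      stop_invalid("maternal profiles must be finite and >= 0")
    rownames(profiles) <- MATERNALS
  }
  structure(list(grid = grid, profiles = profiles), class = "maternal_field")
}

# evaluate the maternal profiles at time t (minutes)
maternal_at <- function(field, t) {
  if (is.function(field$profiles)) {
    m <- field$profiles(t)
    rownames(m) <- MATERNALS
    m
  } else field$profiles
}

#' @export
print.maternal_field <- function(x, ...) {
  kind <- if (is.function(x$profiles)) "time-varying" else "static"
  cat(sprintf("<maternal_field> %s, %d bins (bcd, cad, tll, hkb)\n",
              kind, x$grid$n_bins))
  invisible(x)
}

#' Default synthetic maternal input profiles
#'
#' Builds the four maternal regulator profiles used throughout the package:
#' an exponential Bcd gradient decaying from the anterior pole with the
#' stated length scale (around 80 um in vivo), a logistic posterior Cad
#' ramp, a posterior terminal Tll ramp and Hkb bumps at both poles. All
#' profiles lie in \[0, 1\]. The Cad/Tll/Hkb shapes are smooth synthetic
#' stand-ins chosen to give the circuit the posterior and terminal
#' repression it needs; only Bcd has a quantitatively specified form,
#' `bcd(x) = exp(-(100 - x) * L / (100 * length_scale))`.
#'
#' @param grid an [axis_grid()].
#' @param length_scale Bcd exponential length scale in micrometres
#'   (default 80).
#' @param seed unused for the default (deterministic) shapes; accepted so
#'   all generators share a signature.
#' @return a [maternal_field()].
#' @export
#' @examples
#' mf <- make_maternal_inputs(axis_grid(100))
#' mf$profiles["bcd", 100]  # ~1 at the anterior pole
make_maternal_inputs <- function(grid, length_scale = 80, seed = NULL) {
  stopifnot(inherits(grid, "axis_grid"))
  if (!is_scalar_number(length_scale) || length_scale <= 0)
    stop_invalid("length_scale must be > 0")
  x <- grid$el
  bcd <- exp(-anterior_distance_um(x, grid$embryo_length) / length_scale)
  cad <- 1 / (1 + exp((x - 42) / 4))
  tll <- 1 / (1 + exp((x - 35) / 3))
  hkb <- pmin(1, exp(-x / 5) + exp(-(100 - x) / 5))
  maternal_field(grid, rbind(bcd = bcd, cad = cad, tll = tll, hkb = hkb))
}
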