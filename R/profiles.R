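#' Expression profile along the AP axis
#'
#' The common currency of boundary calling and gradient fitting: intensity
#' (arbitrary units) versus AP position in %EL (anterior = 100). Missing
#' bins are allowed as NA values.
#'
#' @param positions numeric vector of %EL positions, strictly increasing.
#' @param values numeric intensities (NA marks empty bins).
#' @param normalization one of "none", "peak", "posterior_peak".
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(positions, values, normalization = "none") {
  if (length(positions) != length(values))
    stop_invalid("positions and values must have equal length")
  if (any(!is.finite(positions)) || any(diff(positions) <= 0))
    stop_invalid("positions must be finite and strictly increasing")
  if (any(positions < 0 | positions > 100))
    stop_invalid("positions must lie in [0, 100] %%EL")
  normalization <- match.arg(normalization, c("none", "peak", "posterior_peak"))
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 normalization = normalization),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d bins, %g-%g %%EL, normalization: %s\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$normalization))
  invisible(x)
}

#' @export
plot.expression_profile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "l", lwd = 2,
                 xlab = "AP position (%EL, anterior = 100)",
                 ylab = "intensity (a.u.)", xlim = c(100, 0), ...)
  invisible(x)
}

#' Normalise an expression profile
#'
#' Either to its global peak or, as done for Hb, to the peak value of the
#' posterior domain. Normalising an already normalised profile is a no-op.
#'
#' @param profile an [expression_profile()].
#' @param method "peak" or "posterior_peak".
#' @param posterior_window %EL window defining the posterior domain used by
#'   `posterior_peak` (default 0-40 %EL).
#' @return normalised [expression_profile()].
#' @export
normalize_profile <- function(profile, method = c("peak", "posterior_peak"),
                              posterior_window = c(0, 40)) {
  stopifnot(inherits(profile, "expression_profile"))
  method <- match.arg(method)
  if (profile$normalization == method) return(profile)
  ref <- if (method == "peak") {
    max(profile$values, na.rm = TRUE)
  } else {
    sel <- profile$positions >= posterior_window[1] &
      profile$positions <= posterior_window[2]
    if (!any(sel) || all(is.na(profile$values[sel])))
      stop_domain("no data in the posterior window")
    max(profile$values[sel], na.rm = TRUE)
  }
  if (!is.finite(ref) || ref <= 0) stop_domain("non-positive peak; cannot normalise")
  expression_profile(profile$positions, profile$values / ref, method)
}

#' Bin nuclear intensities into an AP profile
#'
#' Nuclei are binned into spatial steps of `bin_width` micrometres along
#' the AP axis (measured from the posterior pole) and averaged per bin.
#' Empty bins are reported as NA, not zero. For tabular input the
#' background is a scalar already subtracted from the image (morphological
#' opening upstream) or supplied here.
#'
#' @param nuclei data frame with columns `position_um` (distance from the
#'   posterior pole) and `intensity`; an `el` column is accepted in place
#'   of `position_um`.
#' @param bin_width bin size in micrometres (default 5).
#' @param embryo_length egg length in micrometres (default 500).
#' @param background scalar background intensity subtracted before binning
#'   (default 0).
#' @return an [expression_profile()] with bin-centre positions in %EL.
#' @export
extract_profile <- function(nuclei, bin_width = 5, embryo_length = 500,
                            background = 0) {
  nuclei <- as.data.frame(nuclei)
  if (!nrow(nuclei)) stop_invalid("need at least one nucleus")
  if (is.null(nuclei$position_um)) {
    if (is.null(nuclei$el)) stop_invalid("nuclei need a position_um or el column")
    nuclei$position_um <- nuclei$el / 100 * embryo_length
  }
  check_finite(nuclei$position_um, "position_um")
  check_finite(nuclei$intensity, "intensity")
  if (!is_scalar_number(bin_width) || bin_width <= 0)
    stop_invalid("bin_width must be > 0")
  n_bins <- ceiling(embryo_length / bin_width)
  idx <- pmin(floor(nuclei$position_um / bin_width), n_bins - 1L) + 1L
  vals <- rep(NA_real_, n_bins)
  agg <- tapply(nuclei$intensity - background, idx, mean)
  vals[as.integer(names(agg))] <- agg
  centers_um <- (seq_len(n_bins) - 0.5) * bin_width
  expression_profile(centers_um / embryo_length * 100, vals)
}

#' Fit an exponential gradient
#'
#' Least-squares fit of `value(x) = amplitude * exp(-d(x)/length_scale) +
#' offset` where `d(x)` is the distance from the anterior pole in
#' micrometres. This is the model used for the Bcd gradient, whose in vivo
#' length scale is around 80 um. The fit uses Levenberg-Marquardt with a
#' deterministic initialisation (amplitude = max - min, offset = min,
#' length_scale = embryo_length / 6) so results are reproducible.
#'
#' @param profile an [expression_profile()].
#' @param embryo_length egg length in micrometres.
#' @param include_offset fit the additive offset term (default TRUE); with
#'   FALSE the offset is fixed at zero.
#' @return object of class `exp_fit` with fields `amplitude`,
#'   `length_scale` (um), `offset` and `rms_residual`.
#' @export
#' @examples
#' x <- seq(1, 99, by = 2)
#' p <- expression_profile(x, exp(-(100 - x) * 5 / 80))
#' fit_exponential(p, 500)$length_scale  # 80
fit_exponential <- function(profile, embryo_length = 500, include_offset = TRUE) {
  stopifnot(inherits(profile, "expression_profile"))
  keep <- is.finite(profile$values)
  d <- anterior_distance_um(profile$positions[keep], embryo_length)
  y <- profile$values[keep]
  if (length(y) < 3L) stop_invalid("need at least 3 finite bins to fit")
  if (stats::sd(y) == 0)
    stop_fit("constant profile: length scale unidentifiable")
  start <- list(A = max(y) - min(y), ell = embryo_length / 6)
  fit <- tryCatch({
    if (include_offset) {
      minpack.lm::nlsLM(y ~ A * exp(-d / ell) + C,
                        start = c(start, list(C = min(y))),
                        lower = c(A = -Inf, ell = 1e-6, C = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-d / ell), start = start,
                        lower = c(A = -Inf, ell = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) stop_fit("exponential fit failed: %s", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]),
                 length_scale = unname(cf["ell"]),
                 offset = if (include_offset) unname(cf["C"]) else 0,
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(y)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> amplitude %.4g, length scale %.4g um, offset %.4g (rms %.3g, n = %d)\n",
              x$amplitude, x$length_scale, x$offset, x$rms_residual, x$n))
  invisible(x)
}

#' Half-maximum boundary position
#'
#' Finds the AP position where the profile crosses half of its domain peak
#' on the requested flank, linearly interpolated between bins. The
#' "anterior" boundary is the crossing nearer the anterior pole
#' (100 %EL); the "posterior" boundary the crossing nearer 0 %EL. The peak
#' is the maximum of the profile restricted to the stated domain window.
#'
#' @param profile an [expression_profile()].
#' @param side "anterior" or "posterior".
#' @param domain `c(lo, hi)` %EL window containing the expression domain.
#' @return boundary position in %EL.
#' @export
#' @examples
#' ramp <- expression_profile(seq(40, 60, 1), seq(0, 1, length.out = 21))
#' boundary_position(ramp, "posterior", c(40, 60))  # 50
boundary_position <- function(profile, side = c("anterior", "posterior"),
                              domain = c(0, 100)) {
  stopifnot(inherits(profile, "expression_profile"))
  side <- match.arg(side)
  sel <- profile$positions >= domain[1] & profile$positions <= domain[2] &
    is.finite(profile$values)
  x <- profile$positions[sel]; y <- profile$values[sel]
  if (length(x) < 2L) stop_domain("fewer than 2 finite bins in domain [%g, %g]",
                                  domain[1], domain[2])
  peak <- max(y)
  if (peak <= 0) stop_domain("no positive peak in domain [%g, %g]",
                             domain[1], domain[2])
  half <- peak / 2
  ipk <- which.max(y)
  if (side == "anterior") {
    # walk from the peak towards the anterior pole (increasing %EL)
    idx <- seq(ipk, length(x))
  } else {
    idx <- seq(ipk, 1L)
  }
  yy <- y[idx]; xx <- x[idx]
  below <- which(yy < half)
  if (!length(below))
    stop_domain("profile does not cross half-maximum on the %s flank in [%g, %g]",
                side, domain[1], domain[2])
  j <- below[1L]
  # linear interpolation between the last point above and first below half
  x1 <- xx[j - 1L]; y1 <- yy[j - 1L]; x2 <- xx[j]; y2 <- yy[j]
  unname(x1 + (half - y1) * (x2 - x1) / (y2 - y1))
}

#' ChIP-qPCR percent-input normalisation
#'
#' `percent_input` implements the percent-input method,
#' `100 * 2^(adjusted_input - Ct(IP))`. The adjusted input Ct corrects the
#' input-control Ct for the fraction of material used
#' (`adjusted = Ct(input) - log2(100 / input_percent)`; the assays use a 2%
#' input control). `relative_percent_input` expresses an illuminated
#' sample relative to its dark control.
#'
#' @param ct_ip Ct value of the immunoprecipitated sample.
#' @param adjusted_input adjusted input Ct (see [adjusted_input_ct()]).
#' @return percent of input recovered (100 means all of it).
#' @export
#' @examples
#' percent_input(25, 25)      # 100
#' percent_input(26, 25)      # 50
percent_input <- function(ct_ip, adjusted_input) {
  check_finite(ct_ip, "ct_ip"); check_finite(adjusted_input, "adjusted_input")
  100 * 2^(adjusted_input - ct_ip)
}

#' @rdname percent_input
#' @param ct_input raw Ct of the input control.
#' @param input_percent percentage of material in the input control
#'   (default 2).
#' @export
adjusted_input_ct <- function(ct_input, input_percent = 2) {
  check_finite(ct_input, "ct_input")
  if (!is_scalar_number(input_percent) || input_percent <= 0 || input_percent > 100)
    stop_invalid("input_percent must be in (0, 100]")
  ct_input - log2(100 / input_percent)
}

#' @rdname percent_input
#' @param percent_light,percent_dark percent-input values of the
#'   illuminated sample and its dark control.
#' @export
relative_percent_input <- function(percent_light, percent_dark) {
  check_finite(percent_light, "percent_light")
  check_finite(percent_dark, "percent_dark")
  percent_light / percent_dark
}
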