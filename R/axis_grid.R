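#' Spatial grid along the anterior-posterior axis
#'
#' Discretises the AP axis of the embryo into equal bins of percent egg
#' length (%EL). Throughout the package the coordinate convention is the one
#' used for region labels such as "100-75 %EL": position 100 %EL is the
#' ANTERIOR pole and 0 %EL the posterior pole.
#'
#' @param n_bins integer number of spatial bins (>= 10).
#' @param bin_width width of one bin in %EL; `n_bins * bin_width` must equal
#'   100 %EL.
#' @param embryo_length physical egg length in micrometres (default 500).
#'
#' @return An object of class `axis_grid` with fields `n_bins`, `bin_width`,
#'   `embryo_length` and `el` (bin-centre positions in %EL, ascending, i.e.
#'   posterior first).
#' @export
#' @examples
#' g <- axis_grid(100)
#' range(g$el)
axis_grid <- function(n_bins = 100L, bin_width = 100 / n_bins,
                      embryo_length = 500) {
  if (!is_scalar_number(n_bins) || n_bins < 10 || n_bins != round(n_bins))
    stop_invalid("n_bins must be an integer >= 10")
  if (!is_scalar_number(bin_width) || abs(n_bins * bin_width - 100) > 1e-9)
    stop_invalid("n_bins * bin_width must equal 100 %%EL")
  if (!is_scalar_number(embryo_length) || embryo_length <= 0)
    stop_invalid("embryo_length must be > 0")
  n_bins <- as.integer(n_bins)
  structure(list(
    n_bins        = n_bins,
    bin_width     = bin_width,
    embryo_length = embryo_length,
    el            = (seq_len(n_bins) - 0.5) * bin_width
  ), class = "axis_grid")
}

#' @export
print.axis_grid <- function(x, ...) {
  cat(sprintf("<axis_grid> %d bins x %.3g %%EL (embryo %g um; 100 %%EL = anterior)\n",
              x$n_bins, x$bin_width, x$embryo_length))
  invisible(x)
}

# distance from the anterior pole in micrometres for positions in %EL
anterior_distance_um <- function(el, embryo_length) {
  (100 - el) / 100 * embryo_length
}
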