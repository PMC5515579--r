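#' Developmental timeline of the syncytial blastoderm
#'
#' Encodes the gastrulation-anchored clock used for all illumination
#' scenarios: time 0 is the onset of gastrulation and earlier events carry
#' negative times. The last nuclear cycle (n.c. 14) lasts about 45 min,
#' n.c. 13 lasts 15 min and n.c. 10-12 together about 30 min; the whole
#' blastoderm stage (fertilisation to gastrulation) spans 2.5 h.
#'
#' @return an object of class `dev_timeline` with the interval of each
#'   epoch in minutes.
#' @export
#' @examples
#' dev_timeline()$nc14  # c(-45, 0)
dev_timeline <- function() {
  structure(list(
    gastrulation_t   = 0,
    nc14             = c(-45, 0),
    nc13             = c(-60, -45),
    nc10_12          = c(-90, -60),
    blastoderm_total = 150
  ), class = "dev_timeline")
}

#' @export
print.dev_timeline <- function(x, ...) {
  cat("<dev_timeline> minutes on the gastrulation clock (t = 0 at gastrulation)\n")
  cat(sprintf("  n.c. 14:    [%g, %g]\n", x$nc14[1], x$nc14[2]))
  cat(sprintf("  n.c. 13:    [%g, %g]\n", x$nc13[1], x$nc13[2]))
  cat(sprintf("  n.c. 10-12: [%g, %g]\n", x$nc10_12[1], x$nc10_12[2]))
  cat(sprintf("  blastoderm: %g min total\n", x$blastoderm_total))
  invisible(x)
}

#' Illumination scenario
#'
#' A set of time windows during which Bcd transcriptional activity is
#' switched off (the optogenetic "light on" state). Windows are half-open
#' `[start, end)` intervals in minutes on the gastrulation clock; they must
#' be sorted, non-overlapping, and end at or before gastrulation (t = 0).
#'
#' @param id scenario label (the scenario battery uses "1".."8").
#' @param windows list of numeric `c(start, end)` pairs; empty for the dark
#'   control.
#' @return an object of class `illumination_scenario`.
#' @export
#' @examples
#' illumination_scenario("5", list(c(-60, 0)))
illumination_scenario <- function(id, windows = list()) {
  if (length(windows) && is.numeric(windows)) windows <- list(windows)
  for (w in windows) {
    if (length(w) != 2L || any(!is.finite(w)))
      stop_invalid("each window must be a finite c(start, end) pair")
    if (w[1] >= w[2]) stop_invalid("window start must precede its end")
    if (w[2] > 0) stop_invalid("windows must end at or before gastrulation (t = 0)")
  }
  if (length(windows) > 1L) {
    starts <- vapply(windows, `[`, numeric(1), 1L)
    ends   <- vapply(windows, `[`, numeric(1), 2L)
    o <- order(starts)
    windows <- windows[o]
    if (any(ends[o][-length(o)] > starts[o][-1L]))
      stop_invalid("illumination windows must not overlap")
  }
  structure(list(id = as.character(id), windows = windows),
            class = "illumination_scenario")
}

#' @export
print.illumination_scenario <- function(x, ...) {
  if (!length(x$windows)) {
    cat(sprintf("<scenario %s> dark control (no illumination)\n", x$id))
  } else {
    w <- paste(vapply(x$windows, function(z) sprintf("[%g, %g)", z[1], z[2]),
                      character(1)), collapse = ", ")
    cat(sprintf("<scenario %s> Bcd off during %s min\n", x$id, w))
  }
  invisible(x)
}

#' Default scenario battery
#'
#' The eight illumination windows of the experimental battery, on the
#' gastrulation clock: (1) dark control; (2) last 20 min; (3) last 30 min;
#' (4) n.c. 14; (5) from n.c. 13 onward; (6) illumination until -30 min
#' then dark recovery; (7) illumination until n.c. 13 then recovery;
#' (8) a pre-blastoderm window ending before n.c. 10. Only some endpoints
#' are fixed by the timeline; the remainder are package defaults and can be
#' overridden through the shared configuration.
#'
#' @param ids which scenarios to return (default all eight).
#' @return named list of [illumination_scenario()] objects.
#' @export
default_scenarios <- function(ids = as.character(1:8)) {
  all <- list(
    `1` = illumination_scenario("1", list()),
    `2` = illumination_scenario("2", list(c(-20, 0))),
    `3` = illumination_scenario("3", list(c(-30, 0))),
    `4` = illumination_scenario("4", list(c(-45, 0))),
    `5` = illumination_scenario("5", list(c(-60, 0))),
    `6` = illumination_scenario("6", list(c(-90, -30))),
    `7` = illumination_scenario("7", list(c(-90, -60))),
    `8` = illumination_scenario("8", list(c(-120, -90)))
  )
  missing <- setdiff(as.character(ids), names(all))
  if (length(missing))
    stop_invalid("unknown scenario id(s): %s", paste(missing, collapse = ", "))
  all[as.character(ids)]
}

#' Bcd activity mask for a scenario
#'
#' For each query time, reports whether Bcd transcriptional activity is ON
#' (TRUE, dark) or OFF (FALSE, illuminated). A time `t` is illuminated iff
#' it falls inside some half-open window `[start, end)` of the scenario.
#'
#' @param scenario an [illumination_scenario()].
#' @param times sorted numeric vector of times in minutes.
#' @return logical vector: `bcd_active` per time.
#' @export
#' @examples
#' sc <- illumination_scenario("3", list(c(-30, 0)))
#' scenario_to_mask(sc, c(-45, -10))  # TRUE, FALSE
scenario_to_mask <- function(scenario, times) {
  stopifnot(inherits(scenario, "illumination_scenario"))
  if (!is.numeric(times) || any(!is.finite(times)))
    stop_invalid("times must be finite numeric")
  if (is.unsorted(times)) stop_invalid("times must be sorted")
  active <- rep(TRUE, length(times))
  for (w in scenario$windows)
    active[times >= w[1] & times < w[2]] <- FALSE
  active
}

# earliest illumination start, or NULL for a dark scenario
first_window_start <- function(scenario) {
  if (!length(scenario$windows)) NULL
  else min(vapply(scenario$windows, `[`, numeric(1), 1L))
}
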