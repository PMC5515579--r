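#' Run a battery of illumination scenarios
#'
#' Simulates the circuit once per scenario on a shared grid and time base.
#' The battery must contain the dark control (a scenario with no
#' illumination windows); it is always run and returned first.
#'
#' @param params a [circuit_params()].
#' @param maternal a [maternal_field()].
#' @param scenarios named list of [illumination_scenario()] objects, e.g.
#'   `default_scenarios(1:6)`.
#' @param ... further arguments passed to [simulate_circuit()].
#' @return named list of `circuit_trajectory` objects, dark control first.
#' @export
run_scenarios <- function(params, maternal, scenarios = default_scenarios(1:6),
                          ...) {
  if (!length(scenarios)) stop_invalid("empty scenario list")
  n_win <- vapply(scenarios, function(s) length(s$windows), integer(1))
  if (!any(n_win == 0L))
    stop_invalid("the battery must include the dark control (scenario without windows)")
  ord <- order(n_win != 0L)  # dark control(s) first, otherwise stable
  scenarios <- scenarios[ord]
  out <- vector("list", length(scenarios))
  names(out) <- vapply(scenarios, `[[`, character(1), "id")
  for (i in seq_along(scenarios)) {
    out[[i]] <- tryCatch(
      simulate_circuit(params, maternal, scenario = scenarios[[i]], ...),
      error = function(e) stop_numerical("scenario %s failed: %s",
                                         scenarios[[i]]$id, conditionMessage(e)))
  }
  out
}

#' Default gene-domain windows used for boundary calls
#'
#' %EL windows bracketing each scored expression domain: the central Kr
#' domain (printed extent 58-45 %EL), the posterior Kni domain (45-37
#' %EL), the anterior Hb domain and the anterior Gt and Kni territories.
#'
#' @return named list of `c(lo, hi)` windows.
#' @export
default_domains <- function() {
  list(kr       = c(30, 72),
       kni_post = c(25, 55),
       hb_ant   = c(30, 100),
       gt_ant   = c(55, 100),
       kni_ant  = c(85, 100))
}

#' Score the five perturbation criteria
#'
#' Compares a perturbed end-state against the dark control and scores the
#' five qualitative observations used to assess model parameter sets:
#' (i) anterior shift of the Kr anterior boundary; (ii) anterior shift of
#' the anterior boundary of the posterior Kni domain; (iii) reduction of
#' anterior Kni expression; (iv) reduction of anterior Gt expression;
#' (v) anterior shift of the posterior boundary of the anterior Hb domain
#' AND reduction of anterior Hb expression (conjunctive). An "anterior
#' shift" is an increase in %EL position. Shift criteria require the
#' boundary to exist in the control (otherwise a domain error is raised);
#' a boundary that disappears under perturbation yields NA and a FALSE
#' criterion. Level criteria compare domain peaks and are defined even
#' without a half-maximum crossing.
#'
#' @param control,perturbed 4 x n_bins end-state matrices (rows
#'   `hb, gt, kr, kni`), e.g. from [end_state()].
#' @param grid the shared [axis_grid()].
#' @param thresholds list with `shift_el` (minimum anterior shift in %EL,
#'   default 1) and `level_drop` (minimum fractional reduction of the
#'   control domain peak, default 0.10).
#' @param domains gene-domain windows, see [default_domains()].
#' @param scenario_id label recorded in the report.
#' @return object of class `criterion_report`: list with `scenario_id`,
#'   `measures` (named numeric), `criteria` (named logical `i`..`v`),
#'   `n_met` and the thresholds used.
#' @export
score_criteria <- function(control, perturbed, grid,
                           thresholds = list(shift_el = 1, level_drop = 0.10),
                           domains = default_domains(),
                           scenario_id = NA_character_) {
  control <- as.matrix(control); perturbed <- as.matrix(perturbed)
  if (!all(dim(control) == dim(perturbed)) || ncol(control) != grid$n_bins)
    stop_invalid("control and perturbed must share the grid")
  prof <- function(state, gene) expression_profile(grid$el, state[gene, ])
  bnd <- function(state, gene, side, dom) {
    boundary_position(prof(state, gene), side, dom)
  }
  bnd_try <- function(state, gene, side, dom) {
    tryCatch(bnd(state, gene, side, dom), bcdecode_domain_error = function(e) NA_real_)
  }
  peak_level <- function(state, gene, dom) {
    v <- state[gene, grid$el >= dom[1] & grid$el <= dom[2]]
    if (!length(v)) 0 else max(v)
  }
  # shifts: control boundary must exist (error otherwise, per contract)
  shifts <- c(
    kr_anterior  = bnd_try(perturbed, "kr", "anterior", domains$kr) -
      bnd(control, "kr", "anterior", domains$kr),
    kr_posterior = bnd_try(perturbed, "kr", "posterior", domains$kr) -
      bnd(control, "kr", "posterior", domains$kr),
    kni_anterior = bnd_try(perturbed, "kni", "anterior", domains$kni_post) -
      bnd(control, "kni", "anterior", domains$kni_post),
    hb_posterior = bnd_try(perturbed, "hb", "posterior", domains$hb_ant) -
      bnd(control, "hb", "posterior", domains$hb_ant)
  )
  drop_frac <- function(gene, dom) {
    p0 <- peak_level(control, gene, dom)
    if (p0 <= 0) return(0)  # nothing expressed in the control: no reduction
    (p0 - peak_level(perturbed, gene, dom)) / p0
  }
  drops <- c(kni_ant = drop_frac("kni", domains$kni_ant),
             gt_ant  = drop_frac("gt", domains$gt_ant),
             hb_ant  = drop_frac("hb", domains$hb_ant))
  sh <- thresholds$shift_el %||% 1
  lv <- thresholds$level_drop %||% 0.10
  criteria <- c(
    i   = isTRUE(shifts[["kr_anterior"]] >= sh),
    ii  = isTRUE(shifts[["kni_anterior"]] >= sh),
    iii = isTRUE(drops[["kni_ant"]] >= lv),
    iv  = isTRUE(drops[["gt_ant"]] >= lv),
    v   = isTRUE(shifts[["hb_posterior"]] >= sh) && isTRUE(drops[["hb_ant"]] >= lv)
  )
  structure(list(scenario_id = scenario_id,
                 measures = c(shifts, drops),
                 criteria = criteria,
                 n_met = sum(criteria),
                 thresholds = list(shift_el = sh, level_drop = lv)),
            class = "criterion_report")
}

#' @export
print.criterion_report <- function(x, ...) {
  cat(sprintf("<criterion_report> scenario %s: %d of 5 criteria met\n",
              x$scenario_id, x$n_met))
  lab <- c(i = "Kr anterior boundary shift", ii = "Kni anterior boundary shift",
           iii = "anterior Kni reduction", iv = "anterior Gt reduction",
           v = "Hb posterior shift + reduction")
  for (k in names(x$criteria))
    cat(sprintf("  (%s) %-32s %s\n", k, lab[[k]],
                if (x$criteria[[k]]) "yes" else "no"))
  cat("measures (%EL shifts / fractional drops):\n")
  print(round(x$measures, 3))
  invisible(x)
}

#' Convert criterion reports to a data frame
#'
#' @param reports list of `criterion_report` objects.
#' @return data frame with one row per report: scenario, the measured
#'   quantities, the per-criterion booleans and the count met.
#' @export
criteria_table <- function(reports) {
  if (inherits(reports, "criterion_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    cbind(data.frame(scenario = r$scenario_id),
          as.data.frame(as.list(r$measures)),
          as.data.frame(as.list(stats::setNames(r$criteria,
                                                paste0("crit_", names(r$criteria))))),
          data.frame(n_met = r$n_met))
  }))
}

#' Select parameter sets agreeing with enough criteria
#'
#' @param scores data frame with columns `id` and `n_met` (as produced by
#'   scoring each ensemble member), or a list of such report rows.
#' @param min_criteria minimum number of criteria met (default 3, the
#'   "at least three of the above criteria" rule).
#' @return character vector of selected ids, in input order.
#' @export
select_subset <- function(scores, min_criteria = 3) {
  scores <- as.data.frame(scores)
  if (!nrow(scores)) stop_invalid("empty score table")
  if (is.null(scores$id) || is.null(scores$n_met))
    stop_invalid("scores need columns id and n_met")
  as.character(scores$id[scores$n_met >= min_criteria])
}

#' Parameter-subset z-scores
#'
#' For every scalar circuit parameter, measures how far the mean over a
#' selected subset of parameter sets deviates from the mean over the full
#' ensemble: `z_i = (<p_i^all> - <p_i^subset>) / (sigma_i^all / sqrt(n))`,
#' with `sigma` the sample standard deviation over the full ensemble and
#' `n` the full-ensemble size. Positive z therefore means the subset mean
#' lies BELOW the ensemble mean. Parameters constant across the ensemble
#' (`sigma = 0`) get z = 0 and are flagged degenerate. The denominator
#' convention can be switched to `sigma / n`.
#'
#' @param all_params named list of [circuit_params()] objects (the full
#'   ensemble).
#' @param subset_ids names of the selected subset (non-empty, all present
#'   in `all_params`).
#' @param denominator "sqrt_n" (default) or "n".
#' @return data frame with columns `parameter`, `z`, `degenerate`.
#' @export
#' @examples
#' # three one-parameter "ensembles" via R: ensemble {1,2,3}, subset {3}
#' # gives z = (2 - 3)/(1/sqrt(3)) = -sqrt(3)
param_zscore <- function(all_params, subset_ids, denominator = c("sqrt_n", "n")) {
  denominator <- match.arg(denominator)
  if (!length(all_params)) stop_invalid("empty ensemble")
  if (is.null(names(all_params)))
    names(all_params) <- as.character(seq_along(all_params))
  subset_ids <- as.character(subset_ids)
  if (!length(subset_ids)) stop_invalid("empty subset")
  if (!all(subset_ids %in% names(all_params)))
    stop_invalid("subset ids not contained in the ensemble")
  mat <- vapply(all_params, as_param_vector,
                numeric(length(as_param_vector(all_params[[1]]))))
  n <- ncol(mat)
  mean_all <- rowMeans(mat)
  mean_sub <- rowMeans(mat[, subset_ids, drop = FALSE])
  sd_all <- apply(mat, 1L, stats::sd)
  denom <- sd_all / if (denominator == "sqrt_n") sqrt(n) else n
  z <- ifelse(sd_all == 0, 0, (mean_all - mean_sub) / denom)
  data.frame(parameter = rownames(mat), z = unname(z),
             degenerate = unname(sd_all == 0), row.names = NULL)
}

#' Reshape interaction z-scores to the regulator x gene layout
#'
#' Extracts the `T` and `M` entries from a [param_zscore()] table and
#' arranges them as a matrix with one row per interacting element (Hb
#' monomer, Hb dimer, Gt, Kr, Kni, Bcd, Cad, Tll, Hkb) and one column per
#' target gene, convenient for export and heatmaps.
#'
#' @param ztab data frame from [param_zscore()].
#' @return 9 x 4 numeric matrix.
#' @export
zscore_matrix <- function(ztab) {
  rows <- c(REGULATORS, MATERNALS)
  out <- matrix(NA_real_, length(rows), length(GENES),
                dimnames = list(rows, GENES))
  for (g in GENES) {
    for (r in REGULATORS)
      out[r, g] <- ztab$z[ztab$parameter == sprintf("T[%s,%s]", g, r)]
    for (m in MATERNALS)
      out[m, g] <- ztab$z[ztab$parameter == sprintf("M[%s,%s]", g, m)]
  }
  out
}
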