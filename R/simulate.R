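#' Regulatory input of each gap gene
#'
#' Computes the summed regulatory input `u_a(x)` for every gene and spatial
#' bin: gap-gene cross-regulation (with Hb split into monomer and dimer via
#' [hb_partition()]) plus maternal input plus the basal offset. When
#' `bcd_active` is FALSE the Bcd column contributes exactly zero regardless
#' of the stored weights, which is how optogenetic Bcd shutdown enters the
#' model.
#'
#' @param state 4 x n_bins matrix of gene concentrations (rows
#'   `hb, gt, kr, kni`).
#' @param maternal_mat 4 x n_bins matrix of maternal profiles (rows
#'   `bcd, cad, tll, hkb`), e.g. `maternal_field$profiles`.
#' @param params a [circuit_params()] object.
#' @param bcd_active logical; FALSE while illuminated.
#' @return 4 x n_bins matrix of inputs `u`.
#' @export
regulatory_input <- function(state, maternal_mat, params, bcd_active = TRUE) {
  stopifnot(inherits(params, "circuit_params"))
  state <- as.matrix(state); maternal_mat <- as.matrix(maternal_mat)
  if (nrow(state) != 4L || nrow(maternal_mat) != 4L ||
      ncol(state) != ncol(maternal_mat))
    stop_invalid("state and maternal profiles must be 4 x n_bins with matching n_bins")
  part <- hb_partition(pmax(state[1L, ], 0), params$K_hb)
  reg <- rbind(hb_m = part$monomer, hb_d = part$dimer,
               gt = state[2L, ], kr = state[3L, ], kni = state[4L, ])
  M <- params$M
  if (!isTRUE(bcd_active)) M[, "bcd"] <- 0
  params$T %*% reg + M %*% maternal_mat + params$h
}

#' Simulate the gap-gene circuit
#'
#' Integrates the reaction-diffusion dynamics
#' `dv_a/dt = R_a * Phi(u_a) - lam_a * v_a + D_a * d2v_a/dx2`
#' on a 1-D AP axis with no-flux boundaries. The production/decay part is
#' advanced with an exponential (ETD1) update - exact for pure first-order
#' decay and for the constant-input fixed point `R * Phi(u) / lam` - while
#' diffusion uses an explicit central-difference step, subject to the usual
#' stability bound. `u_a` comes from [regulatory_input()] with
#' `bcd_active = TRUE` except while the scenario illuminates the embryo, in
#' which case all Bcd weights are zero (the switch is instantaneous).
#'
#' @param params a [circuit_params()].
#' @param maternal a [maternal_field()] on the same grid.
#' @param scenario an [illumination_scenario()], or NULL for the dark
#'   control.
#' @param grid an [axis_grid()]; defaults to the maternal field's grid.
#' @param t_start,t_end simulation window in minutes on the gastrulation
#'   clock; `t_start < t_end <= 0`. The default window `[-90, 0]` covers
#'   n.c. 10 through gastrulation.
#' @param dt Euler step in minutes; must satisfy the diffusion stability
#'   bound `dt < bin_width^2 / (2 * max(D))`.
#' @param v0 4 x n_bins initial condition (>= 0); defaults to
#'   [default_initial_state()].
#' @param t_out times at which states are stored (defaults to every minute).
#' @param sigmoid activation function, by default [circuit_sigmoid()].
#' @return an object of class `circuit_trajectory`: list with `times`,
#'   `states` (4 x n_bins x length(times) array), `grid`, `params_id` and
#'   `scenario_id`.
#' @export
#' @examples
#' grid <- axis_grid(50)
#' mat <- make_maternal_inputs(grid)
#' par <- make_reference_circuit()
#' tr <- simulate_circuit(par, mat, grid = grid, t_out = c(-45, 0))
#' dim(tr$states)
simulate_circuit <- function(params, maternal, scenario = NULL, grid = maternal$grid,
                             t_start = -90, t_end = 0, dt = 0.01,
                             v0 = default_initial_state(params, maternal, grid),
                             t_out = seq(ceiling(t_start), floor(t_end), by = 1),
                             sigmoid = circuit_sigmoid) {
  stopifnot(inherits(params, "circuit_params"), inherits(maternal, "maternal_field"),
            inherits(grid, "axis_grid"))
  if (is.null(scenario)) scenario <- illumination_scenario("dark", list())
  if (!is_scalar_number(t_start) || !is_scalar_number(t_end) ||
      t_start >= t_end || t_end > 0)
    stop_invalid("need t_start < t_end <= 0 (minutes before gastrulation)")
  if (!is_scalar_number(dt) || dt <= 0) stop_config("dt must be > 0")
  if (max(params$D) > 0 && dt >= grid$bin_width^2 / (2 * max(params$D)))
    stop_config("dt = %g violates the diffusion stability bound %g",
                dt, grid$bin_width^2 / (2 * max(params$D)))
  v0 <- as.matrix(v0)
  if (!all(dim(v0) == c(4L, grid$n_bins)) || any(v0 < 0) || any(!is.finite(v0)))
    stop_invalid("v0 must be a finite non-negative 4 x n_bins matrix")
  t_out <- sort(unique(t_out))
  if (any(t_out < t_start - 1e-9) || any(t_out > t_end + 1e-9))
    stop_invalid("t_out must lie within [t_start, t_end]")

  n_steps <- ceiling((t_end - t_start) / dt - 1e-9)
  step_t <- t_start + dt * (0:n_steps)
  # map each requested output time to the nearest integration step
  out_idx <- vapply(t_out, function(tt) which.min(abs(step_t - tt)), integer(1))

  n <- grid$n_bins
  static_mat <- !is.function(maternal$profiles)
  g_mat <- maternal_at(maternal, step_t[1])
  Ddx2 <- params$D / grid$bin_width^2
  e_lam <- exp(-params$lam * dt)        # exact decay factor per gene
  gain <- (1 - e_lam) / params$lam      # ETD1 weight of the production term
  states <- array(NA_real_, c(4L, n, length(t_out)),
                  dimnames = list(GENES, NULL, NULL))
  v <- v0
  for (k in which(out_idx == 1L)) states[, , k] <- v

  # precompute the bcd activity per step (half-open illumination windows)
  active <- scenario_to_mask(scenario, step_t)

  for (s in seq_len(n_steps)) {
    t_now <- step_t[s]
    if (!static_mat) g_mat <- maternal_at(maternal, t_now)
    u <- regulatory_input(v, g_mat, params, bcd_active = active[s])
    prod <- params$R * sigmoid(u)
    # central-difference Laplacian; no-flux boundaries via ghost = edge bin
    lap <- v[, c(1L, 1:(n - 1L)), drop = FALSE] +
      v[, c(2:n, n), drop = FALSE] - 2 * v
    v <- v * e_lam + gain * prod + dt * Ddx2 * lap
    if (any(!is.finite(v)))
      stop_numerical("non-finite state at t = %.4f min", step_t[s + 1L])
    hit <- which(out_idx == s + 1L)
    for (k in hit) states[, , k] <- v
  }
  if (min(states, na.rm = TRUE) < -1e-9)
    stop_numerical("negative concentrations beyond tolerance")

  structure(list(times = step_t[out_idx], states = states, grid = grid,
                 params_id = params$id, scenario_id = scenario$id),
            class = "circuit_trajectory")
}

#' Default initial condition of the circuit
#'
#' Gt, Kr and Kni start at zero; Hb is initialised from a maternal-Hb-like
#' anterior profile, taken as the steady state of its own (Bcd-driven)
#' production so that maternal Hb already fills the anterior at the start
#' of the simulated window.
#'
#' @inheritParams simulate_circuit
#' @return 4 x n_bins matrix.
#' @export
default_initial_state <- function(params, maternal, grid = maternal$grid) {
  g <- maternal_at(maternal, -90)
  u_hb <- drop(params$M["hb", , drop = FALSE] %*% g) + params$h["hb"]
  hb0 <- params$R["hb"] / params$lam["hb"] * circuit_sigmoid(u_hb)
  rbind(hb = hb0, gt = 0, kr = 0, kni = numeric(grid$n_bins))
}

#' Closed-form steady state of a single gene
#'
#' For a frozen regulatory input `u` and no diffusion the rate equation has
#' the fixed point `v = R * Phi(u) / lam`; used as an analytic oracle for
#' the integrator.
#'
#' @param params a [circuit_params()].
#' @param u_const frozen total regulatory input (offset already included).
#' @param gene gene name or index.
#' @return the steady-state concentration.
#' @export
steady_state_closed_form <- function(params, u_const, gene) {
  stopifnot(inherits(params, "circuit_params"))
  if (is.character(gene)) gene <- match(gene, params$genes)
  if (is.na(gene) || gene < 1 || gene > 4) stop_invalid("unknown gene")
  if (params$lam[gene] <= 0) stop_invalid("lam must be > 0")
  unname(params$R[gene] * circuit_sigmoid(u_const) / params$lam[gene])
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> params '%s', scenario '%s'\n",
              x$params_id, x$scenario_id))
  cat(sprintf("  %d stored times in [%g, %g] min; %d bins\n",
              length(x$times), min(x$times), max(x$times), x$grid$n_bins))
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj a `circuit_trajectory`.
#' @return 4 x n_bins matrix of concentrations at the last stored time.
#' @export
end_state <- function(traj) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  traj$states[, , dim(traj$states)[3L]]
}

#' @export
as.data.frame.circuit_trajectory <- function(x, ...) {
  nt <- length(x$times); n <- x$grid$n_bins
  data.frame(
    time = rep(x$times, each = 4L * n),
    gene = rep(GENES, times = n * nt),
    bin  = rep(rep(seq_len(n), each = 4L), times = nt),
    el   = rep(rep(x$grid$el, each = 4L), times = nt),
    value = as.numeric(x$states)
  )
}

#' Write a trajectory as CSV
#'
#' Long-format CSV with columns `time` (min), `gene`, `bin`, `el` (%EL) and
#' `value` (concentration, arbitrary units).
#'
#' @param traj a `circuit_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.circuit_trajectory <- function(x, t = max(x$times), ...) {
  k <- which.min(abs(x$times - t))
  st <- x$states[, , k]
  graphics::matplot(x$grid$el, t(st), type = "l", lty = 1, lwd = 2,
                    xlab = "AP position (%EL, anterior = 100)",
                    ylab = "concentration (a.u.)",
                    main = sprintf("scenario %s, t = %g min", x$scenario_id,
                                   x$times[k]), xlim = c(100, 0), ...)
  graphics::legend("topright", legend = GENES, col = 1:4, lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}
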