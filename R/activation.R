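#' Gene-circuit activation sigmoid
#'
#' The saturating response function used for transcriptional activation in
#' the gap-gene circuit: `Phi(u) = (u / sqrt(u^2 + 1) + 1) / 2`. It maps the
#' summed regulatory input `u` to a production fraction strictly between 0
#' and 1, with `Phi(0) = 0.5` and `Phi(-u) = 1 - Phi(u)`.
#'
#' @param u numeric vector of regulatory inputs; must be finite.
#' @return numeric vector of the same shape, strictly in (0, 1).
#' @export
#' @examples
#' circuit_sigmoid(0)    # 0.5
#' circuit_sigmoid(1)    # (1/sqrt(2) + 1)/2
circuit_sigmoid <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop_invalid("sigmoid input must be finite numeric")
  (u / sqrt(u^2 + 1) + 1) / 2
}

#' Monomer/dimer partition of Hunchback
#'
#' Hunchback acts on its targets both as a monomer and as a homodimer. Given
#' a total concentration `v_total` the two forms are assumed to be at
#' mass-action equilibrium,
#' `monomer^2 / dimer = K_hb` with `monomer + 2 * dimer = v_total`,
#' which has the closed-form solution
#' `monomer = (-K_hb + sqrt(K_hb^2 + 8 * K_hb * v_total)) / 4`.
#'
#' @param v_total total Hb concentration (vectorised, >= 0).
#' @param K_hb dimer dissociation constant (> 0).
#' @return list with numeric fields `monomer` and `dimer`.
#' @export
#' @examples
#' hb_partition(2, 1)  # monomer = (sqrt(17) - 1)/4
hb_partition <- function(v_total, K_hb) {
  if (!is.numeric(v_total) || any(!is.finite(v_total)) || any(v_total < 0))
    stop_invalid("v_total must be finite and >= 0")
  if (!is_scalar_number(K_hb) || K_hb <= 0)
    stop_invalid("K_hb must be a finite scalar > 0")
  monomer <- (-K_hb + sqrt(K_hb^2 + 8 * K_hb * v_total)) / 4
  list(monomer = monomer, dimer = (v_total - monomer) / 2)
}
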