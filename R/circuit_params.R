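GENES <- c("hb", "gt", "kr", "kni")
REGULATORS <- c("hb_m", "hb_d", "gt", "kr", "kni")
MATERNALS <- c("bcd", "cad", "tll", "hkb")

#' Parameters of the gap-gene circuit
#'
#' Bundles the interaction weights and kinetic constants of the four-gene
#' gap circuit (hb, gt, kr, kni). Regulation of gene `a` at position `x` is
#' `u_a(x) = sum_b T[a, b] reg_b(x) + sum_m M[a, m] g_m(x) + h[a]`, where
#' the gap-gene regulators are `hb_m` (Hb monomer), `hb_d` (Hb dimer), `gt`,
#' `kr` and `kni`, and the maternal inputs are Bcd, Cad, Tll and Hkb. The
#' Bcd column of `M` carries the Bcd interaction weights that are set to
#' zero during illumination.
#'
#' @param T 4 x 5 matrix of gap-gene interaction weights, rows `hb, gt, kr,
#'   kni`, columns `hb_m, hb_d, gt, kr, kni` (dimensionless).
#' @param M 4 x 4 matrix of maternal-input weights, columns
#'   `bcd, cad, tll, hkb`.
#' @param h length-4 basal offsets.
#' @param R length-4 maximal production rates (concentration/min), >= 0.
#' @param lam length-4 first-order decay rates (1/min), > 0.
#' @param D length-4 diffusion coefficients (%EL^2/min), >= 0.
#' @param K_hb Hb dimer dissociation constant (> 0).
#' @param id optional provenance label.
#'
#' @return an object of class `circuit_params`.
#' @seealso [make_reference_circuit()] for the shipped reference set.
#' @export
circuit_params <- function(T, M, h, R, lam, D, K_hb, id = "custom") {
  T <- as.matrix(T); M <- as.matrix(M)
  if (!all(dim(T) == c(4L, 5L))) stop_invalid("T must be 4 x 5 (genes x regulators)")
  if (!all(dim(M) == c(4L, 4L))) stop_invalid("M must be 4 x 4 (genes x maternal inputs)")
  for (v in list(T = T, M = M, h = h, R = R, lam = lam, D = D, K_hb = K_hb))
    if (!is.numeric(v) || any(!is.finite(v))) stop_invalid("all parameter arrays must be finite")
  if (length(h) != 4L || length(R) != 4L || length(lam) != 4L || length(D) != 4L)
    stop_invalid("h, R, lam, D must have length 4")
  if (any(lam <= 0)) stop_invalid("decay rates lam must be > 0")
  if (any(R < 0)) stop_invalid("production rates R must be >= 0")
  if (any(D < 0)) stop_invalid("diffusion coefficients D must be >= 0")
  if (!is_scalar_number(K_hb) || K_hb <= 0) stop_invalid("K_hb must be > 0")
  dimnames(T) <- list(GENES, REGULATORS)
  dimnames(M) <- list(GENES, MATERNALS)
  structure(list(
    genes = GENES,
    T = T, M = M,
    h = stats::setNames(as.numeric(h), GENES),
    R = stats::setNames(as.numeric(R), GENES),
    lam = stats::setNames(as.numeric(lam), GENES),
    D = stats::setNames(as.numeric(D), GENES),
    K_hb = as.numeric(K_hb),
    id = id
  ), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> id: %s\n", x$id))
  cat("gap-gene interaction weights T (genes x regulators):\n")
  print(round(x$T, 3))
  cat("maternal-input weights M (bcd column is light-switchable):\n")
  print(round(x$M, 3))
  cat("h:   ", paste(sprintf("%s=%.3g", names(x$h), x$h), collapse = "  "), "\n")
  cat("R:   ", paste(sprintf("%s=%.3g", names(x$R), x$R), collapse = "  "), "/min\n")
  cat("lam: ", paste(sprintf("%s=%.3g", names(x$lam), x$lam), collapse = "  "), "/min\n")
  cat("D:   ", paste(sprintf("%s=%.3g", names(x$D), x$D), collapse = "  "), "%EL^2/min\n")
  cat(sprintf("K_hb: %.3g\n", x$K_hb))
  invisible(x)
}

#' Flatten circuit parameters to a named numeric vector
#'
#' One entry per scalar parameter (every `T`, `M`, `h`, `R`, `lam`, `D`
#' entry plus `K_hb`), with stable names such as `T[kr,hb_d]`. This is the
#' parameter order used by [param_zscore()].
#'
#' @param params a `circuit_params` object.
#' @return named numeric vector of length 53.
#' @export
as_param_vector <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  tn <- outer(GENES, REGULATORS, function(g, r) sprintf("T[%s,%s]", g, r))
  mn <- outer(GENES, MATERNALS, function(g, m) sprintf("M[%s,%s]", g, m))
  c(stats::setNames(as.numeric(params$T), tn),
    stats::setNames(as.numeric(params$M), mn),
    stats::setNames(params$h, sprintf("h[%s]", GENES)),
    stats::setNames(params$R, sprintf("R[%s]", GENES)),
    stats::setNames(params$lam, sprintf("lam[%s]", GENES)),
    stats::setNames(params$D, sprintf("D[%s]", GENES)),
    c(K_hb = params$K_hb))
}

#' Read and write circuit parameter sets as JSON
#'
#' Parameter sets are serialised as structured JSON with named matrices so
#' that externally fitted sets can be imported and shipped sets re-exported.
#'
#' @param params a `circuit_params` object.
#' @param path file path.
#' @return `read_circuit_params` returns a `circuit_params` object;
#'   `write_circuit_params` invisibly returns `path`.
#' @export
write_circuit_params <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  obj <- list(id = params$id, genes = params$genes,
              T = params$T, M = params$M, h = params$h, R = params$R,
              lam = params$lam, D = params$D, K_hb = params$K_hb)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_circuit_params
#' @export
read_circuit_params <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  circuit_params(T = as_mat(obj$T), M = as_mat(obj$M),
                 h = unlist(obj$h), R = unlist(obj$R), lam = unlist(obj$lam),
                 D = unlist(obj$D), K_hb = obj$K_hb,
                 id = obj$id %||% "imported")
}
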