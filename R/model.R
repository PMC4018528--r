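#' Mass-action right-hand side of the initiation model
#'
#' Time derivatives of the six state variables under the law of mass action:
#' reversible eIF4E/4E-BP and eIF4E/eIF4G binding, 4E-BP synthesis
#' proportional to the eIF4E:eIF4G complex, degradation of free 4E-BP, and
#' protein output proportional to eIF4E:eIF4G.
#'
#' @param state a [species_state()] (or named numeric with the same fields).
#' @param params a [rate_parameters()] object.
#' @return named numeric vector of derivatives (uM/s; protein AU/s).
#' @export
#' @examples
#' rhs(species_state(eif4e_free = 0.02, fourebp_free = 1.9,
#'                   eif4g_free = 1.79, complex_eb = 1.77,
#'                   complex_eg = 0.36), rate_parameters())
rhs <- function(state, params) {
  params <- validate_rate_parameters(params)
  y <- setNames(as.numeric(unclass(state)[.species_names]), .species_names)
  if (anyNA(y) || any(!is.finite(y))) stop("state must be finite")
  if (any(y < 0)) stop("state concentrations must be >= 0")
  E <- y[["eif4e_free"]]; B <- y[["fourebp_free"]]; G <- y[["eif4g_free"]]
  C1 <- y[["complex_eb"]]; C2 <- y[["complex_eg"]]
  a1 <- params[["k_on1"]] * E * B; d1 <- params[["k_off1"]] * C1
  a2 <- params[["k_on2"]] * E * G; d2 <- params[["k_off2"]] * C2
  c(eif4e_free   = d1 + d2 - a1 - a2,
    fourebp_free = d1 + params[["k_cat_4ebp"]] * C2 -
                   params[["k_lys_4ebp"]] * B - a1,
    eif4g_free   = d2 - a2,
    complex_eb   = a1 - d1,
    complex_eg   = a2 - d2,
    protein      = params[["k_cat_protein"]] * C2)
}

#' Integrate the initiation model
#'
#' Adaptive Dormand-Prince 5(4) integration of the mass-action system from
#' `t = 0`, with rate constants optionally ramped linearly in time. Output is
#' reported exactly at the requested grid times.
#'
#' @param initial a [species_state()] giving the state at `t = 0`.
#' @param ramp either a [parameter_ramp()] or a plain [rate_parameters()]
#'   object (interpreted as "no parameter change").
#' @param t_grid_s strictly increasing output times, seconds (>= 0).
#' @param rel_tol,abs_tol solver tolerances. The defaults resolve the fast
#'   binding and slow synthesis time scales with ample margin.
#' @return `data.frame` of class `model_trajectory` with columns `time_s`,
#'   `time_min`, the six species, and `total_4ebp` (free + complexed, uM).
#'   Attribute `initial_total_4ebp` stores the t = 0 total used by
#'   [total_4ebp_pct()].
#' @export
#' @examples
#' eq <- equilibrium_partition(totals(), kd1 = 23.66e-3, kd2 = 109.9e-3)
#' tr <- simulate_model(eq, rate_parameters(), t_grid_s = seq(0, 600, 60))
#' head(tr)
simulate_model <- function(initial, ramp, t_grid_s,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  if (inherits(ramp, "rate_parameters")) ramp <- parameter_ramp(ramp)
  stopifnot(inherits(ramp, "parameter_ramp"))
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be > 0")
  y0 <- setNames(as.numeric(unclass(initial)[.species_names]),
                 .species_names)
  if (anyNA(y0) || any(y0 < 0)) stop("initial state must be >= 0")
  t_grid_s <- as.numeric(t_grid_s)
  m <- ode_simulate_cpp(y0, unclass(ramp$initial), ramp$fold, ramp$t_start,
                        ramp$duration, t_grid_s, rel_tol, abs_tol)
  colnames(m) <- .species_names
  out <- data.frame(time_s = t_grid_s, time_min = t_grid_s / 60, m)
  out$total_4ebp <- out$fourebp_free + out$complex_eb
  attr(out, "initial_total_4ebp") <- y0[["fourebp_free"]] + y0[["complex_eb"]]
  class(out) <- c("model_trajectory", "data.frame")
  out
}

#' Total 4E-BP as percent of its initial value
#'
#' @param trajectory a `model_trajectory` from [simulate_model()].
#' @return numeric vector, one value per trajectory row, 100 at `t = 0`.
#' @export
total_4ebp_pct <- function(trajectory) {
  tot0 <- attr(trajectory, "initial_total_4ebp")
  if (is.null(tot0)) tot0 <- trajectory$total_4ebp[1]
  if (tot0 <= 0) stop("initial total 4E-BP must be positive")
  100 * trajectory$total_4ebp / tot0
}
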