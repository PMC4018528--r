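#' Coupled binding-equilibrium partition
#'
#' Solves the two coupled equilibria for the unfertilized egg: given the
#' three total pools and the two dissociation constants, find the unique
#' partition of eIF4E between free form, the eIF4E:4E-BP complex and the
#' eIF4E:eIF4G complex. The system reduces to a one-dimensional root find in
#' free eIF4E: with `E` free, both complexes are closed-form
#' (`C1 = Btot E/(KD1+E)`, `C2 = Gtot E/(KD2+E)`) and the eIF4E conservation
#' residual `E + C1 + C2 - Etot` is strictly increasing in `E`, so the
#' bracketed root is unique.
#'
#' @param tot a [totals()] object (uM).
#' @param kd1 dissociation constant of eIF4E:4E-BP, uM.
#' @param kd2 dissociation constant of eIF4E:eIF4G, uM.
#' @param tol residual tolerance of the root find, uM.
#' @return a [species_state()] (protein = 0).
#' @export
#' @examples
#' p <- rate_parameters()
#' equilibrium_partition(totals(), kd1(p), kd2(p))
equilibrium_partition <- function(tot, kd1, kd2, tol = 1e-12) {
  tot <- unclass(tot)
  stopifnot(length(tot) == 3, all(tot >= 0), kd1 > 0, kd2 > 0)
  Btot <- tot[["total_4ebp"]]; Etot <- tot[["total_eif4e"]]
  Gtot <- tot[["total_eif4g"]]
  if (Etot == 0)
    return(species_state(fourebp_free = Btot, eif4g_free = Gtot))
  resid <- function(E) E + Btot * E / (kd1 + E) + Gtot * E / (kd2 + E) - Etot
  sol <- uniroot(resid, c(0, Etot), tol = tol)
  E <- sol$root
  C1 <- Btot * E / (kd1 + E)
  C2 <- Gtot * E / (kd2 + E)
  species_state(eif4e_free = E, fourebp_free = Btot - C1,
                eif4g_free = Gtot - C2, complex_eb = C1, complex_eg = C2)
}

#' Flux-balance steady state of the full model
#'
#' Steady state of the complete system including 4E-BP turnover: both binding
#' reactions are at equilibrium, eIF4E and eIF4G are conserved, and 4E-BP
#' synthesis from the eIF4E:eIF4G complex balances degradation of free 4E-BP
#' (`k_cat_4ebp * complex_eg = k_lys_4ebp * fourebp_free`). The total 4E-BP
#' pool is an output here, not an input. As in
#' [equilibrium_partition()] the problem reduces to a monotone
#' one-dimensional root find in free eIF4E.
#'
#' @param total_eif4e,total_eif4g conserved pools, uM.
#' @param params a [rate_parameters()] object with `k_lys_4ebp > 0`.
#' @param tol residual tolerance, uM.
#' @return a [species_state()]; attribute `total_4ebp` holds the steady-state
#'   4E-BP pool (uM).
#' @export
flux_balance_steady_state <- function(total_eif4e, total_eif4g, params,
                                      tol = 1e-12) {
  params <- validate_rate_parameters(params)
  stopifnot(total_eif4e >= 0, total_eif4g >= 0)
  if (params[["k_lys_4ebp"]] <= 0)
    stop("flux balance requires k_lys_4ebp > 0")
  kd1v <- kd1(params); kd2v <- kd2(params)
  ratio <- params[["k_cat_4ebp"]] / params[["k_lys_4ebp"]]
  if (total_eif4e == 0)
    return(structure(species_state(eif4g_free = total_eif4g),
                     total_4ebp = 0))
  bfree <- function(E) ratio * total_eif4g * E / (kd2v + E)
  resid <- function(E) {
    C2 <- total_eif4g * E / (kd2v + E)
    E + E * bfree(E) / kd1v + C2 - total_eif4e
  }
  sol <- uniroot(resid, c(0, total_eif4e), tol = tol)
  E <- sol$root
  C2 <- total_eif4g * E / (kd2v + E)
  B <- bfree(E)
  C1 <- E * B / kd1v
  st <- species_state(eif4e_free = E, fourebp_free = B,
                      eif4g_free = total_eif4g - C2,
                      complex_eb = C1, complex_eg = C2)
  attr(st, "total_4ebp") <- B + C1
  st
}

#' Per-species fold changes between two states
#'
#' Elementwise ratio `perturbed / reference`. Species with a zero reference
#' concentration are reported as `NA` (undefined), never as infinite.
#'
#' @param reference,perturbed [species_state()] objects.
#' @return named numeric vector of ratios.
#' @export
fold_changes <- function(reference, perturbed) {
  r <- setNames(as.numeric(unclass(reference)[.species_names]),
                .species_names)
  p <- setNames(as.numeric(unclass(perturbed)[.species_names]),
                .species_names)
  out <- p / r
  out[r == 0] <- NA_real_
  out
}

#' Rate parameters balanced at the unfertilized partition
#'
#' Returns `params` with `k_cat_4ebp` replaced by the closed-form flux
#' balance value `k_lys_4ebp * fourebp_free / complex_eg` evaluated at the
#' coupled-equilibrium partition of `tot`, so that the partition is an exact
#' fixed point of the full system (total 4E-BP stays flat at 100%).
#'
#' @param tot a [totals()] object.
#' @param params a [rate_parameters()] object.
#' @return [rate_parameters()] with the balanced synthesis constant.
#' @export
balanced_parameters <- function(tot = totals(), params = rate_parameters()) {
  params <- validate_rate_parameters(params)
  eq <- equilibrium_partition(tot, kd1(params), kd2(params))
  if (eq[["complex_eg"]] <= 0)
    stop("cannot balance synthesis: eIF4E:eIF4G complex is zero")
  k <- params[["k_lys_4ebp"]] * eq[["fourebp_free"]] / eq[["complex_eg"]]
  params[["k_cat_4ebp"]] <- k
  validate_rate_parameters(params)
}
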