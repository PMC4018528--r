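.param_names <- c("k_on1", "k_off1", "k_on2", "k_off2",
                  "k_cat_4ebp", "k_lys_4ebp", "k_cat_protein")

.species_names <- c("eif4e_free", "fourebp_free", "eif4g_free",
                    "complex_eb", "complex_eg", "protein")

#' Kinetic rate constants of the minimal initiation model
#'
#' Container for the seven rate constants. Units: second-order association
#' rates in per-uM per-second, all first-order rates in per-second. Defaults
#' are the unfertilized sea urchin egg values (SPR measurement for the
#' eIF4E/4E-BP pair, literature values for eIF4E/eIF4G, emetine fit for the
#' degradation rate, flux-balance printed value for 4E-BP synthesis). The
#' protein output rate is unconstrained by relative protein measurements and
#' defaults to 1 so protein is reported in arbitrary units.
#'
#' @param k_on1 association rate eIF4E + 4E-BP (uM^-1 s^-1). The literature
#'   value 9.3e3 M^-1 s^-1 corresponds to 9.3e-3 here.
#' @param k_off1 dissociation rate of eIF4E:4E-BP (s^-1).
#' @param k_on2 association rate eIF4E + eIF4G (uM^-1 s^-1).
#' @param k_off2 dissociation rate of eIF4E:eIF4G (s^-1).
#' @param k_cat_4ebp 4E-BP synthesis rate from eIF4E:eIF4G (s^-1).
#' @param k_lys_4ebp degradation rate of free 4E-BP (s^-1).
#' @param k_cat_protein protein production rate from eIF4E:eIF4G (s^-1,
#'   arbitrary output units).
#' @return object of class `rate_parameters` (named numeric vector).
#' @seealso [kd1()], [kd2()], [balanced_parameters()]
#' @export
#' @examples
#' p <- rate_parameters()
#' kd1(p) * 1000  # dissociation constant of eIF4E:4E-BP, nM
rate_parameters <- function(k_on1 = 9.3e-3, k_off1 = 2.2e-4,
                            k_on2 = 1.82e-3, k_off2 = 2.0e-4,
                            k_cat_4ebp = 3.2e-3, k_lys_4ebp = 5.9e-4,
                            k_cat_protein = 1.0) {
  p <- c(k_on1 = k_on1, k_off1 = k_off1, k_on2 = k_on2, k_off2 = k_off2,
         k_cat_4ebp = k_cat_4ebp, k_lys_4ebp = k_lys_4ebp,
         k_cat_protein = k_cat_protein)
  validate_rate_parameters(p)
}

validate_rate_parameters <- function(p) {
  p <- unclass(p)[.param_names]
  if (anyNA(p) || any(!is.finite(p)))
    stop("rate parameters must be finite and named: ",
         paste(.param_names, collapse = ", "))
  if (any(p < 0)) stop("rate parameters must be >= 0")
  structure(p, class = "rate_parameters")
}

#' @rdname rate_parameters
#' @param x a `rate_parameters` object.
#' @export
kd1 <- function(x) {
  x <- validate_rate_parameters(x)
  unname(x["k_off1"] / x["k_on1"])
}

#' @rdname rate_parameters
#' @export
kd2 <- function(x) {
  x <- validate_rate_parameters(x)
  unname(x["k_off2"] / x["k_on2"])
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (uM, s):\n")
  print(setNames(as.numeric(x), names(x)))
  cat(sprintf("KD1 = %.4g nM, KD2 = %.4g nM\n", kd1(x) * 1e3, kd2(x) * 1e3))
  invisible(x)
}

#' Total concentrations of the three factors
#'
#' @param total_4ebp,total_eif4e,total_eif4g total pools in uM. Defaults are
#'   the unfertilized egg measurements (immunoblot densitometry for 4E-BP and
#'   eIF4E; eIF4G set equal to eIF4E on stoichiometric grounds).
#' @return object of class `totals`.
#' @export
totals <- function(total_4ebp = 3.67, total_eif4e = 2.15,
                   total_eif4g = 2.15) {
  x <- c(total_4ebp = total_4ebp, total_eif4e = total_eif4e,
         total_eif4g = total_eif4g)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop("total concentrations must be finite and >= 0")
  structure(x, class = "totals")
}

#' Molecular species state
#'
#' Concentrations of the five molecular species (uM) plus accumulated
#' protein (arbitrary units).
#'
#' @param eif4e_free,fourebp_free,eif4g_free free factor concentrations, uM.
#' @param complex_eb eIF4E:4E-BP complex, uM.
#' @param complex_eg eIF4E:eIF4G complex, uM.
#' @param protein accumulated protein, arbitrary units.
#' @return object of class `species_state`.
#' @export
species_state <- function(eif4e_free = 0, fourebp_free = 0, eif4g_free = 0,
                          complex_eb = 0, complex_eg = 0, protein = 0) {
  x <- c(eif4e_free = eif4e_free, fourebp_free = fourebp_free,
         eif4g_free = eif4g_free, complex_eb = complex_eb,
         complex_eg = complex_eg, protein = protein)
  if (anyNA(x) || any(!is.finite(x))) stop("species state must be finite")
  if (any(x < 0)) stop("species concentrations must be >= 0")
  structure(x, class = "species_state")
}

as_species_state <- function(x) {
  do.call(species_state, as.list(setNames(as.numeric(x), .species_names)))
}

#' @export
print.species_state <- function(x, ...) {
  cat("Species state (uM; protein in AU):\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Linear parameter ramp
#'
#' Describes the "parameter time change": each perturbed rate constant moves
#' linearly in value from its initial value to `fold * initial` over the
#' window `[t_start, t_start + duration]` and is constant outside it.
#'
#' @param initial a [rate_parameters()] object.
#' @param fold_changes named numeric vector of multiplicative factors, names
#'   among the rate parameter names; omitted parameters keep fold 1.
#' @param t_start ramp start, seconds.
#' @param duration ramp duration, seconds; 0 gives a step change at
#'   `t_start`.
#' @return object of class `parameter_ramp`.
#' @export
#' @examples
#' fert <- parameter_ramp(rate_parameters(),
#'                        c(k_off1 = 8, k_lys_4ebp = 32.5),
#'                        duration = 300)
#' params_at_time(fert, 150)  # ramp midpoint
parameter_ramp <- function(initial, fold_changes = numeric(),
                           t_start = 0, duration = 0) {
  initial <- validate_rate_parameters(initial)
  fold <- setNames(rep(1, length(.param_names)), .param_names)
  if (length(fold_changes)) {
    if (is.null(names(fold_changes)) ||
        !all(names(fold_changes) %in% .param_names))
      stop("fold_changes must be named with rate parameter names")
    if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
      stop("fold factors must be finite and > 0")
    fold[names(fold_changes)] <- fold_changes
  }
  if (!is.finite(t_start) || t_start < 0) stop("t_start must be >= 0")
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0")
  structure(list(initial = initial, fold = fold, t_start = t_start,
                 duration = duration),
            class = "parameter_ramp")
}

#' @rdname parameter_ramp
#' @param ramp a `parameter_ramp`.
#' @param t time in seconds.
#' @return `params_at_time()`: the [rate_parameters()] in force at time `t`.
#' @export
params_at_time <- function(ramp, t) {
  stopifnot(inherits(ramp, "parameter_ramp"), is.finite(t), t >= 0)
  s <- if (t <= ramp$t_start) 0
       else if (ramp$duration <= 0 || t >= ramp$t_start + ramp$duration) 1
       else (t - ramp$t_start) / ramp$duration
  p <- unclass(ramp$initial) * (1 + (ramp$fold - 1) * s)
  validate_rate_parameters(p)
}

#' @export
print.parameter_ramp <- function(x, ...) {
  changed <- x$fold[x$fold != 1]
  cat(sprintf("Parameter ramp: t_start = %g s, duration = %g s\n",
              x$t_start, x$duration))
  if (length(changed)) {
    cat("fold changes:\n")
    print(changed)
  } else cat("no parameter changes\n")
  invisible(x)
}

#' Assemble a time-course table
#'
#' Time courses hold replicate observations of total 4E-BP as a percentage
#' of its initial value (or protein in arbitrary units), the common exchange
#' format of the fitting and synthetic-data functions.
#'
#' @param replicate_id replicate labels.
#' @param time_min observation times, minutes.
#' @param value_pct observed values (% of initial, or AU for protein).
#' @return `data.frame` of class `timecourse` with those three columns.
#' @export
timecourse <- function(replicate_id, time_min, value_pct) {
  tc <- data.frame(replicate_id = as.character(replicate_id),
                   time_min = as.numeric(time_min),
                   value_pct = as.numeric(value_pct),
                   stringsAsFactors = FALSE)
  validate_timecourse(tc)
}

validate_timecourse <- function(tc, context = "timecourse") {
  need <- c("replicate_id", "time_min", "value_pct")
  if (!all(need %in% names(tc)))
    stop(context, " must have columns ", paste(need, collapse = ", "))
  if (nrow(tc) == 0) stop(context, ": no observations (empty input)")
  bad <- which(!is.finite(tc$time_min) | !is.finite(tc$value_pct))
  if (length(bad))
    stop(context, ": non-finite value in row ", bad[1])
  for (r in unique(tc$replicate_id)) {
    tt <- tc$time_min[tc$replicate_id == r]
    if (any(diff(tt) <= 0)) {
      row <- which(tc$replicate_id == r)[which(diff(tt) <= 0)[1] + 1]
      stop(context, ": times not strictly increasing within replicate '",
           r, "' at row ", row)
    }
  }
  class(tc) <- c("timecourse", "data.frame")
  tc
}
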