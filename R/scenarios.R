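# The four named egg experiments, packaged as configured runs. Every
# scenario starts from the coupled-equilibrium partition with the synthesis
# rate balanced so the unfertilized baseline is an exact fixed point.

scenario_names <- c("unfertilized", "emetine", "fertilization", "rapamycin")

scenario_spec <- function(name) {
  switch(name,
    unfertilized = list(fold = numeric(), duration_s = 0, kcat_zero = FALSE),
    # emetine blocks all protein synthesis, hence 4E-BP production, from t=0
    emetine = list(fold = numeric(), duration_s = 0, kcat_zero = TRUE),
    fertilization = list(fold = c(k_off1 = 8, k_lys_4ebp = 32.5),
                         duration_s = 300, kcat_zero = FALSE),
    rapamycin = list(fold = c(k_off1 = 1, k_lys_4ebp = 16),
                     duration_s = 33 * 60, kcat_zero = FALSE),
    stop("unknown scenario '", name, "'; choose one of: ",
         paste(scenario_names, collapse = ", "))
  )
}

#' Run a named egg scenario
#'
#' Simulates one of the four reference experiments from the unfertilized
#' coupled-equilibrium state:
#' * `unfertilized`: baseline, no parameter change (flat control);
#' * `emetine`: 4E-BP synthesis switched off at t = 0 (protein-synthesis
#'   inhibitor), isolating degradation of the free form;
#' * `fertilization`: eIF4E:4E-BP dissociation x8 and 4E-BP degradation
#'   x32.5, ramped linearly over 5 min;
#' * `rapamycin`: fertilization in the presence of the mTOR inhibitor -
#'   dissociation unchanged (x1), degradation x16, ramped over 33 min.
#'
#' @param name scenario name.
#' @param horizon_min simulated horizon, minutes.
#' @param dt_out_s output spacing, seconds.
#' @param overrides optional named list overriding `fold` (named numeric),
#'   `duration_s`, `tot`, or `params`.
#' @param tot a [totals()] object.
#' @param params baseline [rate_parameters()]; `k_cat_4ebp` is re-balanced at
#'   the partition unless the scenario zeroes it.
#' @param rel_tol,abs_tol solver tolerances.
#' @return object of class `scenario_run`: list with `name`, `trajectory`
#'   (a `model_trajectory`), `pct` (time_min, total 4E-BP %), `initial`
#'   (partition state), `steady_state` (asymptotic flux-balance state under
#'   the final parameters, `NULL` for emetine where the 4E-BP pool empties),
#'   `fold_vs_initial` (per-species asymptotic fold changes), and `config`.
#' @export
#' @examples
#' fert <- run_scenario("fertilization")
#' fert$fold_vs_initial[["complex_eg"]]  # ~4.2
run_scenario <- function(name, horizon_min = 60, dt_out_s = 30,
                         overrides = list(),
                         tot = totals(), params = rate_parameters(),
                         rel_tol = 1e-8, abs_tol = 1e-10) {
  name <- match.arg(name, scenario_names)
  spec <- scenario_spec(name)
  for (nm in intersect(names(overrides), c("fold", "duration_s")))
    spec[[nm]] <- overrides[[nm]]
  tot <- overrides$tot %||% tot
  params <- overrides$params %||% params

  params <- balanced_parameters(tot, params)
  if (spec$kcat_zero) {
    params[["k_cat_4ebp"]] <- 0
    params <- validate_rate_parameters(params)
  }
  eq <- equilibrium_partition(tot, kd1(params), kd2(params))
  ramp <- parameter_ramp(params, spec$fold, t_start = 0,
                         duration = spec$duration_s)
  t_grid <- seq(0, horizon_min * 60, by = dt_out_s)
  traj <- simulate_model(eq, ramp, t_grid, rel_tol, abs_tol)

  final <- params_at_time(ramp, ramp$t_start + ramp$duration + 1)
  stead <- if (final[["k_cat_4ebp"]] > 0 && final[["k_lys_4ebp"]] > 0)
    flux_balance_steady_state(tot[["total_eif4e"]], tot[["total_eif4g"]],
                              final)
  else NULL
  fold <- if (!is.null(stead)) fold_changes(eq, stead) else NULL

  structure(list(
    name = name,
    trajectory = traj,
    pct = data.frame(time_min = traj$time_min,
                     total_4ebp_pct = total_4ebp_pct(traj)),
    initial = eq,
    steady_state = stead,
    fold_vs_initial = fold,
    config = list(name = name, fold = as.list(spec$fold),
                  duration_s = spec$duration_s, horizon_min = horizon_min,
                  dt_out_s = dt_out_s, tot = as.list(unclass(tot)),
                  params = as.list(unclass(params)),
                  rel_tol = rel_tol, abs_tol = abs_tol)
  ), class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("Scenario:", x$name, "(", max(x$trajectory$time_min), "min )\n")
  cat(sprintf("total 4E-BP at end: %.1f%% of initial\n",
              x$pct$total_4ebp_pct[nrow(x$pct)]))
  if (!is.null(x$fold_vs_initial))
    cat(sprintf("asymptotic eIF4E:eIF4G fold vs initial: %.3g\n",
                x$fold_vs_initial[["complex_eg"]]))
  invisible(x)
}

#' Protein accumulation curve of a scenario run
#'
#' The accumulated protein (cumulative integral of `k_cat_protein *
#' [eIF4E:eIF4G]`) carried along the trajectory, as a single-replicate
#' [timecourse()] in arbitrary units. Nondecreasing by construction;
#' asymptotically linear with slope proportional to the steady-state
#' eIF4E:eIF4G complex.
#'
#' @param run a `scenario_run` from [run_scenario()].
#' @return a [timecourse()] (`value_pct` holds AU here).
#' @export
protein_accumulation <- function(run) {
  stopifnot(inherits(run, "scenario_run"))
  timecourse("sim", run$trajectory$time_min, run$trajectory$protein)
}
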