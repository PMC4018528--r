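# Parameter learning from total 4E-BP time courses. All fits share one
# objective: the sum of squared residuals (SSR, %^2 units) between observed
# and simulated total 4E-BP, both expressed as % of the t = 0 value, pooled
# over replicates. Grid evaluations run through the compiled batch solver.

#' Sum of squared residuals against a prediction
#'
#' @param observed a [timecourse()] (values in % of initial).
#' @param predicted function of time in minutes returning predicted total
#'   4E-BP %.
#' @return SSR over all observation points, pooled across replicates.
#' @export
ssr <- function(observed, predicted) {
  observed <- validate_timecourse(observed, "observed")
  stopifnot(is.function(predicted))
  pred <- predicted(observed$time_min)
  if (length(pred) != nrow(observed) || any(!is.finite(pred)))
    stop("prediction must return one finite value per observation")
  sum((observed$value_pct - pred)^2)
}

# Pool a timecourse into (unique times, 0-based index, value) for the
# compiled SSR kernel.
pooled_obs <- function(tc) {
  tc <- validate_timecourse(tc)
  t_uniq <- sort(unique(tc$time_min))
  list(t_uniq_s = t_uniq * 60,
       idx = match(tc$time_min, t_uniq) - 1L,
       val = tc$value_pct)
}

# Batch SSR over a fold matrix (columns = the seven rate parameters).
batch_ssr <- function(tc, tot, params, fold_matrix, durations_s,
                      t_start = 0, rel_tol = 1e-6, abs_tol = 1e-9) {
  params <- validate_rate_parameters(params)
  y0 <- equilibrium_partition(tot, kd1(params), kd2(params))
  ob <- pooled_obs(tc)
  grid_ssr_cpp(unclass(y0), unclass(params), fold_matrix,
               durations_s, t_start, ob$t_uniq_s, ob$idx, ob$val,
               rel_tol, abs_tol)
}

fold_matrix <- function(n, ...) {
  m <- matrix(1, n, length(.param_names),
              dimnames = list(NULL, .param_names))
  cols <- list(...)
  for (nm in names(cols)) m[, nm] <- cols[[nm]]
  m
}

new_fit_result <- function(best, grid, n_obs, settings) {
  structure(list(best = best, grid = grid, n_obs = n_obs,
                 settings = settings),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Grid-search fit over", nrow(x$grid), "parameter combinations,",
      x$n_obs, "observations\n")
  cat(sprintf(
    "best: fold k_off1 = %.4g, fold k_lys_4ebp = %.4g, ramp = %g min, SSR = %.4g\n",
    x$best$fold_koff1, x$best$fold_klys, x$best$ramp_min, x$best$ssr))
  if (!is.null(x$refined))
    cat(sprintf(
      "refined: fold k_off1 = %.4g, fold k_lys_4ebp = %.4g, ramp = %.3g min, SSR = %.4g\n",
      x$refined$fold_koff1, x$refined$fold_klys, x$refined$ramp_min,
      x$refined$ssr))
  invisible(x)
}

#' Fit the 4E-BP degradation rate from an emetine decay course
#'
#' With protein synthesis blocked (no 4E-BP production), total 4E-BP decays
#' through degradation of the free form while the two binding reactions
#' re-equilibrate. Starting from the coupled-equilibrium partition with
#' `k_cat_4ebp = 0`, the degradation rate is fitted by minimizing the SSR of
#' simulated vs observed total 4E-BP (%) over `bounds` (log-scale 1-D
#' minimization).
#'
#' @param decay a [timecourse()] of total 4E-BP in % of initial.
#' @param tot a [totals()] object.
#' @param params baseline [rate_parameters()] (its `k_lys_4ebp` is ignored
#'   as a start value; binding rates are used as-is).
#' @param bounds search interval for `k_lys_4ebp`, s^-1.
#' @param rel_tol,abs_tol solver tolerances used inside the objective.
#' @return list with `k_lys_4ebp` (s^-1), `ssr`, and logical `at_boundary`.
#'   A warning is raised when the optimum sits on a search bound.
#' @export
fit_klys_emetine <- function(decay, tot = totals(),
                             params = rate_parameters(),
                             bounds = c(1e-6, 1e-1),
                             rel_tol = 1e-8, abs_tol = 1e-10) {
  decay <- validate_timecourse(decay, "decay")
  params <- validate_rate_parameters(params)
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1])
  base <- params
  base[["k_cat_4ebp"]] <- 0
  base <- validate_rate_parameters(base)
  obj <- function(log10_klys) {
    f <- 10^log10_klys / base[["k_lys_4ebp"]]
    batch_ssr(decay, tot, base, fold_matrix(1, k_lys_4ebp = f), 0,
              rel_tol = rel_tol, abs_tol = abs_tol)
  }
  opt <- optimize(obj, log10(bounds), tol = 1e-7)
  est <- 10^opt$minimum
  best_ssr <- opt$objective
  at_boundary <- FALSE
  for (b in bounds) {
    s_b <- obj(log10(b))
    if (s_b <= best_ssr + 1e-12) {
      est <- b
      best_ssr <- s_b
      at_boundary <- TRUE
    }
  }
  if (at_boundary)
    warning("fitted k_lys_4ebp is at a search bound (", signif(est, 4),
            " s^-1); the decay data do not constrain it inside the interval")
  list(k_lys_4ebp = est, ssr = best_ssr, at_boundary = at_boundary)
}

#' Infer the 4E-BP synthesis rate by flux balance
#'
#' The synthesis constant is the value that keeps simulated total 4E-BP
#' constant, as close as possible to 100%, over the horizon. The
#' least-squares route minimizes the deviation of the simulated % curve from
#' 100 on a dense grid; the closed form is the flux balance
#' `k_lys_4ebp * fourebp_free / complex_eg` at the coupled-equilibrium
#' partition. The two agree to well under 1%.
#'
#' @param tot a [totals()] object.
#' @param params [rate_parameters()] with `k_lys_4ebp` already determined.
#' @param horizon_min least-squares horizon, minutes.
#' @param method `"least_squares"` (default, the operational definition) or
#'   `"closed_form"`.
#' @return inferred `k_cat_4ebp`, s^-1.
#' @export
infer_kcat_4ebp <- function(tot = totals(), params = rate_parameters(),
                            horizon_min = 60,
                            method = c("least_squares", "closed_form")) {
  method <- match.arg(method)
  params <- validate_rate_parameters(params)
  if (params[["k_lys_4ebp"]] == 0) return(0)
  eq <- equilibrium_partition(tot, kd1(params), kd2(params))
  closed <- params[["k_lys_4ebp"]] * eq[["fourebp_free"]] /
    eq[["complex_eg"]]
  if (method == "closed_form") return(closed)
  flat <- timecourse("target", seq(0, horizon_min, by = 0.5),
                     100)
  base <- params
  obj <- function(kcat) {
    f <- if (base[["k_cat_4ebp"]] > 0) kcat / base[["k_cat_4ebp"]] else 1
    b <- base
    if (base[["k_cat_4ebp"]] == 0) {
      b[["k_cat_4ebp"]] <- kcat
      b <- validate_rate_parameters(b)
      f <- 1
    }
    batch_ssr(flat, tot, b, fold_matrix(1, k_cat_4ebp = f), 0)
  }
  optimize(obj, c(0, 10 * closed), tol = 1e-10)$minimum
}

# Core exhaustive grid evaluation shared by the fertilization and rapamycin
# fits. Returns the full SSR surface plus its argmin; optional bounded local
# refinement seeded at the argmin (off by default: the reference procedure
# is pure grid evaluation).
grid_search_timecourse <- function(data, fold_koff1, fold_klys, ramp_min,
                                   tot, params, rel_tol, abs_tol,
                                   refine = FALSE) {
  data <- validate_timecourse(data, "data")
  params <- validate_rate_parameters(params)
  grid <- expand.grid(fold_koff1 = fold_koff1, fold_klys = fold_klys,
                      ramp_min = ramp_min, KEEP.OUT.ATTRS = FALSE)
  fm <- fold_matrix(nrow(grid), k_off1 = grid$fold_koff1,
                    k_lys_4ebp = grid$fold_klys)
  grid$ssr <- batch_ssr(data, tot, params, fm, grid$ramp_min * 60,
                        rel_tol = rel_tol, abs_tol = abs_tol)
  ibest <- which.min(grid$ssr)
  res <- new_fit_result(grid[ibest, , drop = FALSE], grid, nrow(data),
                        list(tot = tot, params = params, rel_tol = rel_tol,
                             abs_tol = abs_tol))
  if (refine) {
    obj <- function(theta) {
      batch_ssr(data, tot, params,
                fold_matrix(1, k_off1 = 10^theta[1],
                            k_lys_4ebp = 10^theta[2]),
                theta[3] * 60, rel_tol = rel_tol, abs_tol = abs_tol)
    }
    start <- c(log10(res$best$fold_koff1), log10(res$best$fold_klys),
               res$best$ramp_min)
    lo <- c(log10(min(fold_koff1)), log10(min(fold_klys)), min(ramp_min))
    hi <- c(log10(max(fold_koff1)), log10(max(fold_klys)), max(ramp_min))
    op <- optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi)
    res$refined <- data.frame(fold_koff1 = 10^op$par[1],
                              fold_klys = 10^op$par[2],
                              ramp_min = op$par[3], ssr = op$value)
  }
  res
}

#' Grid-search fit of the fertilization parameter changes
#'
#' Exhaustive SSR evaluation over fold changes in the eIF4E:4E-BP
#' dissociation rate and the 4E-BP degradation rate, combined with an
#' integer-minute linear ramp duration. Default grids are 25 log-spaced folds
#' per axis over 1-100 with the reference optima (8, 32.5) injected as exact
#' nodes, and ramps of 1-15 min. Freeze an axis by passing a single value
#' (e.g. `fold_koff1 = 1`) to reproduce the single-parameter searches.
#'
#' @param data a [timecourse()] of total 4E-BP in % of initial.
#' @param fold_koff1,fold_klys fold grids (see [fold_grid()]).
#' @param ramp_min ramp durations, minutes.
#' @param tot,params stated-world totals and baseline rates; `k_cat_4ebp` is
#'   re-balanced internally so the baseline is stationary.
#' @param rel_tol,abs_tol solver tolerances for grid evaluation (looser than
#'   the simulation defaults; the SSR is in %^2 units, so 1e-6 relative is
#'   far below the objective's resolution).
#' @param refine if `TRUE`, polish the argmin by bounded continuous
#'   minimization (off by default; the reference procedure is pure grid
#'   evaluation).
#' @return a `fit_result` with the argmin (`$best`) and the full SSR surface
#'   (`$grid`, long format suitable for heatmapping).
#' @export
grid_search_fertilization <- function(data,
                                      fold_koff1 = fold_grid(1, 100, 25, include = 8),
                                      fold_klys = fold_grid(1, 100, 25, include = 32.5),
                                      ramp_min = 1:15,
                                      tot = totals(),
                                      params = rate_parameters(),
                                      rel_tol = 1e-6, abs_tol = 1e-9,
                                      refine = FALSE) {
  params <- balanced_parameters(tot, params)
  grid_search_timecourse(data, fold_koff1, fold_klys, ramp_min, tot, params,
                         rel_tol, abs_tol, refine)
}

#' Grid-search fit of the rapamycin-treated fertilization response
#'
#' Same procedure as [grid_search_fertilization()] with the attenuated
#' search ranges: dissociation fold 1-8, degradation fold 1-32.5, ramp 1-100
#' min (reference optima 1, 16 and 33 min injected as nodes).
#'
#' @inheritParams grid_search_fertilization
#' @return a `fit_result`.
#' @export
fit_rapamycin <- function(data,
                          fold_koff1 = fold_grid(1, 8, 25, include = c(1, 8)),
                          fold_klys = fold_grid(1, 32.5, 25, include = c(16, 32.5)),
                          ramp_min = 1:100,
                          tot = totals(), params = rate_parameters(),
                          rel_tol = 1e-6, abs_tol = 1e-9, refine = FALSE) {
  params <- balanced_parameters(tot, params)
  grid_search_timecourse(data, fold_koff1, fold_klys, ramp_min, tot, params,
                         rel_tol, abs_tol, refine)
}

#' Which rate constant carries the KD1/KD2 change?
#'
#' An 8-fold increase in the KD1/KD2 ratio can be produced by four
#' single-parameter alternatives: `k_off1` x8, `k_on2` x8, `k_on1` x(1/8) or
#' `k_off2` x(1/8). Each alternative (combined with the fixed degradation
#' fold and ramp) is simulated and scored against the data; kinetically the
#' four are not equivalent even though they produce identical equilibrium
#' ratios.
#'
#' @param data a [timecourse()].
#' @param parameters which alternatives to evaluate.
#' @param fold_ratio target fold increase of KD1/KD2.
#' @param fold_klys_fixed fixed degradation fold applied with each
#'   alternative.
#' @param ramp_fixed_min fixed ramp duration, minutes.
#' @inheritParams grid_search_fertilization
#' @return `data.frame` with columns `parameter`, `fold`, `kd_ratio_fold`,
#'   `ssr`, ordered as given.
#' @export
equivalence_scan <- function(data,
                             parameters = c("k_off1", "k_on2", "k_on1", "k_off2"),
                             fold_ratio = 8, fold_klys_fixed = 32.5,
                             ramp_fixed_min = 5,
                             tot = totals(), params = rate_parameters(),
                             rel_tol = 1e-6, abs_tol = 1e-9) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  params <- balanced_parameters(tot, params)
  fold <- ifelse(parameters %in% c("k_off1", "k_on2"),
                 fold_ratio, 1 / fold_ratio)
  fm <- fold_matrix(length(parameters),
                    k_lys_4ebp = rep(fold_klys_fixed, length(parameters)))
  for (i in seq_along(parameters)) fm[i, parameters[i]] <- fold[i]
  s <- batch_ssr(data, tot, params, fm,
                 rep(ramp_fixed_min * 60, length(parameters)),
                 rel_tol = rel_tol, abs_tol = abs_tol)
  kd_ratio <- (fm[, "k_off1"] / fm[, "k_on1"]) *
    (fm[, "k_on2"] / fm[, "k_off2"])
  data.frame(parameter = parameters, fold = fold,
             kd_ratio_fold = unname(kd_ratio), ssr = s)
}

#' Constrained scan of all four binding-rate factors
#'
#' Enumerates every tuple of fold changes `(k_off1, k_on1, k_on2, k_off2) =
#' (base^a, base^b, base^c, base^d)` with integer exponents in
#' `exponents` whose combined effect increases the KD1/KD2 ratio exactly
#' `target_ratio`-fold (constraint `a - b + c - d = log_base(target_ratio)`),
#' scores each against the data, and aggregates the SSR per parameter and
#' per fold value (mean and SD across tuples sharing that fold).
#'
#' @param data a [timecourse()].
#' @param exponents integer exponent range for each parameter (default
#'   -5:5, i.e. folds 1/32 to 32 in powers of 2).
#' @param base step base of the fold ladder.
#' @param target_ratio required fold increase of KD1/KD2; must be an exact
#'   power of `base` within the exponent range.
#' @inheritParams equivalence_scan
#' @return list with `tuples` (one row per enumerated combination, with its
#'   SSR) and `summary` (per parameter and fold: n, mean SSR, SD).
#' @export
combined_factor_scan <- function(data, exponents = -5:5, base = 2,
                                 target_ratio = 8, fold_klys_fixed = 32.5,
                                 ramp_fixed_min = 5,
                                 tot = totals(), params = rate_parameters(),
                                 rel_tol = 1e-6, abs_tol = 1e-9) {
  stopifnot(all(exponents == round(exponents)), base > 1)
  k <- log(target_ratio, base)
  if (abs(k - round(k)) > 1e-9)
    stop("target_ratio must be an integer power of base")
  k <- round(k)
  ex <- expand.grid(a = exponents, b = exponents, c = exponents,
                    d = exponents, KEEP.OUT.ATTRS = FALSE)
  ex <- ex[ex$a - ex$b + ex$c - ex$d == k, , drop = FALSE]
  if (nrow(ex) == 0) stop("no tuples satisfy the KD-ratio constraint")
  tuples <- data.frame(fold_koff1 = base^ex$a, fold_kon1 = base^ex$b,
                       fold_kon2 = base^ex$c, fold_koff2 = base^ex$d)
  params <- balanced_parameters(tot, params)
  fm <- fold_matrix(nrow(tuples), k_off1 = tuples$fold_koff1,
                    k_on1 = tuples$fold_kon1, k_on2 = tuples$fold_kon2,
                    k_off2 = tuples$fold_koff2,
                    k_lys_4ebp = rep(fold_klys_fixed, nrow(tuples)))
  tuples$ssr <- batch_ssr(data, tot, params, fm,
                          rep(ramp_fixed_min * 60, nrow(tuples)),
                          rel_tol = rel_tol, abs_tol = abs_tol)
  cols <- c(k_off1 = "fold_koff1", k_on1 = "fold_kon1",
            k_on2 = "fold_kon2", k_off2 = "fold_koff2")
  summ <- do.call(rbind, lapply(names(cols), function(p) {
    f <- tuples[[cols[[p]]]]
    agg <- lapply(split(tuples$ssr, f), function(s)
      c(n = length(s), mean_ssr = mean(s), sd_ssr = sd(s)))
    data.frame(parameter = p, fold = as.numeric(names(agg)),
               do.call(rbind, agg), row.names = NULL)
  }))
  list(tuples = tuples, summary = summ)
}
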