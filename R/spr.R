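# 1:1 Langmuir surface plasmon resonance: closed-form sensorgram simulation
# and global kinetic fitting of an analyte dilution series. Concentrations
# are molar here (instrument convention), unlike the uM used in the cell
# model; the boundary conversion is 1 uM^-1 s^-1 = 1e6 M^-1 s^-1.

#' Simulate a 1:1 binding sensorgram
#'
#' Closed-form pseudo-first-order Langmuir kinetics for a single analyte
#' injection: during association
#' `R(t) = R_eq (1 - exp(-(k_on C + k_off) t))` with
#' `R_eq = r_max C / (KD + C)`; after the injection ends the response decays
#' from the association endpoint as `exp(-k_off tau)`. Optional i.i.d.
#' Gaussian noise emulates instrument noise on a double-referenced curve.
#'
#' @param k_on association rate, M^-1 s^-1.
#' @param k_off dissociation rate, s^-1.
#' @param r_max saturating response, uRIU.
#' @param concentration analyte concentration, M.
#' @param t_assoc,t_dissoc phase durations, s.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise SD, uRIU.
#' @param seed RNG seed for the noise (`NULL` leaves the RNG state alone).
#' @return `data.frame` of class `sensorgram` with columns `time_s`,
#'   `response_riu`, `conc_M`, `phase` (`"association"`/`"dissociation"`);
#'   attributes `t_assoc`, `t_dissoc`.
#' @export
#' @examples
#' sg <- simulate_sensorgram(9.3e3, 2.2e-4, 60, 4.37e-6)
#' max(sg$response_riu)
simulate_sensorgram <- function(k_on, k_off, r_max, concentration,
                                t_assoc = 300, t_dissoc = 300, dt = 1,
                                noise_sd = 0, seed = NULL) {
  stopifnot(k_on >= 0, k_off >= 0, r_max >= 0, concentration >= 0,
            t_assoc > 0, t_dissoc >= 0, dt > 0, noise_sd >= 0)
  t_a <- seq(0, t_assoc, by = dt)
  t_d <- if (t_dissoc > 0) seq(dt, t_dissoc, by = dt) else numeric()
  r_a <- langmuir_association(t_a, k_on, k_off, r_max, concentration)
  r_end <- langmuir_association(t_assoc, k_on, k_off, r_max, concentration)
  r_d <- r_end * exp(-k_off * t_d)
  sg <- data.frame(
    time_s = c(t_a, t_assoc + t_d),
    response_riu = c(r_a, r_d),
    conc_M = concentration,
    phase = c(rep("association", length(t_a)),
              rep("dissociation", length(t_d))),
    stringsAsFactors = FALSE)
  if (noise_sd > 0)
    sg$response_riu <- sg$response_riu +
      with_seed(seed, rnorm(nrow(sg), 0, noise_sd))
  attr(sg, "t_assoc") <- t_assoc
  attr(sg, "t_dissoc") <- t_dissoc
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

langmuir_association <- function(t, k_on, k_off, r_max, conc) {
  kobs <- k_on * conc + k_off
  kd <- if (k_on > 0) k_off / k_on else Inf
  req <- if (is.finite(kd)) r_max * conc / (kd + conc) else 0
  if (kobs == 0) return(rep(0, length(t)))
  req * (1 - exp(-kobs * t))
}

#' Three-fold analyte dilution series
#'
#' Simulates one sensorgram per concentration of a geometric dilution series,
#' by default the measured range 4.37 uM down to 53.9 nM in 3-fold steps
#' (five injections).
#'
#' @param c_top top analyte concentration, M.
#' @param dilution dilution factor between consecutive injections.
#' @param n number of concentrations.
#' @param seed base seed; injection `i` uses `seed + i` so curves are
#'   independently seeded but jointly reproducible.
#' @inheritParams simulate_sensorgram
#' @return list of `sensorgram` objects, highest concentration first.
#' @export
spr_dilution_series <- function(k_on = 9.3e3, k_off = 2.2e-4, r_max = 60,
                                c_top = 4.37e-6, dilution = 3, n = 5,
                                t_assoc = 300, t_dissoc = 300, dt = 1,
                                noise_sd = 0, seed = NULL) {
  stopifnot(n >= 1, dilution > 1, c_top > 0)
  concs <- c_top / dilution^(seq_len(n) - 1)
  lapply(seq_along(concs), function(i)
    simulate_sensorgram(k_on, k_off, r_max, concs[i], t_assoc, t_dissoc, dt,
                        noise_sd,
                        seed = if (is.null(seed)) NULL else seed + i))
}

#' Global 1:1 kinetic fit of a sensorgram series
#'
#' Nonlinear least squares over all curves jointly, sharing one `k_on`,
#' `k_off` and `r_max` across concentrations (the standard global analysis
#' of a dilution series). Start values come from a log-linear regression of
#' the pooled dissociation phases (`k_off`) and a Langmuir fit of
#' extrapolated equilibrium responses (`KD`, `r_max`); the joint objective
#' is then minimized over `(log10 k_on, log10 k_off, log10 r_max)` by
#' Nelder-Mead followed by a BFGS polish. Standard errors come from the
#' Gauss-Newton approximation at the optimum.
#'
#' @param sensorgrams list of `sensorgram` objects (>= 2 concentrations
#'   recommended; a single curve is accepted but poorly constrains `r_max`).
#' @return object of class `binding_fit`: list with `k_on` (M^-1 s^-1),
#'   `k_off` (s^-1), `r_max` (uRIU), `kd` (M), standard errors `se_k_on`,
#'   `se_k_off`, `se_r_max`, `ssr`, `residual_norm` (RMS residual, uRIU),
#'   `n_points`, and `convergence` (0 = clean optimizer exit).
#' @export
global_fit <- function(sensorgrams) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(length(sensorgrams) >= 1)
  for (sg in sensorgrams)
    if (!all(c("time_s", "response_riu", "conc_M", "phase") %in% names(sg)))
      stop("each sensorgram needs columns time_s, response_riu, conc_M, phase")
  concs <- vapply(sensorgrams, function(sg) sg$conc_M[1], numeric(1))
  if (length(unique(concs)) < 2 && length(sensorgrams) > 1)
    warning("all sensorgrams share one concentration; the global fit is ",
            "poorly conditioned")

  pred_one <- function(sg, k_on, k_off, r_max) {
    t_a <- attr(sg, "t_assoc") %||% max(sg$time_s[sg$phase == "association"])
    p <- numeric(nrow(sg))
    ia <- sg$phase == "association"
    p[ia] <- langmuir_association(sg$time_s[ia], k_on, k_off, r_max,
                                  sg$conc_M[1])
    if (any(!ia)) {
      r_end <- langmuir_association(t_a, k_on, k_off, r_max, sg$conc_M[1])
      p[!ia] <- r_end * exp(-k_off * (sg$time_s[!ia] - t_a))
    }
    p
  }
  obs <- unlist(lapply(sensorgrams, function(sg) sg$response_riu))
  predict_all <- function(k_on, k_off, r_max)
    unlist(lapply(sensorgrams, pred_one, k_on, k_off, r_max))

  start <- spr_start_values(sensorgrams)
  obj <- function(theta) {
    r <- obs - predict_all(10^theta[1], 10^theta[2], 10^theta[3])
    sum(r * r)
  }
  op <- optim(log10(start), obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  op <- optim(op$par, obj, method = "BFGS", hessian = TRUE,
              control = list(maxit = 500, reltol = 1e-14))
  theta <- unname(op$par)
  k_on <- 10^theta[1]; k_off <- 10^theta[2]; r_max <- 10^theta[3]

  n <- length(obs)
  dof <- max(n - 3, 1)
  sigma2 <- op$value / dof
  se_log <- rep(NA_real_, 3)
  cv <- tryCatch(solve(op$hessian / 2), error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(diag(cv))) || any(diag(cv) < 0)) {
    warning("ill-conditioned global fit: parameter errors unavailable")
  } else {
    se_log <- sqrt(sigma2 * diag(cv))
  }
  ln10 <- log(10)
  structure(list(
    k_on = k_on, k_off = k_off, r_max = r_max, kd = k_off / k_on,
    se_k_on = k_on * ln10 * se_log[1],
    se_k_off = k_off * ln10 * se_log[2],
    se_r_max = r_max * ln10 * se_log[3],
    ssr = op$value, residual_norm = sqrt(op$value / n),
    n_points = n, convergence = op$convergence
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 global fit (%d points):\n", x$n_points))
  cat(sprintf("  k_on  = %.4g +/- %.2g M^-1 s^-1\n", x$k_on, x$se_k_on))
  cat(sprintf("  k_off = %.4g +/- %.2g s^-1\n", x$k_off, x$se_k_off))
  cat(sprintf("  r_max = %.4g uRIU, KD = %.4g nM, RMS residual %.3g uRIU\n",
              x$r_max, x$kd * 1e9, x$residual_norm))
  invisible(x)
}

# Heuristic start values: k_off from pooled log-linear dissociation decay,
# then KD and r_max from a Langmuir fit of per-curve equilibrium responses
# extrapolated out of the association phase.
spr_start_values <- function(sensorgrams) {
  slopes <- c()
  for (sg in sensorgrams) {
    d <- sg[sg$phase == "dissociation" & sg$response_riu > 0, ]
    if (nrow(d) >= 3)
      slopes <- c(slopes, -coef(lm(log(response_riu) ~ time_s, d))[[2]])
  }
  k_off0 <- median(slopes[slopes > 0])
  if (!is.finite(k_off0) || k_off0 <= 0) k_off0 <- 1e-3

  req <- conc <- numeric()
  for (sg in sensorgrams) {
    a <- sg[sg$phase == "association", ]
    fit <- suppressWarnings(fit_association_exp(a))  # heuristic start only
    if (!is.null(fit)) {
      req <- c(req, fit$req)
      conc <- c(conc, a$conc_M[1])
    }
  }
  kd0 <- NULL
  r_max0 <- max(req, 1e-6)
  if (length(req) >= 2) {
    lf <- suppressWarnings(fit_langmuir_isotherm(req, conc))
    if (!is.null(lf) && all(unlist(lf) > 0)) {
      r_max0 <- lf$r_max
      kd0 <- lf$kd
    }
  }
  if (is.null(kd0)) kd0 <- median(vapply(sensorgrams,
                                         function(sg) sg$conc_M[1],
                                         numeric(1)))
  c(k_on = max(k_off0 / kd0, 1), k_off = k_off0, r_max = r_max0)
}

# Single-curve exponential approach to equilibrium: R(t) = Req (1 - e^{-k t}).
# Only kobs is nonlinear; Req enters linearly, so the partially linear
# Gauss-Newton variant is robust even on barely-curving low-concentration
# injections.
fit_association_exp <- function(a) {
  fit <- tryCatch(
    nls(response_riu ~ cbind(Req = 1 - exp(-k * time_s)), a,
        start = list(k = 2 / max(a$time_s)), algorithm = "plinear",
        control = nls.control(maxiter = 500, scaleOffset = 1, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  list(kobs = cf[["k"]], req = cf[[".lin.Req"]])
}

fit_langmuir_isotherm <- function(req, conc) {
  fit <- tryCatch(
    nls(req ~ cbind(R = conc / (K + conc)), start = list(K = median(conc)),
        algorithm = "plinear",
        control = nls.control(maxiter = 500, scaleOffset = 1, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  list(kd = cf[["K"]], r_max = cf[[".lin.R"]])
}

#' Equilibrium-analysis KD from a sensorgram series
#'
#' The kinetic-free route: per curve, extrapolate the equilibrium response
#' `R_eq` from the association phase (2-parameter exponential fit), then fit
#' the Langmuir isotherm `R_eq = r_max C / (KD + C)` across concentrations.
#' On clean 1:1 data this KD matches `k_off/k_on` from [global_fit()].
#'
#' @param sensorgrams list of `sensorgram` objects at >= 2 concentrations.
#' @return list with `kd` (M) and `r_max` (uRIU).
#' @export
equilibrium_fit <- function(sensorgrams) {
  stopifnot(length(sensorgrams) >= 2)
  req <- conc <- numeric()
  for (sg in sensorgrams) {
    a <- sg[sg$phase == "association", ]
    fit <- fit_association_exp(a)
    if (is.null(fit)) stop("association-phase fit failed for concentration ",
                           a$conc_M[1])
    req <- c(req, fit$req)
    conc <- c(conc, a$conc_M[1])
  }
  lf <- fit_langmuir_isotherm(req, conc)
  if (is.null(lf)) stop("Langmuir isotherm fit failed")
  list(kd = lf$kd, r_max = lf$r_max)
}
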