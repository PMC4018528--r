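# Shared fixtures: everything is computed, nothing is stored.

base_params <- function() rate_parameters()

balanced <- function() balanced_parameters(totals(), rate_parameters())

partition <- function(params = rate_parameters())
  equilibrium_partition(totals(), kd1(params), kd2(params))

# Table 1 unfertilized concentrations (uM, two decimals as printed)
table1_partition <- c(eif4e_free = 0.02, fourebp_free = 1.90,
                      eif4g_free = 1.79, complex_eb = 1.77,
                      complex_eg = 0.36)

fert_fold <- c(k_off1 = 8, k_lys_4ebp = 32.5)
rapa_fold <- c(k_off1 = 1, k_lys_4ebp = 16)

# index distance on a fold grid ("within one grid step")
grid_step_dist <- function(value, truth, grid)
  abs(match(value, grid) - match(truth, grid))

# classical RK4 oracle for the 1-D Langmuir ODE dR/dt = kon*C*(rmax-R)-koff*R
rk4_langmuir <- function(t_out, k_on, k_off, r_max, conc, r0 = 0, dt = 0.01) {
  f <- function(r) k_on * conc * (r_max - r) - k_off * r
  step <- function(r, h) {
    k1 <- f(r); k2 <- f(r + h / 2 * k1); k3 <- f(r + h / 2 * k2)
    k4 <- f(r + h * k3)
    r + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  r <- r0; t_prev <- 0
  out <- numeric(length(t_out))
  for (i in seq_along(t_out)) {
    span <- t_out[i] - t_prev
    if (span > 0) {
      n <- max(1L, as.integer(round(span / dt)))
      h <- span / n
      for (k in seq_len(n)) r <- step(r, h)
    }
    out[i] <- r
    t_prev <- t_out[i]
  }
  out
}
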