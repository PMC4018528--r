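test_that("mass-action derivatives vanish at zero state and obey stoichiometry", {
  p <- base_params()
  expect_equal(unname(rhs(species_state(), p)), rep(0, 6))

  # conservation is built into the reaction stoichiometry: the eIF4E pool
  # (free + both complexes) and the eIF4G pool (free + complex) never move
  set.seed(101)
  for (i in 1:20) {
    st <- species_state(runif(1, 0, 3), runif(1, 0, 4), runif(1, 0, 3),
                        runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 10))
    d <- rhs(st, p)
    # algebraically zero; independent rounding of each derivative leaves
    # only ~1e-17 floating-point residue
    expect_lt(abs(d[["eif4e_free"]] + d[["complex_eb"]] +
                    d[["complex_eg"]]), 1e-12)
    expect_lt(abs(d[["eif4g_free"]] + d[["complex_eg"]]), 1e-12)
  }

  expect_error(rate_parameters(k_on1 = -1), "must be >= 0")
  expect_error(species_state(eif4e_free = -0.1), ">= 0")
})

test_that("derivatives vanish at the flux-balanced unfertilized partition", {
  pb <- balanced()
  eq <- partition(pb)
  d <- rhs(eq, pb)
  expect_lt(max(abs(d[setdiff(names(d), "protein")])), 1e-9)
  # protein output rate equals k_cat_protein * [eIF4E:eIF4G]
  expect_equal(d[["protein"]],
               pb[["k_cat_protein"]] * eq[["complex_eg"]])
})

test_that("parameter ramps interpolate linearly in value and clamp", {
  ramp <- parameter_ramp(base_params(), c(k_off1 = 8), t_start = 0,
                         duration = 300)
  expect_equal(params_at_time(ramp, 0)[["k_off1"]], 2.2e-4)
  expect_equal(params_at_time(ramp, 150)[["k_off1"]], (1 + 8) / 2 * 2.2e-4)
  at_end <- params_at_time(ramp, 1e6)
  expect_equal(at_end[["k_off1"]], 8 * 2.2e-4)
  expect_equal(at_end[["k_on1"]], 9.3e-3)  # untouched parameter

  late <- parameter_ramp(base_params(), c(k_lys_4ebp = 2), t_start = 600,
                         duration = 60)
  expect_equal(unclass(params_at_time(late, 599)),
               unclass(base_params()))
})

test_that("trajectories conserve eIF4E and eIF4G pools to 1e-6 uM", {
  pb <- balanced()
  eq <- partition(pb)
  ramp <- parameter_ramp(pb, fert_fold, duration = 300)
  tr <- simulate_model(eq, ramp, seq(0, 3600, 30))
  e_pool <- tr$eif4e_free + tr$complex_eb + tr$complex_eg
  g_pool <- tr$eif4g_free + tr$complex_eg
  expect_lt(max(abs(e_pool - e_pool[1])), 1e-6)
  expect_lt(max(abs(g_pool - g_pool[1])), 1e-6)
  expect_true(all(diff(tr$protein) >= 0))

  # unfertilized baseline is a fixed point: total 4E-BP stays at 100 +/- 0.5%
  flat <- simulate_model(eq, pb, seq(0, 3600, 30))
  expect_true(all(abs(total_4ebp_pct(flat) - 100) < 0.5))
})

test_that("a zero-duration ramp is the step-change limit", {
  pb <- balanced()
  eq <- partition(pb)
  t_grid <- seq(0, 1800, 60)
  step <- simulate_model(eq, parameter_ramp(pb, fert_fold, duration = 0),
                         t_grid)
  near <- simulate_model(eq, parameter_ramp(pb, fert_fold, duration = 1e-6),
                         t_grid)
  for (sp in c("eif4e_free", "fourebp_free", "complex_eb", "complex_eg"))
    expect_equal(step[[sp]], near[[sp]], tolerance = 1e-7)
})

test_that("halving solver tolerances moves concentrations by < 0.1%", {
  pb <- balanced()
  eq <- partition(pb)
  ramp <- parameter_ramp(pb, fert_fold, duration = 300)
  t_grid <- seq(0, 3600, 300)
  a <- simulate_model(eq, ramp, t_grid, rel_tol = 1e-8, abs_tol = 1e-10)
  b <- simulate_model(eq, ramp, t_grid, rel_tol = 5e-9, abs_tol = 5e-11)
  for (sp in c("eif4e_free", "fourebp_free", "eif4g_free", "complex_eb",
               "complex_eg")) {
    denom <- pmax(abs(a[[sp]]), 1e-6)
    expect_lt(max(abs(a[[sp]] - b[[sp]]) / denom), 1e-3)
  }
})

test_that("total 4E-BP is not conserved once synthesis is blocked", {
  em <- run_scenario("emetine")
  expect_lt(min(em$pct$total_4ebp_pct), 90)
  expect_true(all(diff(em$pct$total_4ebp_pct) < 0))
})

test_that("compiled integrator agrees with the R derivative for small steps", {
  pb <- balanced()
  st <- species_state(0.5, 1.2, 0.9, 0.8, 0.4, 0)
  h <- 0.01
  tr <- simulate_model(st, pb, c(0, h))
  euler <- unclass(st) + h * rhs(st, pb)
  got <- as.numeric(tr[2, c("eif4e_free", "fourebp_free", "eif4g_free",
                            "complex_eb", "complex_eg", "protein")])
  expect_lt(max(abs(got - euler)), 1e-6)  # O(h^2) residual is ~1e-8 here
})

test_that("invalid integration inputs are rejected", {
  pb <- balanced()
  eq <- partition(pb)
  expect_error(simulate_model(eq, pb, c(0, 10, 5)), "increasing")
  expect_error(simulate_model(eq, pb, c(0, 10), rel_tol = 0), "> 0")
  expect_error(parameter_ramp(pb, c(k_off1 = -2)), "> 0")
  expect_error(parameter_ramp(pb, c(bogus = 2)), "named")
})
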