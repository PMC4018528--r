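test_that("coupled equilibria reproduce the published unfertilized partition", {
  p <- base_params()
  eq <- partition(p)
  expect_equal(round(unclass(eq)[names(table1_partition)], 2),
               table1_partition)
  # both binding equilibria hold to 1e-8 relative
  expect_lt(abs(eq[["eif4e_free"]] * eq[["fourebp_free"]] /
                  eq[["complex_eb"]] - kd1(p)) / kd1(p), 1e-8)
  expect_lt(abs(eq[["eif4e_free"]] * eq[["eif4g_free"]] /
                  eq[["complex_eg"]] - kd2(p)) / kd2(p), 1e-8)
  # pool identities
  expect_equal(eq[["eif4e_free"]] + eq[["complex_eb"]] + eq[["complex_eg"]],
               2.15, tolerance = 1e-10)
  expect_equal(eq[["fourebp_free"]] + eq[["complex_eb"]], 3.67,
               tolerance = 1e-10)
})

test_that("partition limits: single binder and vanishing affinity", {
  p <- base_params()
  # no 4E-BP: the remaining single equilibrium has a closed-form quadratic
  eq <- equilibrium_partition(totals(total_4ebp = 0), kd1(p), kd2(p))
  Etot <- 2.15; Gtot <- 2.15; K <- kd2(p)
  b <- Etot + Gtot + K
  c2_quad <- (b - sqrt(b^2 - 4 * Etot * Gtot)) / 2
  expect_equal(eq[["complex_eb"]], 0)
  expect_equal(eq[["complex_eg"]], c2_quad, tolerance = 1e-9)

  # vanishing affinity: everything free
  weak <- equilibrium_partition(totals(), 1e6, 1e6)
  expect_lt(weak[["complex_eb"]], 1e-5)
  expect_lt(weak[["complex_eg"]], 1e-5)
  expect_equal(weak[["fourebp_free"]], 3.67, tolerance = 1e-5)
})

test_that("flux balance reproduces the fertilization and rapamycin folds", {
  pb <- balanced()
  eq <- partition(pb)
  perturb <- function(fold) {
    p <- unclass(pb)
    p[names(fold)] <- p[names(fold)] * fold
    validate_rate_parameters(p)
  }
  fert <- flux_balance_steady_state(2.15, 2.15, perturb(fert_fold))
  expect_equal(fert[["complex_eg"]] / eq[["complex_eg"]], 4.2,
               tolerance = 0.05)
  rapa <- flux_balance_steady_state(2.15, 2.15, perturb(rapa_fold))
  expect_equal(rapa[["complex_eg"]] / eq[["complex_eg"]], 2.58,
               tolerance = 0.05)

  # no synthesis, positive degradation: the 4E-BP pool empties
  none <- pb; none[["k_cat_4ebp"]] <- 0
  dry <- flux_balance_steady_state(2.15, 2.15,
                                   validate_rate_parameters(none))
  expect_equal(dry[["fourebp_free"]], 0)
  expect_equal(dry[["complex_eb"]], 0)
  expect_equal(attr(dry, "total_4ebp"), 0)
})

test_that("flux balance agrees with long-horizon ODE relaxation", {
  pb <- balanced()
  eq <- partition(pb)
  p <- unclass(pb)
  p[names(fert_fold)] <- p[names(fert_fold)] * fert_fold
  stepped <- validate_rate_parameters(p)
  relax <- simulate_model(eq, stepped, c(0, 1e6))
  fb <- flux_balance_steady_state(2.15, 2.15, stepped)
  got <- as.numeric(relax[2, c("eif4e_free", "fourebp_free", "eif4g_free",
                               "complex_eb", "complex_eg")])
  expect_lt(max(abs(got - unclass(fb)[1:5])), 1e-4)
})

test_that("the balanced partition is the flux-balance special case", {
  pb <- balanced()
  eq <- partition(pb)
  fb <- flux_balance_steady_state(2.15, 2.15, pb)
  expect_lt(max(abs(unclass(fb)[1:5] - unclass(eq)[1:5])), 1e-6)
  expect_equal(attr(fb, "total_4ebp"), 3.67, tolerance = 1e-6)
})

test_that("fold changes are elementwise with undefined zero references", {
  eq <- partition()
  expect_equal(unname(fold_changes(eq, eq)[1:5]), rep(1, 5))
  ref <- species_state(complex_eg = 0.36)
  per <- species_state(complex_eg = 1.512)
  fc <- fold_changes(ref, per)
  expect_equal(fc[["complex_eg"]], 4.2)
  expect_true(is.na(fc[["eif4e_free"]]))  # zero reference, not Inf
  expect_false(any(is.infinite(fc)))
})

test_that("weakening eIF4E:4E-BP binding frees eIF4E for eIF4G", {
  p <- base_params()
  kd1_grid <- kd1(p) * c(0.25, 0.5, 1, 2, 4, 8, 32)
  c2 <- vapply(kd1_grid, function(k)
    equilibrium_partition(totals(), k, kd2(p))[["complex_eg"]], numeric(1))
  expect_true(all(diff(c2) >= 0))
})

test_that("partition scales with a common concentration factor", {
  p <- base_params()
  s <- 3.7
  a <- equilibrium_partition(totals(), kd1(p), kd2(p))
  b <- equilibrium_partition(totals(3.67 * s, 2.15 * s, 2.15 * s),
                             kd1(p) * s, kd2(p) * s)
  expect_equal(unclass(b)[1:5], unclass(a)[1:5] * s, tolerance = 1e-9)
})
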