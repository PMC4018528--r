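test_that("SSR arithmetic, pooling, and input validation", {
  tc <- timecourse(rep(c("a", "b"), each = 5),
                   rep(c(0, 10, 20, 30, 40), 2), rep(50, 10))
  expect_equal(ssr(tc, function(t) rep(50, length(t))), 0)
  expect_equal(ssr(tc, function(t) rep(51, length(t))), 10)

  # replicate order must not matter
  shuffled <- tc[c(6:10, 1:5), ]
  f <- function(t) 100 - t
  expect_equal(ssr(tc, f), ssr(shuffled, f))

  expect_error(timecourse(character(), numeric(), numeric()), "empty")
  expect_error(ssr(tc, function(t) 1), "one finite value")
})

test_that("SSR per point matches the generator noise variance", {
  tc <- gen_4ebp_timecourse("fertilization", noise_sd_pct = 5,
                            n_replicates = 50, seed = 42,
                            renormalize = FALSE)
  truth <- attr(tc, "truth")
  times <- attr(tc, "config")$sample_times_min
  pred <- function(tm) truth[match(tm, times)]
  chi2 <- ssr(tc, pred) / nrow(tc)
  expect_lt(abs(chi2 - 25), 5)  # E[chi2] = sigma^2 = 25
})

test_that("emetine fit recovers the degradation rate", {
  clean <- gen_emetine_decay(noise_sd_pct = 0, n_replicates = 1)
  fit <- fit_klys_emetine(clean)
  expect_lt(abs(fit$k_lys_4ebp / 5.9e-4 - 1), 1e-3)
  expect_false(fit$at_boundary)

  # Monte-Carlo recovery at experimental noise
  est <- vapply(1:20, function(s)
    fit_klys_emetine(gen_emetine_decay(seed = s))$k_lys_4ebp, numeric(1))
  expect_lt(abs(median(est) / 5.9e-4 - 1), 0.10)

  # degenerate input: a flat 100% course pins the rate at the lower bound
  flat <- timecourse(rep("r1", 5), c(0, 10, 20, 30, 60), rep(100, 5))
  expect_warning(flat_fit <- fit_klys_emetine(flat), "bound")
  expect_equal(flat_fit$k_lys_4ebp, 1e-6)
  expect_true(flat_fit$at_boundary)
})

test_that("synthesis-rate inference: least squares matches flux balance", {
  ls_route <- infer_kcat_4ebp(method = "least_squares")
  closed <- infer_kcat_4ebp(method = "closed_form")
  expect_lt(abs(ls_route / closed - 1), 0.01)
  # no degradation needs no synthesis
  p0 <- rate_parameters(k_lys_4ebp = 0)
  expect_equal(infer_kcat_4ebp(params = p0), 0)
})

test_that("grid search is exactly self-consistent at zero noise", {
  clean <- gen_4ebp_timecourse("fertilization", noise_sd_pct = 0,
                               n_replicates = 1)
  fit <- grid_search_fertilization(clean)
  expect_equal(fit$best$fold_koff1, 8)
  expect_equal(fit$best$fold_klys, 32.5)
  expect_equal(fit$best$ramp_min, 5)
  expect_lt(fit$best$ssr, 1e-6)
  expect_equal(nrow(fit$grid),
               length(fold_grid(1, 100, 25, include = 8)) *
                 length(fold_grid(1, 100, 25, include = 32.5)) * 15)
})

test_that("freezing the degradation axis gives a strictly worse fit", {
  tc <- gen_4ebp_timecourse("fertilization", seed = 1)
  joint <- grid_search_fertilization(tc)
  koff1_only <- grid_search_fertilization(tc, fold_klys = 1)
  # destabilization alone cannot produce the decay: raising k_off1 with
  # degradation frozen releases 4E-BP into the (stable) free pool, so the
  # frozen search collapses to "no change" with a vastly worse SSR
  expect_gt(koff1_only$best$ssr, 10 * joint$best$ssr)
})

test_that("noisy recovery lands within one grid step of the generating node", {
  kg <- fold_grid(1, 100, 25, include = 8)
  lg <- fold_grid(1, 100, 25, include = 32.5)
  for (s in 1:3) {
    fit <- grid_search_fertilization(gen_4ebp_timecourse("fertilization",
                                                         seed = s))
    expect_lte(grid_step_dist(fit$best$fold_koff1, 8, kg), 1)
    expect_lte(grid_step_dist(fit$best$fold_klys, 32.5, lg), 1)
    expect_lte(abs(fit$best$ramp_min - 5), 1)
  }
})

test_that("median recovered folds sit within one grid step across seeds", {
  kg <- fold_grid(1, 100, 25, include = 8)
  lg <- fold_grid(1, 100, 25, include = 32.5)
  best <- t(vapply(1:5, function(s) {
    fit <- grid_search_fertilization(gen_4ebp_timecourse("fertilization",
                                                         seed = s))
    c(fit$best$fold_koff1, fit$best$fold_klys, fit$best$ramp_min)
  }, numeric(3)))
  expect_lte(grid_step_dist(median(best[, 1]), 8, kg), 1)
  expect_lte(grid_step_dist(median(best[, 2]), 32.5, lg), 1)
  expect_lte(abs(median(best[, 3]) - 5), 1)
})

test_that("KD-ratio equivalence scan singles out the dissociation mechanism", {
  clean <- gen_4ebp_timecourse("fertilization", noise_sd_pct = 0,
                               n_replicates = 1)
  scan <- equivalence_scan(clean)
  # every alternative changes KD1/KD2 by exactly the target ratio
  expect_equal(scan$kd_ratio_fold, rep(8, 4))
  expect_equal(scan$parameter[which.min(scan$ssr)], "k_off1")
  # the equilibrium-equivalent alternatives are kinetically distinguishable
  expect_gt(min(scan$ssr[scan$parameter != "k_off1"]), 100)

  # flat (null) data cannot single out a mechanism: every alternative
  # misfits grossly, none is decisively better (kinetic differences remain,
  # so the SSRs are large but comparable rather than equal)
  null_tc <- gen_4ebp_timecourse("unfertilized", noise_sd_pct = 0,
                                 n_replicates = 1)
  null_scan <- equivalence_scan(null_tc)
  expect_true(all(null_scan$ssr > 1e4))
  expect_lt(max(null_scan$ssr) / min(null_scan$ssr), 2)
})

test_that("combined factor scan enumerates the constrained power-of-2 lattice", {
  clean <- gen_4ebp_timecourse("fertilization", noise_sd_pct = 0,
                               n_replicates = 1)
  scan <- combined_factor_scan(clean)
  # independent counting oracle: pairs (a+c = s) times pairs (b+d = s-3)
  pair_count <- function(s) ifelse(abs(s) <= 10, 11 - abs(s), 0)
  expected_n <- sum(vapply(-10:10, function(s)
    pair_count(s) * pair_count(s - 3), numeric(1)))
  expect_equal(nrow(scan$tuples), expected_n)
  expect_equal(expected_n, 804)

  ratio <- with(scan$tuples,
                (fold_koff1 / fold_kon1) * (fold_kon2 / fold_koff2))
  expect_equal(ratio, rep(8, nrow(scan$tuples)))

  # the pure dissociation tuple is enumerated and wins on matching data
  i8 <- with(scan$tuples, which(fold_koff1 == 8 & fold_kon1 == 1 &
                                  fold_kon2 == 1 & fold_koff2 == 1))
  expect_length(i8, 1)
  expect_equal(i8, which.min(scan$tuples$ssr))
  expect_true(all(c("parameter", "fold", "mean_ssr", "sd_ssr") %in%
                    names(scan$summary)))
})

test_that("rapamycin fit: self-consistency and ramp-speed ordering", {
  clean <- gen_4ebp_timecourse("rapamycin", noise_sd_pct = 0,
                               n_replicates = 1)
  fit <- fit_rapamycin(clean)
  expect_equal(fit$best$fold_koff1, 1)
  expect_equal(fit$best$fold_klys, 16)
  expect_equal(fit$best$ramp_min, 33)

  # a slower ramp delays the decay: higher total 4E-BP at 15 min
  slow <- run_scenario("rapamycin")
  fast <- run_scenario("rapamycin", overrides = list(duration_s = 300))
  at15 <- function(run) run$pct$total_4ebp_pct[run$pct$time_min == 15]
  expect_gt(at15(slow), at15(fast))
})

test_that("grid refinement never increases the best SSR", {
  tc <- gen_4ebp_timecourse("fertilization", seed = 1)
  coarse_k <- fold_grid(1, 100, 7, include = 8)
  coarse_l <- fold_grid(1, 100, 7, include = 32.5)
  fine_k <- sort(unique(c(coarse_k, fold_grid(1, 100, 19))))
  fine_l <- sort(unique(c(coarse_l, fold_grid(1, 100, 19))))
  coarse <- grid_search_fertilization(tc, coarse_k, coarse_l, c(3, 5, 9))
  fine <- grid_search_fertilization(tc, fine_k, fine_l, c(3, 5, 7, 9))
  expect_lte(fine$best$ssr, coarse$best$ssr)

  # optional continuous refinement can only improve on its seeding node
  ref <- grid_search_fertilization(tc, coarse_k, coarse_l, c(3, 5, 9),
                                   refine = TRUE)
  expect_lte(ref$refined$ssr, ref$best$ssr)
})
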