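test_that("individual parameters follow the allometric covariate model", {
  pop <- pk_params()
  p70 <- individual_params(70, pop)
  expect_equal(c(p70$v, p70$cl, p70$ka), c(18, 1, 0.9))
  # quarter of the reference weight, power-law arithmetic
  p <- individual_params(17.5, pop)
  expect_equal(p$v, 18 * 0.25)
  expect_equal(p$cl, 1 * 0.25^0.75)
  expect_equal(p$ka, 0.9)
  # hand-computed with nonzero etas
  p35 <- individual_params(35, pop, eta = c(0.1, -0.2, 0))
  expect_equal(p35$v, 18 * exp(0.1) * 0.5^1)
  expect_equal(p35$cl, 1 * exp(-0.2) * 0.5^0.75)
  expect_equal(p35$ka, 0.9)
})

test_that("eta draws have the specified covariance structure", {
  pop <- pk_params()
  expect_equal(draw_etas(5, pk_params(cv_v = 0, cv_cl = 0, cv_ka = 0), seed = 1),
               matrix(0, 5, 3), ignore_attr = TRUE)
  e <- draw_etas(1e5, pop, seed = 2)
  expect_equal(cor(e[, 1], e[, 2]), 0.7, tolerance = 0.015)
  expect_equal(abs(cor(e[, 2], e[, 3])), 0, tolerance = 0.02)
  # log-normal CV <-> variance identity
  expect_equal(sd(e[, 2]), sqrt(log(1 + 0.49^2)), tolerance = 0.005)
  # alternative mapping: CV used directly as SD
  e2 <- draw_etas(1e5, pk_params(iiv_mapping = "cv_as_sd"), seed = 3)
  expect_equal(sd(e2[, 2]), 0.49, tolerance = 0.005)
  expect_error(draw_etas(5, pk_params(corr_v_cl = 0.999999999)), NA)
})

test_that("closed-form concentration matches the absorption ODE system", {
  p <- individual_params(70, pk_params())
  times <- sort(c(sampling_scheme("ped_dense")$nominal_days, 0.25, 3.3, 50))
  closed <- conc_profile(times, 140, p$v, p$cl, p$ka)
  ode <- oracle_conc_ode(times, 140, p$v, p$cl, p$ka)
  expect_equal(closed, ode, tolerance = 1e-6)
  expect_equal(conc_profile(0, 140, p$v, p$cl, p$ka), 0)
  # near-degenerate ka ~ ke limit stays continuous and matches the ODE
  near <- conc_profile(times, 140, v = 10, cl = 9 - 1e-10, ka = 0.9)
  expect_equal(near, oracle_conc_ode(times, 140, 10, 9 - 1e-10, 0.9),
               tolerance = 1e-6)
})

test_that("mass balance: AUC(0, Inf) equals dose/CL", {
  p <- individual_params(42, pk_params(), eta = c(0.2, -0.1, 0.15))
  dose <- 2 * 42
  auc <- stats::integrate(function(t) conc_profile(t, dose, p$v, p$cl, p$ka),
                          0, Inf, rel.tol = 1e-9)$value
  expect_equal(auc, dose / p$cl, tolerance = 1e-4)
})

test_that("profile is unimodal with the analytic tmax and ~12.5-day half-life", {
  p <- individual_params(70, pk_params())
  ke <- p$cl / p$v
  tmax <- log(p$ka / ke) / (p$ka - ke)
  grid <- seq(0.01, 56, by = 0.01)
  cg <- conc_profile(grid, 140, p$v, p$cl, p$ka)
  expect_true(all(cg > 0))
  expect_equal(grid[which.max(cg)], tmax, tolerance = 0.01)
  expect_true(all(diff(cg[grid < tmax]) > 0))
  expect_true(all(diff(cg[grid > tmax]) < 0))
  # elimination half-life ln(2)*V/CL; 56 days spans > 4 half-lives
  t_half <- log(2) * p$v / p$cl
  expect_equal(t_half, log(2) * 18, tolerance = 1e-12)
  expect_gt(56 / t_half, 4)
})

test_that("sampling windows are centered, bounded, and zero-window is exact", {
  sch <- sampling_scheme("ped_standard")
  expect_equal(sch$nominal_days, c(1, 2, 4, 14, 28))
  exact <- realize_sampling_times(sampling_scheme("ped_sparse", window_days = 0),
                                  5, seed = 1)
  expect_equal(exact, matrix(rep(c(4, 14, 28), each = 5), 5, 3))
  tm <- realize_sampling_times(sch, 500, seed = 2)
  expect_true(all(abs(sweep(tm, 2, sch$nominal_days)) <= 0.3 + 1e-12))
  expect_true(all(t(apply(tm, 1, diff)) > 0))
  # uniform-mean oracle: mean of realized day-14 times ~ 14.0
  many <- realize_sampling_times(sch, 10000, seed = 3)
  expect_equal(mean(many[, 4]), 14, tolerance = 0.01)
})

test_that("simulate_dataset is reproducible and collapses correctly without noise", {
  cohort <- make_tiny_cohort(c(20, 40, 70))
  pop0 <- pk_params(cv_v = 0, cv_cl = 0, cv_ka = 0, sigma_prop = 0)
  sch0 <- sampling_scheme("ped_sparse", window_days = 0)
  ds <- simulate_dataset(cohort, pop0, sch0, seed = 5)
  # all noise off: DV equals the deterministic typical-profile evaluation
  for (i in 1:3) {
    p <- individual_params(cohort$weight_kg[i], pop0)
    expect_equal(ds$DV[ds$ID == i & ds$EVID == 0],
                 conc_profile(c(4, 14, 28), 2 * cohort$weight_kg[i],
                              p$v, p$cl, p$ka))
  }
  expect_equal(ds$AMT[ds$EVID == 1], 2 * cohort$weight_kg)
  expect_identical(ds, simulate_dataset(cohort, pop0, sch0, seed = 5))
  # across-subject variability at day 14 matches a 10x Monte-Carlo oracle
  pop <- pk_params()
  pool <- generate_pediatric_pool(fixture_lms, age_group("2-17"),
                                  n_per_age = 13L, seed = 6)
  sch <- sampling_scheme("ped_sparse")
  co <- sample_cohort(pool, 240, seed = 7)
  ds1 <- simulate_dataset(co, pop, sch, seed = 8)
  cv1 <- with(subset(ds1, EVID == 0 & NOMDAY == 14), sd(DV) / mean(DV))
  co10 <- sample_cohort(pool, 2400, seed = 9)
  ds10 <- simulate_dataset(co10, pop, sch, seed = 10)
  cv10 <- with(subset(ds10, EVID == 0 & NOMDAY == 14), sd(DV) / mean(DV))
  expect_equal(cv1, cv10, tolerance = 0.15)
})
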