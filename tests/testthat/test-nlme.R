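make_toy_dataset <- function(n = 3, weights = c(13, 28, 55), seed = 11,
                             pop = pk_params()) {
  cohort <- make_tiny_cohort(weights[seq_len(n)])
  simulate_dataset(cohort, pop, sampling_scheme("ped_sparse"), seed = seed)
}

test_that("individual_neg2ll matches an independent transcription", {
  pop <- pk_params()
  ds <- make_toy_dataset()
  for (id in 1:3) {
    sub <- ds[ds$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    for (eta in list(c(0, 0, 0), c(0.1, -0.2, 0.05), c(-0.4, 0.3, -0.1))) {
      expect_equal(individual_neg2ll(pop, eta, sub),
                   oracle_neg2_joint(pop, eta, sub$AMT[sub$EVID == 1],
                                     sub$WT[1], obs$TIME, obs$DV))
    }
  }
})

test_that("zero residual gives only the variance and prior terms", {
  pop <- pk_params()
  w <- 30
  p <- individual_params(w, pop)
  t_obs <- 14
  f <- conc_profile(t_obs, 2 * w, p$v, p$cl, p$ka)
  sub <- data.frame(ID = 1, TIME = c(0, t_obs), AMT = c(2 * w, NA),
                    DV = c(NA, f), EVID = c(1, 0), MDV = c(1, 0), WT = w)
  om <- eta_cov(pop)
  expect_equal(individual_neg2ll(pop, c(0, 0, 0), sub),
               log(2 * pi * (pop$sigma_prop * f)^2) + log(det(2 * pi * om)))
})

test_that("inner_ebe finds the conditional mode (grid-search oracle)", {
  pop <- pk_params()
  ds <- make_toy_dataset(n = 1, weights = 25, seed = 13)
  sub <- ds[ds$ID == 1, ]
  ebe <- inner_ebe(pop, sub)
  expect_true(ebe$converged)
  # dense 3-d grid around the mode: no grid point does better
  grid <- seq(-1.2, 1.2, by = 0.08)
  best <- Inf
  best_eta <- NULL
  obs <- sub[sub$EVID == 0, ]
  for (a in grid) for (b in grid) for (cc in grid) {
    val <- oracle_neg2_joint(pop, c(a, b, cc), sub$AMT[sub$EVID == 1],
                             sub$WT[1], obs$TIME, obs$DV)
    if (val < best) { best <- val; best_eta <- c(a, b, cc) }
  }
  expect_true(all(abs(ebe$eta - best_eta) <= 0.08))
  expect_lte(ebe$neg2ll, best + 1e-8)
  # data simulated without any noise: mode near zero (the interaction term
  # 2*log(sigma*f) biases the mode away from zero by O(sigma^2), so a small
  # residual SD is used for this property)
  pop0 <- pk_params(cv_v = 0.3, cv_cl = 0.3, cv_ka = 0.3, sigma_prop = 0.02)
  w <- 40; p0 <- individual_params(w, pop0)
  f <- conc_profile(c(4, 14, 28), 2 * w, p0$v, p0$cl, p0$ka)
  sub0 <- data.frame(ID = 1, TIME = c(0, 4, 14, 28), AMT = c(2 * w, NA, NA, NA),
                     DV = c(NA, f), EVID = c(1, 0, 0, 0), MDV = c(1, 0, 0, 0),
                     WT = w)
  expect_equal(inner_ebe(pop0, sub0)$eta, c(0, 0, 0), tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("FOCEI objective agrees with adaptive Gauss-Hermite quadrature", {
  pop <- pk_params()
  for (seed in c(11, 29)) {
    ds <- make_toy_dataset(seed = seed)
    expect_lt(abs(focei_objective(pop, ds) - oracle_agq_dataset(pop, ds, nodes = 9)),
              0.5)
  }
})

test_that("compiled and reference engines agree", {
  pop <- pk_params()
  ds <- make_toy_dataset(n = 3, seed = 17)
  expect_equal(focei_objective(pop, ds, engine = "cpp"),
               focei_objective(pop, ds, engine = "r"), tolerance = 1e-10)
  ds2 <- simulate_dataset(make_tiny_cohort(c(15, 33, 48, 61, 80)), pop,
                          sampling_scheme("ped_standard"), seed = 18)
  expect_equal(focei_objective(pop, ds2, engine = "cpp"),
               focei_objective(pop, ds2, engine = "r"), tolerance = 1e-10)
})

test_that("objective is invariant to row order and subject relabeling", {
  pop <- pk_params()
  ds <- make_toy_dataset(seed = 19)
  ref <- focei_objective(pop, ds)
  shuffled <- ds[sample(nrow(ds)), ]
  expect_equal(focei_objective(pop, shuffled), ref, tolerance = 1e-10)
  relabeled <- ds
  relabeled$ID <- c(7, 2, 9)[relabeled$ID]
  expect_equal(focei_objective(pop, relabeled), ref, tolerance = 1e-10)
})

test_that("noise-free data identify all parameters including the exponents", {
  pop0 <- pk_params(cv_v = 0, cv_cl = 0, cv_ka = 0, sigma_prop = 0)
  pool <- generate_pediatric_pool(fixture_lms, age_group("2-17"),
                                  n_per_age = 2L, seed = 31)
  cohort <- sample_cohort(pool, 50, seed = 32)
  ds <- simulate_dataset(cohort, pop0,
                         sampling_scheme("ped_dense", window_days = 0),
                         seed = 33)
  fit <- fit_nlme(ds, estimation_spec())
  expect_true(fit$converged)
  expect_equal(fit$estimates$tv_v, 18, tolerance = 1e-3)
  expect_equal(fit$estimates$tv_cl, 1, tolerance = 1e-3)
  expect_equal(fit$estimates$tv_ka, 0.9, tolerance = 1e-3)
  expect_equal(fit$exp_v, 1.0, tolerance = 1e-3)
  expect_equal(fit$exp_cl, 0.75, tolerance = 1e-3)
})

test_that("fixing the exponents is a nested (never better) model", {
  pop <- pk_params()
  pool <- generate_pediatric_pool(fixture_lms, age_group("2-17"),
                                  n_per_age = 2L, seed = 41)
  ds <- simulate_dataset(sample_cohort(pool, 40, seed = 42), pop,
                         sampling_scheme("ped_standard"), seed = 43)
  fixed <- fit_nlme(ds, estimation_spec(estimate_exp_v = FALSE,
                                        estimate_exp_cl = FALSE))
  expect_true(fixed$converged)
  expect_identical(fixed$exp_v, 1.0)
  expect_identical(fixed$exp_cl, 0.75)
  # free fit started from the fixed solution cannot be worse
  free <- fit_nlme(ds, estimation_spec(init = list(
    tv_v = fixed$estimates$tv_v, tv_cl = fixed$estimates$tv_cl,
    tv_ka = fixed$estimates$tv_ka, exp_v = 1.0, exp_cl = 0.75,
    sd_v = max(sqrt(log(1 + fixed$estimates$cv_v^2)), 0.01),
    sd_cl = max(sqrt(log(1 + fixed$estimates$cv_cl^2)), 0.01),
    sd_ka = max(sqrt(log(1 + fixed$estimates$cv_ka^2)), 0.01),
    corr_v_cl = fixed$estimates$corr_v_cl,
    sigma = fixed$estimates$sigma_prop)))
  expect_lte(free$objective, fixed$objective + 1e-6)
})

test_that("fixing exponents at truth stabilizes the other estimates on sparse small-n data", {
  reps <- 8
  free_cl <- fixed_cl <- numeric(0)
  for (r in seq_len(reps)) {
    sp <- scenario_spec("2-5", n_pediatric = 30, scheme = "ped_sparse",
                        n_replicates = 1, master_seed = 500 + r)
    seeds <- pedallo:::replicate_seeds(sp, 1)
    pool <- generate_pediatric_pool(sp$lms_table, sp$age_group,
                                    seed = seeds$ped_pool)
    ds <- simulate_dataset(sample_cohort(pool, 30, seed = seeds$ped_cohort),
                           sp$pop, sp$scheme, seed = seeds$ped_sim)
    f1 <- fit_nlme(ds, estimation_spec(), seed = 1)
    f2 <- fit_nlme(ds, estimation_spec(estimate_exp_v = FALSE,
                                       estimate_exp_cl = FALSE), seed = 1)
    if (f1$converged) free_cl <- c(free_cl, f1$estimates$tv_cl)
    if (f2$converged) fixed_cl <- c(fixed_cl, f2$estimates$tv_cl)
  }
  expect_gte(length(free_cl), 5)
  expect_gte(length(fixed_cl), 5)
  expect_lt(var(fixed_cl), var(free_cl))
})
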