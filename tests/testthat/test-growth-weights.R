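test_that("lms_weight evaluates the Box-Cox quantile form", {
  # z = 0 returns the median for any parameter set
  expect_equal(lms_weight(0, L = -1.5, M = 20, S = 0.12), 20)
  expect_equal(lms_weight(0, L = 2, M = 55, S = 0.2), 55)
  # L = 1 reduces to M * (1 + z*S)
  expect_equal(lms_weight(2, L = 1, M = 20, S = 0.1), 24)
  # direct quantile-formula oracle at the 97th percentile (z = 1.881)
  rec <- fixture_lms[fixture_lms$age_months == 120, ]
  expect_equal(lms_weight(1.881, rec$L, rec$M, rec$S),
               rec$M * (1 + 1.881 * rec$L * rec$S)^(1 / rec$L))
  # domain error outside the chart's percentile range
  expect_error(lms_weight(10, L = -1.5, M = 20, S = 0.12), "percentile range")
})

test_that("lms_weight is strictly increasing in z and has the log-normal limit", {
  zs <- seq(-3.5, 3.5, by = 0.25)
  for (i in c(1, 50, 100, 150, nrow(fixture_lms))) {
    rec <- fixture_lms[i, ]
    w <- lms_weight(zs, rec$L, rec$M, rec$S)
    expect_true(all(diff(w) > 0))
  }
  # L -> 0 converges to M * exp(z*S)
  expect_equal(lms_weight(zs, L = 1e-6, M = 30, S = 0.15),
               30 * exp(zs * 0.15), tolerance = 1e-4)
  expect_equal(lms_weight(zs, L = 0, M = 30, S = 0.15), 30 * exp(zs * 0.15))
})

test_that("pediatric pools have the right size, median, and nesting", {
  pool25 <- generate_pediatric_pool(fixture_lms, age_group("2-5"), seed = 11)
  expect_equal(nrow(pool25), 48 * 100)
  full <- generate_pediatric_pool(fixture_lms, age_group("2-17"), seed = 11)
  expect_equal(nrow(full), 192 * 100)
  # nesting: same seed implies identical draws for shared months
  expect_equal(full$weight_kg[full$age_months <= 71], pool25$weight_kg)
  mid <- generate_pediatric_pool(fixture_lms, age_group("6-11"), seed = 11)
  old <- generate_pediatric_pool(fixture_lms, age_group("12-17"), seed = 11)
  expect_equal(full$weight_kg,
               c(pool25$weight_kg, mid$weight_kg, old$weight_kg))
  # pool median per age-month ~ M (Monte-Carlo tolerance at n = 100/month)
  rec <- fixture_lms[fixture_lms$age_months == 60, ]
  big <- generate_pediatric_pool(fixture_lms[fixture_lms$age_months == 60, ],
                                 list(label = "m60", lo = 60L, hi = 60L),
                                 n_per_age = 4000L, seed = 12)
  expect_equal(median(big$weight_kg), rec$M, tolerance = 0.02)
  # missing month is a configuration error
  gap <- fixture_lms[fixture_lms$age_months != 100, ]
  expect_error(generate_pediatric_pool(gap, age_group("2-17"), seed = 1),
               "missing age-month")
})

test_that("2-5 pool weights stay below the adult range even at extreme z", {
  rec <- fixture_lms[fixture_lms$age_months %in% 24:71, ]
  w4 <- lms_weight(rep(4, nrow(rec)), rec$L, rec$M, rec$S)
  expect_true(all(w4 < 60))
})

test_that("cohort sampling is without replacement, seeded, and uniform", {
  pool <- generate_pediatric_pool(fixture_lms, age_group("2-5"),
                                  n_per_age = 10L, seed = 3)
  expect_error(sample_cohort(pool, nrow(pool) + 1), "pool of")
  all_of_it <- sample_cohort(pool, nrow(pool), seed = 4)
  expect_setequal(all_of_it$id, pool$id)
  s1 <- sample_cohort(pool, 30, seed = 5)
  expect_identical(s1, sample_cohort(pool, 30, seed = 5))
  expect_false(setequal(s1$id, sample_cohort(pool, 30, seed = 6)$id))
  # inclusion frequency ~ Binomial(reps, n/N)
  reps <- 600
  counts <- integer(nrow(pool))
  for (r in seq_len(reps)) {
    counts[sample_cohort(pool, 60, seed = 1000 + r)$id] <-
      counts[sample_cohort(pool, 60, seed = 1000 + r)$id] + 1L
  }
  p <- 60 / nrow(pool)
  expect_equal(mean(counts) / reps, p, tolerance = 1e-9) # exact by construction
  expect_lt(max(abs(counts / reps - p)), 5 * sqrt(p * (1 - p) / reps))
})

test_that("adult population is truncated-normal with the closed-form mean", {
  adults <- generate_adult_population(seed = 21)
  expect_equal(nrow(adults), 200)
  expect_true(all(adults$weight_kg >= 60 & adults$weight_kg <= 110))
  expect_true(all(is.na(adults$age_months)))
  expect_identical(adults, generate_adult_population(seed = 21))
  # closed-form truncated-normal mean oracle
  a <- (60 - 70) / 10; b <- (110 - 70) / 10
  mu_trunc <- 70 + 10 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  big <- generate_adult_population(n = 20000, seed = 22)
  sd_trunc <- sd(big$weight_kg)
  expect_equal(mean(big$weight_kg), mu_trunc,
               tolerance = 3 * sd_trunc / sqrt(20000) / mu_trunc)
  # adult study arm sampling
  arm <- sample_adult_study(adults, seed = 23)
  expect_equal(nrow(arm), 20)
  expect_true(all(arm$id %in% adults$id))
})
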