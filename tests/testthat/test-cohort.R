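test_that("cohorts are a deterministic function of the seed", {
  a <- generate_cohort(small_pop, seed = 7)
  b <- generate_cohort(small_pop, seed = 7)
  expect_identical(a, b)
  c2 <- generate_cohort(small_pop, seed = 8)
  expect_false(identical(a, c2))
})

test_that("zero prevalence yields an all-healthy screened cohort", {
  pop <- population_params(cohort_size = 1000L, prevalence = 0)
  coh <- generate_cohort(pop, seed = 3)
  expect_true(all(coh$true_status[coh$prescreen != "TREATED"] == "HEALTHY"))
})

test_that("affected and prescreen counts land within binomial bands", {
  coh <- generate_cohort(default_pop, seed = 11)
  n <- default_pop$cohort_size
  # affected among the screening cohort: Binomial(n, 0.038)
  n_aff <- sum(coh$true_status != "HEALTHY" & coh$prescreen != "TREATED")
  expect_lt(abs(n_aff - n * 0.038), 3 * sqrt(n * 0.038 * 0.962))
  # removed at prescreen: Binomial(n, 0.0031), expectation ~7
  n_rm <- sum(coh$prescreen == "TREATED")
  expect_lt(abs(n_rm - n * 0.0031), 3 * sqrt(n * 0.0031 * (1 - 0.0031)))
  # prescreen-treated children are true cases
  expect_true(all(coh$true_status[coh$prescreen == "TREATED"] != "HEALTHY"))
  # distances within the configured range
  expect_true(all(coh$distance_km_ihc >= 4 & coh$distance_km_ihc <= 7))
  expect_true(all(coh$arrival_month >= 0 & coh$arrival_month < 18))
})

test_that("marginal frequencies converge to the parameters at n = 100,000", {
  pop <- population_params(cohort_size = 100000L)
  coh <- generate_cohort(pop, seed = 5)
  n <- pop$cohort_size
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(coh$region == "URBAN") - 2 / 3), se3(2 / 3))
  keep <- coh$prescreen != "TREATED"
  expect_lt(abs(mean(coh$true_status[keep] != "HEALTHY") - 0.038),
            se3(0.038))
  expect_lt(abs(mean(coh$prescreen == "TREATED") - 0.0031), se3(0.0031))
  expect_lt(abs(mean(coh$prescreen == "REFERRED") - 0.0030), se3(0.0030))
  # Graf mix among affected follows the renormalized proportions
  aff <- coh$true_status[keep & coh$true_status != "HEALTHY"]
  mix <- c(0.014, 0.015, 0.005) / 0.034
  obs <- table(factor(aff, levels = c("TYPE_2BC", "TYPE_D", "TYPE_34")))
  expect_lt(max(abs(obs / length(aff) - mix)),
            3 * sqrt(0.5 * 0.5 / length(aff)))
})

test_that("conditional error rates invert the per-screened-child proportions", {
  r <- conditional_rates(fp_rate = 0.013, miss_rate = 0.006,
                         prevalence = 0.038)
  expect_equal(r$miss_given_affected, 0.1578947, tolerance = 1e-6)
  expect_equal(r$fp_given_healthy, 0.01351351, tolerance = 1e-6)
  r <- conditional_rates(fp_rate = 0.006, miss_rate = 0.003,
                         prevalence = 0.038)
  expect_equal(r$miss_given_affected, 0.07894737, tolerance = 1e-6)
  expect_equal(r$fp_given_healthy, 0.006237006, tolerance = 1e-6)
  # exact inversion for every screener profile
  for (i in seq_len(nrow(screener_profiles()))) {
    prof <- screener_profiles()[i, ]
    r <- conditional_rates(prof, prevalence = 0.038)
    expect_equal(r$miss_given_affected * 0.038, prof$miss_rate,
                 tolerance = 1e-15)
    expect_equal(r$fp_given_healthy * (1 - 0.038), prof$fp_rate,
                 tolerance = 1e-15)
  }
  expect_equal(conditional_rates(fp_rate = 0.01, miss_rate = 0,
                                 prevalence = 0.038)$miss_given_affected, 0)
  expect_error(conditional_rates(fp_rate = 0.01, miss_rate = 0.05,
                                 prevalence = 0.038), "inconsistent")
})

test_that("invalid population parameters are rejected", {
  expect_error(population_params(prevalence = 1.5), "\\[0, 1\\]")
  expect_error(population_params(cohort_size = 0), "cohort_size")
  expect_error(population_params(prescreen_referral = 0.001,
                                 prescreen_treated = 0.002), "prescreen")
})
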