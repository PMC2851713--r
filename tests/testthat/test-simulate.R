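test_that("attendance through invitation and reminder matches the region rates", {
  n <- 50000L
  set.seed(101)
  rural <- attendance_draw(rep("RURAL", n), default_pop)
  urban <- attendance_draw(rep("URBAN", n), default_pop)
  # overall screening probabilities: 0.90 + 0.10 x 0.90 and 0.85 + 0.15 x 0.80
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(rural$attended) - 0.99), se3(0.99))
  expect_lt(abs(mean(urban$attended) - 0.97), se3(0.97))
  expect_true(all(!rural$after_reminder | rural$attended))

  sure <- population_params(attendance = c(URBAN = 1, RURAL = 1))
  set.seed(1)
  all_in <- attendance_draw(rep("URBAN", 1000L), sure)
  expect_true(all(all_in$attended))
  expect_true(!any(all_in$after_reminder))
})

test_that("classification follows the latent status and the test result", {
  expect_equal(classify("TYPE_D", TRUE), "TP")
  expect_equal(classify("HEALTHY", TRUE), "FP")
  expect_equal(classify("TYPE_34", FALSE), "FN")
  expect_equal(classify("HEALTHY", FALSE), "TN")
  expect_equal(classify(c("TYPE_2BC", "HEALTHY"), c(FALSE, FALSE)),
               c("FN", "TN"))
})

test_that("per-child outcomes conserve counts and itemized costs", {
  sp <- spec_of("NONE", "INTEGRATED", "RADIOGRAPHIC_TECHNICIAN", "EXTERNAL")
  coh <- generate_cohort(default_pop, seed = 9)
  out <- screen_cohort(coh, sp, default_pop, default_costs)
  cls <- table(factor(out$classification,
                      c("TP", "FP", "FN", "TN", "NOT_SCREENED")))
  expect_equal(sum(cls[c("TP", "FP", "FN", "TN")]), sum(out$attended))
  expect_equal(cls[["TP"]] + cls[["FN"]],
               sum(coh$true_status != "HEALTHY" & out$attended))
  # breakdown additivity, exact
  expect_identical(out$cost_total,
                   out$prescreen_cost + out$staff + out$travel +
                     out$parent_time + out$machine_use + out$rent +
                     out$downstream)
  expect_true(all(out$classification[!out$attended] == "NOT_SCREENED"))
  expect_true(all(out$cost_total >= 0))
})

test_that("scenario simulation is bit-identical under the same seed", {
  sp <- spec_of("LIMITED", "EXTRA", "IHC_NURSE", "IHC_DAYTIME")
  a <- simulate_scenario(sp, small_pop, default_costs, n_reps = 8, seed = 13)
  b <- simulate_scenario(sp, small_pop, default_costs, n_reps = 8, seed = 13)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_scenario(sp, small_pop, default_costs, n_reps = 8, seed = 14)
  expect_false(identical(a$mean_total_cost, c2$mean_total_cost))
})

test_that("simulated means track the closed-form oracle", {
  for (sp in list(spec_of("MANY", "EXTRA", "IHC_PHYSICIAN", "EXTERNAL"),
                  spec_of("NONE", "INTEGRATED", "IHC_NURSE", "IHC_DAYTIME"))) {
    sim <- simulate_scenario(sp, default_pop, default_costs,
                             n_reps = 200, seed = 42)
    exp <- expected_scenario(sp, default_pop, default_costs)
    for (q in c("total_cost", "tp", "fp", "fn")) {
      mu_sim <- switch(q, total_cost = sim$mean_total_cost,
                       tp = sim$mean_detected, fp = sim$mean_fp,
                       fn = sim$mean_missed)
      mu_exp <- switch(q, total_cost = exp$mean_total_cost,
                       tp = exp$mean_detected, fp = exp$mean_fp,
                       fn = exp$mean_missed)
      se <- sim$sd[[q]] / sqrt(sim$n_reps)
      expect_lt(abs(mu_sim - mu_exp), 3 * se)
    }
  }
})

test_that("the analytic engine reproduces the screening test characteristics", {
  # technician screener: expected TP share of screened children is 3.2%
  sp <- spec_of("LIMITED", "INTEGRATED", "RADIOGRAPHIC_TECHNICIAN",
                "IHC_DAYTIME")
  e <- expected_scenario(sp, default_pop, default_costs)
  expect_equal(e$mean_detected / e$mean_screened, 0.032, tolerance = 1e-12)
  expect_equal(e$mean_missed / e$mean_screened, 0.006, tolerance = 1e-12)
  expect_equal(e$mean_fp / e$mean_screened, 0.013, tolerance = 1e-12)
  # perfect attendance, universal disease, perfect test: everyone remaining
  # after the prescreen stage is detected
  all_pop <- population_params(prevalence = 1,
                               graf_mix = c(TYPE_2BC = 1, TYPE_D = 0,
                                            TYPE_34 = 0),
                               attendance = c(URBAN = 1, RURAL = 1))
  perfect <- data.frame(discipline = "IHC_NURSE", wage_per_hour = 42,
                        fp_rate = 0, miss_rate = 0)
  e <- expected_scenario(scenario_from_id(28), all_pop, default_costs,
                         profile = perfect)
  expect_equal(e$mean_detected, 2300 * (1 - 0.0031), tolerance = 1e-9)
})

test_that("degenerate parameters make the CE ratio error out", {
  none <- population_params(prevalence = 0)
  perfect <- data.frame(discipline = "IHC_NURSE", wage_per_hour = 42,
                        fp_rate = 0, miss_rate = 0)
  expect_error(expected_scenario(scenario_from_id(1), none, default_costs,
                                 profile = perfect), "degenerate")
  expect_error(simulate_current(small_pop, default_costs, n_reps = 3,
                                seed = 1,
                                comparator = comparator_params(
                                  missed_rate = 0, fp_rate = 0,
                                  tp_rate = 0)), "degenerate")
})

test_that("the current-screening comparator reproduces its referral profile", {
  pop <- population_params(cohort_size = 50000L)
  cur <- simulate_current(pop, default_costs, n_reps = 4, seed = 21)
  fp_share <- cur$mean_fp / cur$mean_screened
  se3 <- 3 * sqrt(0.165 * (1 - 0.165) / (4 * cur$mean_screened))
  expect_lt(abs(fp_share - 0.165), se3)
  # share of referred children in whom DDH is refuted: 0.165 / 0.193
  refuted <- cur$mean_fp / (cur$mean_fp + cur$mean_detected)
  expect_lt(abs(refuted - 0.165 / 0.193), 0.01)
  # analytic comparator agrees in expectation
  e <- expected_current(pop, default_costs)
  expect_equal(e$mean_fp / e$mean_screened, 0.165, tolerance = 1e-12)
  expect_equal(e$mean_detected / e$mean_screened, 0.028, tolerance = 1e-12)
})

test_that("raising a per-child cost never lowers the mean total cost", {
  sp <- spec_of("LIMITED", "EXTRA", "RADIOGRAPHIC_TECHNICIAN", "IHC_EVENING")
  base <- simulate_scenario(sp, small_pop, default_costs, n_reps = 5,
                            seed = 17)
  for (par in c("missed_case_cost", "parent_time_per_hour", "km_rate",
                "treat_2bc")) {
    up <- cost_params()
    up[[par]] <- up[[par]] * 1.5
    bumped <- simulate_scenario(sp, small_pop, up, n_reps = 5, seed = 17)
    expect_gte(bumped$mean_total_cost, base$mean_total_cost)
  }
})
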