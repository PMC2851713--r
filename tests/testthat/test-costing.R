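# Independent amortization oracle: pay `pay` per period on a balance earning
# interest r; a correct annuity drives the final balance to zero.
amortize_balance <- function(principal, r, n, pay) {
  bal <- principal
  for (i in seq_len(n)) bal <- bal * (1 + r) - pay
  bal
}

test_that("annuity payments agree with the closed form and the amortization oracle", {
  cases <- list(c(32725, 0.05, 5), c(1000, 0.10, 2), c(5000, 0.03, 10),
                c(1, 0.2, 1))
  for (cs in cases) {
    pay <- annuity_payment(cs[1], cs[2], cs[3])
    expect_lt(abs(amortize_balance(cs[1], cs[2], cs[3], pay)), 1e-6)
  }
  expect_equal(annuity_payment(1000, 0, 4), 250)
  expect_equal(annuity_payment(1000, 0.10, 2), 576.1905, tolerance = 1e-6)
  # machine annuity rounds to the tabulated figure
  expect_equal(round(annuity_payment(32725, 0.05, 5), -1), 7560)
  expect_error(annuity_payment(1000, 0.05, 0), "n_periods")
})

test_that("machine ownership costs reproduce the tabulated yearly figures", {
  expect_equal(0.08 * 32725, 2618) # maintenance
  expect_equal(machine_annual_cost(default_costs), 11178)
  expect_equal(machine_cost_per_child(default_costs, 2300, 1), 11178 / 2300)
  expect_equal(round(machine_cost_per_child(default_costs, 2300, 1)), 5)
  expect_equal(machine_cost_per_child(default_costs, 2300, 0), 0)
  expect_equal(machine_cost_per_child(default_costs, 2300, 7), 34.02)
  expect_error(machine_cost_per_child(default_costs, 0, 1), "cohort_size")
})

test_that("training costs scale with screeners and match the rounded figure", {
  expect_equal(training_cost(1, default_costs), 1300)
  expect_equal(training_cost(7, default_costs), 9100)
  # components: 16 h x 73 + 130 = 1298, tabulated at the nearest hundred
  comp <- default_costs$training_hours * default_costs$training_wage +
    default_costs$training_materials
  expect_equal(comp, 1298)
  expect_equal(round(comp, -2), default_costs$training_cost_per_screener)
  expect_error(training_cost(0, default_costs), "n_screeners")
})

test_that("exam staff costs apply presence, doubling and evening rules", {
  cost_of <- function(m, co, s, l) {
    sp <- spec_of(m, co, s, l)
    exam_staff_cost(staffing_plan(sp), sp, default_costs)
  }
  expect_equal(cost_of("LIMITED", "INTEGRATED", "IHC_PHYSICIAN",
                       "IHC_DAYTIME"), 75 / 6)
  # physician present alongside the technician (integrated consultation)
  expect_equal(cost_of("LIMITED", "INTEGRATED", "RADIOGRAPHIC_TECHNICIAN",
                       "IHC_DAYTIME"), 70 / 6 + 75 / 6)
  # extra consultation doubles, evening adds 35%
  expect_equal(cost_of("LIMITED", "EXTRA", "IHC_NURSE", "IHC_EVENING"),
               2 * (42 / 6) * 1.35)
  # delegation: nurse replaces the physician, nothing added
  expect_equal(cost_of("LIMITED", "INTEGRATED", "IHC_NURSE", "IHC_DAYTIME"),
               42 / 6)
  # no presence requirement under an extra consultation
  expect_equal(cost_of("LIMITED", "EXTRA", "MEDICAL_SPECIALIST",
                       "IHC_DAYTIME"), 2 * 106 / 6)
})

test_that("exam staff cost is monotone in every wage", {
  wages <- c("wage_physician", "wage_nurse", "wage_rt", "wage_specialist")
  for (sp in enumerate_scenarios()[c(1, 20, 40, 60, 72)]) {
    plan <- staffing_plan(sp)
    base <- exam_staff_cost(plan, sp, default_costs)
    for (w in wages) {
      up <- cost_params()
      up[[w]] <- up[[w]] + 10
      expect_gte(exam_staff_cost(plan, sp, up), base)
    }
  }
})

test_that("visit overheads cover travel, parent time, rent and machine use", {
  v <- function(m, co, l, d = 5) {
    sp <- spec_of(m, co, "IHC_PHYSICIAN", l)
    out <- visit_overhead_costs(d, sp, default_costs)
    sum(out$travel, out$parent_time, out$rent, out$machine_use)
  }
  expect_equal(v("LIMITED", "INTEGRATED", "IHC_DAYTIME"), 5 * 0.2 + 36)
  expect_equal(v("LIMITED", "EXTRA", "IHC_DAYTIME"), 2 * 1 + 2 * 36)
  # external site, no machines owned: fixed 10 km, rent, hospital usage fee
  expect_equal(v("NONE", "INTEGRATED", "EXTERNAL"),
               10 * 0.2 + 36 + 5 + 61 / 6)
  expect_equal(v("LIMITED", "INTEGRATED", "EXTERNAL"), 10 * 0.2 + 36 + 5)
})

test_that("an extra consultation never costs less than an integrated one", {
  for (m in c("MANY", "LIMITED", "NONE"))
    for (s in c("IHC_PHYSICIAN", "MEDICAL_SPECIALIST"))
      for (l in c("IHC_DAYTIME", "EXTERNAL", "IHC_EVENING")) {
        int <- spec_of(m, "INTEGRATED", s, l)
        ext <- spec_of(m, "EXTRA", s, l)
        per_child <- function(sp) {
          ov <- visit_overhead_costs(5.5, sp, default_costs)
          exam_staff_cost(staffing_plan(sp), sp, default_costs) +
            ov$travel + ov$parent_time + ov$rent + ov$machine_use
        }
        expect_gte(per_child(ext), per_child(int))
      }
})

test_that("downstream costs follow the classification and Graf type", {
  expect_equal(downstream_cost("TP", "TYPE_2BC", default_costs), 897)
  expect_equal(downstream_cost("TP", "TYPE_D", default_costs), 717)
  expect_equal(downstream_cost("TP", "TYPE_34", default_costs), 2043)
  expect_equal(downstream_cost("FN", "TYPE_34", default_costs), 1217)
  expect_equal(downstream_cost("FP", NA, default_costs), 97)
  expect_equal(downstream_cost("TN", NA, default_costs), 0)
  expect_equal(downstream_cost(c("TP", "FN", "TN"),
                               c("TYPE_2BC", NA, NA), default_costs),
               c(897, 1217, 0))
  expect_error(downstream_cost("TP", NA, default_costs), "Graf")
})

test_that("the evening flat-fee variant replaces the wage uplift", {
  flat <- cost_params(evening_flat_fee = TRUE)
  sp <- spec_of("LIMITED", "INTEGRATED", "IHC_NURSE", "IHC_EVENING")
  plan <- staffing_plan(sp)
  expect_equal(exam_staff_cost(plan, sp, flat), 42 / 6)
  ov <- visit_overhead_costs(5, sp, flat)
  expect_equal(ov$rent, 5) # the flat EUR 5 per child
})

test_that("unknown or invalid cost parameters are rejected", {
  expect_error(cost_params(no_such_cost = 1), "unknown")
  expect_error(cost_params(wage_nurse = -1), ">= 0")
  expect_error(cost_params(evening_uplift = 2), "\\[0, 1\\]")
})
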