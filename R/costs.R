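# Itemized societal cost engine: wages per ten-minute exam, parent time,
# travel, machine annuity/insurance/maintenance, training, treatment by Graf
# type, and the costs of false positives and missed cases. All values in 2006
# euros.

#' Unit costs and economic constants
#'
#' Defaults are the study's printed point estimates: hourly wages per
#' discipline, the hospital ultrasound rate, parents' productivity loss,
#' travel at EUR 0.20/km, the EUR 32,725 machine amortized over five years at
#' 5% interest with EUR 1,000/yr insurance and maintenance at 8% of the
#' purchase price, EUR 1,300 training per screener (16 h at EUR 73 plus
#' EUR 130 materials, rounded), treatment costs per Graf type, the EUR 1,217
#' missed-case treatment cost, and the EUR 61 + EUR 36 false-positive visit.
#'
#' Two quantities are not printed and are configuration knobs: the rent per
#' child at an external location (default EUR 5) and the handling of evening
#' sessions. The text applies a 35% wage uplift in the evening while the cost
#' table prints a flat EUR 5/child overhead (35% of the average EUR 73 wage
#' per ten-minute exam -- the same quantity); the uplift is the default and
#' `evening_flat_fee = TRUE` switches to the flat fee instead.
#'
#' @param ... named overrides of any default listed below.
#' @return A validated list of class `ddh_costs`.
#' @export
#' @examples
#' cost_params(rent_per_child_external = 10)
cost_params <- function(...) {
  costs <- list(
    wage_physician = 75,
    wage_nurse = 42,
    wage_rt = 70,
    wage_specialist = 106,
    hospital_us_per_hour = 61,
    parent_time_per_hour = 36,
    km_rate = 0.20,
    external_distance_km = 10,
    machine_price = 32725,
    machine_insurance_per_year = 1000,
    maintenance_fraction = 0.08,
    machine_life_years = 5L,
    interest_rate = 0.05,
    exam_minutes = 10,
    training_hours = 16,
    training_wage = 73,
    training_materials = 130,
    training_cost_per_screener = 1300,
    evening_uplift = 0.35,
    evening_flat_fee = FALSE,
    evening_flat_per_child = 5,
    treat_first_consult = 571,
    treat_2bc = 897,
    treat_D = 717,
    treat_34 = 2043,
    missed_case_cost = 1217,
    fp_visit_cost = 61 + 36,
    rent_per_child_external = 5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(costs))
  if (length(unknown))
    stop("unknown cost parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  costs[names(over)] <- over
  validate_costs(costs)
  class(costs) <- "ddh_costs"
  costs
}

validate_costs <- function(costs) {
  money <- setdiff(names(costs),
                   c("maintenance_fraction", "interest_rate", "evening_uplift",
                     "evening_flat_fee", "exam_minutes", "machine_life_years",
                     "external_distance_km", "training_hours"))
  vals <- unlist(costs[money])
  if (anyNA(vals) || any(vals < 0))
    stop("all monetary cost values must be >= 0", call. = FALSE)
  for (r in c("maintenance_fraction", "interest_rate", "evening_uplift")) {
    if (costs[[r]] < 0 || costs[[r]] > 1)
      stop(r, " must lie in [0, 1]", call. = FALSE)
  }
  if (costs$exam_minutes <= 0) stop("exam_minutes must be > 0", call. = FALSE)
  invisible(costs)
}

wage_for <- function(screener, costs) {
  switch(screener,
    IHC_PHYSICIAN = costs$wage_physician,
    IHC_NURSE = costs$wage_nurse,
    RADIOGRAPHIC_TECHNICIAN = costs$wage_rt,
    MEDICAL_SPECIALIST = costs$wage_specialist,
    stop("unknown screener: ", screener, call. = FALSE)
  )
}

#' Annuity payment amortizing a principal
#'
#' Constant per-period payment repaying `principal` over `n_periods` at
#' interest `rate_per_period`: `principal * r / (1 - (1 + r)^-n)`, or
#' `principal / n` at zero interest.
#'
#' @param principal amount financed (euros).
#' @param rate_per_period interest rate per period (proportion).
#' @param n_periods number of periods (>= 1).
#' @return Payment per period, euros (unrounded).
#' @export
#' @examples
#' annuity_payment(32725, 0.05, 5) # ~7558.6, tabulated as 7560
annuity_payment <- function(principal, rate_per_period, n_periods) {
  if (n_periods < 1) stop("n_periods must be >= 1", call. = FALSE)
  if (rate_per_period < 0) stop("rate must be >= 0", call. = FALSE)
  if (rate_per_period == 0) return(principal / n_periods)
  principal * rate_per_period / (1 - (1 + rate_per_period)^(-n_periods))
}

#' Annual ownership cost of one ultrasound machine
#'
#' Annuity on the purchase price (rounded to the nearest EUR 10, the
#' convention of the tabulated EUR 7,560 figure) plus insurance plus
#' maintenance at `maintenance_fraction` of the purchase price. With
#' defaults: 7560 + 1000 + 2618 = EUR 11,178 per year.
#'
#' @param costs a `ddh_costs`.
#' @return Euros per machine per year.
#' @export
machine_annual_cost <- function(costs) {
  ann <- annuity_payment(costs$machine_price, costs$interest_rate,
                         costs$machine_life_years)
  round(ann, -1) + costs$machine_insurance_per_year +
    costs$maintenance_fraction * costs$machine_price
}

#' Machine ownership cost averaged per child
#'
#' One year's ownership cost of the purchased machines divided by the full
#' cohort: with one machine and 2,300 children, 11178 / 2300 = EUR 4.86,
#' tabulated as EUR 5 per child.
#'
#' @param costs a `ddh_costs`.
#' @param cohort_size number of children (>= 1).
#' @param n_machines machines purchased (>= 0).
#' @return Euros per child.
#' @export
machine_cost_per_child <- function(costs, cohort_size, n_machines) {
  if (cohort_size < 1) stop("cohort_size must be >= 1", call. = FALSE)
  if (n_machines < 0) stop("n_machines must be >= 0", call. = FALSE)
  n_machines * machine_annual_cost(costs) / cohort_size
}

#' Total training cost for the screeners of a scenario
#'
#' Each trained screener costs `training_cost_per_screener` (default the
#' tabulated EUR 1,300, the rounded value of 16 h x EUR 73 + EUR 130 = 1,298).
#'
#' @param n_screeners number trained (>= 1).
#' @param costs a `ddh_costs`.
#' @return Euros.
#' @export
training_cost <- function(n_screeners, costs = cost_params()) {
  if (n_screeners < 1) stop("n_screeners must be >= 1", call. = FALSE)
  n_screeners * costs$training_cost_per_screener
}

#' Staff cost of one ultrasound examination
#'
#' The screener's wage for the ten-minute exam, plus the physician's wage
#' share when assumption 2 requires their presence (integrated consultation
#' with a technician or specialist screener). An extra consultation doubles
#' the salary cost; evening sessions add a 35% uplift (unless the flat
#' per-child evening fee is configured, which is charged in
#' [visit_overhead_costs()] instead). A delegating nurse replaces the
#' physician's time, adding nothing.
#'
#' @param plan a `ddh_staffing` from [staffing_plan()].
#' @param spec the `ddh_scenario`.
#' @param costs a `ddh_costs`.
#' @return Euros per examination.
#' @export
#' @examples
#' sc <- scenario_spec("LIMITED", "INTEGRATED", "IHC_PHYSICIAN", "IHC_DAYTIME")
#' exam_staff_cost(staffing_plan(sc), sc, cost_params()) # 75/6 = 12.50
exam_staff_cost <- function(plan, spec, costs) {
  frac <- costs$exam_minutes / 60
  base <- wage_for(spec$screener, costs) * frac
  if (plan$physician_present_at_exam)
    base <- base + costs$wage_physician * frac
  if (spec$consultation == "EXTRA") base <- base * 2
  if (spec$location == "IHC_EVENING" && !costs$evening_flat_fee)
    base <- base * (1 + costs$evening_uplift)
  base
}

#' Travel, parent-time, rent and machine-usage costs of an attended visit
#'
#' Travel is charged at the km rate over the child's distance to the IHC (or
#' the fixed external distance); an extra consultation doubles travel and
#' means two hours of parents' productivity loss instead of one. External
#' locations add rent per child; scenarios that purchase no machines pay for
#' ultrasound use at the hospital hourly rate pro-rated to the exam length.
#' Vectorized over `distance_km`.
#'
#' @param distance_km the child's travel distance(s) to the IHC, km.
#' @param spec the `ddh_scenario`.
#' @param costs a `ddh_costs`.
#' @return A list of per-visit euro vectors: `travel`, `parent_time`, `rent`,
#'   `machine_use`.
#' @export
visit_overhead_costs <- function(distance_km, spec, costs) {
  dist <- if (spec$location == "EXTERNAL")
    rep(costs$external_distance_km, length(distance_km)) else distance_km
  extra <- spec$consultation == "EXTRA"
  travel <- dist * costs$km_rate * (1L + extra)
  parent <- rep(costs$parent_time_per_hour * (1L + extra), length(dist))
  rent <- rep(if (spec$location == "EXTERNAL")
    costs$rent_per_child_external else 0, length(dist))
  if (spec$location == "IHC_EVENING" && costs$evening_flat_fee)
    rent <- rent + costs$evening_flat_per_child
  machine_use <- rep(if (spec$machines == "NONE")
    costs$hospital_us_per_hour * costs$exam_minutes / 60 else 0, length(dist))
  list(travel = travel, parent_time = parent, rent = rent,
       machine_use = machine_use)
}

#' Downstream cost of a screening classification
#'
#' True positives cost the treatment of their Graf type; missed cases (false
#' negatives) the later, costlier missed-case treatment; false positives one
#' hospital visit plus parents' absence from work; true negatives nothing.
#' Vectorized.
#'
#' @param classification vector over `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @param graf_type vector over `"TYPE_2BC"`, `"TYPE_D"`, `"TYPE_34"`
#'   (required where classification is `"TP"`; ignored elsewhere).
#' @param costs a `ddh_costs`.
#' @return Euros, same length as `classification`.
#' @export
#' @examples
#' downstream_cost(c("TP", "FN", "TN"), c("TYPE_2BC", NA, NA), cost_params())
downstream_cost <- function(classification, graf_type, costs) {
  out <- numeric(length(classification))
  tp <- classification == "TP"
  if (any(tp)) {
    treat <- c(TYPE_2BC = costs$treat_2bc, TYPE_D = costs$treat_D,
               TYPE_34 = costs$treat_34)
    tc <- treat[graf_type[tp]]
    if (anyNA(tc))
      stop("TP without a valid Graf type: inconsistent state", call. = FALSE)
    out[tp] <- tc
  }
  out[classification == "FN"] <- costs$missed_case_cost
  out[classification == "FP"] <- costs$fp_visit_cost
  out
}

# Mean treatment cost of a detected case under the population's Graf mix.
mean_treatment_cost <- function(pop, costs) {
  shares <- graf_shares(pop)
  if (sum(shares) == 0) return(0)
  w <- shares / sum(shares)
  sum(w * c(costs$treat_2bc, costs$treat_D, costs$treat_34))
}
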