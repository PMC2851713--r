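# Screening pathway: invitation, reminder, ultrasound exam, classification,
# itemized costs. Children are independent, so the Monte-Carlo simulator has
# an exact closed-form counterpart (expected_scenario) used as verification
# oracle and as the fast deterministic evaluation mode.

#' Performance of the current screening programme (physical examination)
#'
#' Per screened child: 0.9% missed cases, 16.5% false positives, 2.8% true
#' positives (risk-factor history plus physical exam at ages 1--14 months).
#'
#' @param missed_rate,fp_rate,tp_rate proportions of screened children.
#' @return A validated list of class `ddh_comparator`.
#' @export
comparator_params <- function(missed_rate = 0.009, fp_rate = 0.165,
                              tp_rate = 0.028) {
  x <- list(missed_rate = missed_rate, fp_rate = fp_rate, tp_rate = tp_rate)
  v <- unlist(x)
  if (anyNA(v) || any(v < 0) || any(v > 1) || sum(v) > 1)
    stop("comparator rates must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  class(x) <- "ddh_comparator"
  x
}

#' Draw attendance through invitation and one reminder
#'
#' First invitation is attended with the region's attendance rate;
#' non-attenders receive one reminder and attend with the region's
#' re-attendance rate; otherwise the child is never screened.
#'
#' @param region character vector over `"URBAN"`, `"RURAL"`.
#' @param pop a `ddh_population`.
#' @return A list of logical vectors `attended` (overall) and
#'   `after_reminder` (attended only after the reminder). Consumes two
#'   uniform draws per child from the current RNG stream.
#' @export
attendance_draw <- function(region, pop) {
  urban <- region == "URBAN"
  p_att <- pop$attendance[["RURAL"]] +
    urban * (pop$attendance[["URBAN"]] - pop$attendance[["RURAL"]])
  p_re <- pop$reattendance[["RURAL"]] +
    urban * (pop$reattendance[["URBAN"]] - pop$reattendance[["RURAL"]])
  first <- stats::runif(length(region)) < p_att
  reminded <- stats::runif(length(region)) < p_re
  after_reminder <- !first & reminded
  list(attended = first | after_reminder, after_reminder = after_reminder)
}

#' Classify a screened child's test result against the latent status
#'
#' @param true_status vector over `"HEALTHY"` and the Graf types.
#' @param test_positive logical vector.
#' @return Character vector over `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
#' @examples
#' classify(c("TYPE_D", "HEALTHY", "TYPE_34"), c(TRUE, TRUE, FALSE))
classify <- function(true_status, test_positive) {
  affected <- true_status != "HEALTHY"
  c("TN", "FP", "FN", "TP")[1L + test_positive + 2L * affected]
}

#' Run one cohort through the screening pathway of a scenario
#'
#' Applies the pre-screening stage (early-treated children leave the cohort
#' at the first-consultation treatment cost; referred-but-untreated children
#' incur one hospital visit), the invitation/reminder attendance process, the
#' screener's operating characteristics, and the itemized per-child costs.
#' Uses the current RNG stream; scenario-level fixed costs (training,
#' machine ownership) are not included here (see [simulate_scenario()]).
#'
#' @param cohort a `ddh_cohort` from [generate_cohort()].
#' @param spec a `ddh_scenario`.
#' @param pop a `ddh_population`.
#' @param costs a `ddh_costs`.
#' @param plan optional `ddh_staffing`; default `staffing_plan(spec, n_sites)`.
#' @param n_sites sites served under `"MANY"` machines; default 7.
#' @param rates optional conditional error rates, default derived from the
#'   screener's profile and the population prevalence via
#'   [conditional_rates()].
#' @return A data frame of class `ddh_outcomes`, one row per child:
#'   `attended`, `attended_after_reminder`, `test_positive`,
#'   `classification` (including `"NOT_SCREENED"`), and euro columns
#'   `prescreen_cost`, `staff`, `travel`, `parent_time`, `machine_use`,
#'   `rent`, `downstream`, `cost_total`.
#' @export
screen_cohort <- function(cohort, spec, pop, costs,
                          plan = staffing_plan(spec, n_sites),
                          n_sites = 7L, rates = NULL) {
  n <- nrow(cohort)
  if (is.null(rates))
    rates <- conditional_rates(screener_profile(spec$screener, costs),
                               prevalence = pop$prevalence)

  removed <- cohort$prescreen == "TREATED"
  att <- attendance_draw(cohort$region, pop)
  attended <- att$attended & !removed
  after_reminder <- att$after_reminder & !removed

  affected <- cohort$true_status != "HEALTHY"
  p_pos <- rates$fp_given_healthy +
    affected * (1 - rates$miss_given_affected - rates$fp_given_healthy)
  test_positive <- stats::runif(n) < p_pos
  test_positive[!attended] <- NA

  classification <- rep("NOT_SCREENED", n)
  classification[attended] <- classify(cohort$true_status[attended],
                                       test_positive[attended])

  prescreen_cost <- numeric(n)
  prescreen_cost[removed] <- costs$treat_first_consult
  prescreen_cost[cohort$prescreen == "REFERRED"] <- costs$fp_visit_cost

  staff <- travel <- parent_time <- machine_use <- rent <- downstream <-
    numeric(n)
  if (any(attended)) {
    staff[attended] <- exam_staff_cost(plan, spec, costs)
    vis <- visit_overhead_costs(cohort$distance_km_ihc[attended], spec, costs)
    travel[attended] <- vis$travel
    parent_time[attended] <- vis$parent_time
    machine_use[attended] <- vis$machine_use
    rent[attended] <- vis$rent
    downstream[attended] <- downstream_cost(classification[attended],
                                            cohort$true_status[attended],
                                            costs)
  }

  out <- data.frame(
    id = cohort$id,
    attended = attended,
    attended_after_reminder = after_reminder,
    test_positive = test_positive,
    classification = classification,
    prescreen_cost = prescreen_cost,
    staff = staff,
    travel = travel,
    parent_time = parent_time,
    machine_use = machine_use,
    rent = rent,
    downstream = downstream,
    stringsAsFactors = FALSE
  )
  out$cost_total <- out$prescreen_cost + out$staff + out$travel +
    out$parent_time + out$machine_use + out$rent + out$downstream
  class(out) <- c("ddh_outcomes", "data.frame")
  out
}

# Aggregate one replication's outcomes into counts and cost components.
rep_summary <- function(outcomes, fixed_training, fixed_machines) {
  cls <- outcomes$classification
  comp <- c(
    prescreen = sum(outcomes$prescreen_cost),
    staff = sum(outcomes$staff),
    travel = sum(outcomes$travel),
    parent_time = sum(outcomes$parent_time),
    machine_use = sum(outcomes$machine_use),
    rent = sum(outcomes$rent),
    downstream = sum(outcomes$downstream),
    training = fixed_training,
    machines = fixed_machines
  )
  c(
    screened = sum(outcomes$attended),
    tp = sum(cls == "TP"),
    fp = sum(cls == "FP"),
    fn = sum(cls == "FN"),
    tn = sum(cls == "TN"),
    total_cost = unname(sum(comp)),
    comp
  )
}

new_scenario_result <- function(spec, plan, mode, n_reps, seed, means, sds,
                                components, label = NULL) {
  detected <- means[["tp"]]
  total <- means[["total_cost"]]
  if (detected <= 0)
    stop("no screen-detected children: cost-effectiveness ratio undefined ",
         "(degenerate parameters)", call. = FALSE)
  ce <- total / detected
  if (mode == "EXPECTED" || n_reps < 2) {
    ci <- c(ce, ce)
    if (mode != "EXPECTED") ci <- c(NA_real_, NA_real_)
  } else {
    # normal-approximation CI on the ratio of means via per-replication ratios
    se <- sds[["ce"]] / sqrt(n_reps)
    ci <- ce + c(-1, 1) * stats::qnorm(0.975) * se
  }
  structure(list(
    spec = spec,
    plan = plan,
    mode = mode,
    n_reps = n_reps,
    seed = seed,
    label = label,
    mean_screened = means[["screened"]],
    mean_detected = detected,
    mean_fp = means[["fp"]],
    mean_missed = means[["fn"]],
    mean_tn = means[["tn"]],
    mean_total_cost = total,
    sd = sds,
    components = components,
    ce_ratio = ce,
    ce_ratio_ci = ci
  ), class = "ddh_scenario_result")
}

#' Monte-Carlo evaluation of one implementation scenario
#'
#' For each replication a fresh synthetic cohort is generated and pushed
#' through the pathway of [screen_cohort()]; scenario-level fixed costs
#' (training of the scenario's screeners and one year's ownership of the
#' purchased machines) are added once per replication. Replication seeds are
#' derived deterministically from `seed`, so results are reproducible and
#' independent of evaluation order.
#'
#' @param spec a `ddh_scenario`.
#' @param pop a `ddh_population`; default [population_params()].
#' @param costs a `ddh_costs`; default [cost_params()].
#' @param n_reps number of replications (>= 1); default 100.
#' @param seed integer root seed.
#' @param n_sites sites served under `"MANY"` machines; default 7.
#' @param profile optional one-row screener profile (columns `fp_rate`,
#'   `miss_rate`) overriding [screener_profiles()] for sensitivity use.
#' @return An object of class `ddh_scenario_result`: mean counts (screened,
#'   detected, false positives, missed), mean total cost and per-component
#'   means, the cost-effectiveness ratio (mean cost / mean detected) with a
#'   normal-approximation 95% interval, and per-replication standard
#'   deviations in `$sd`.
#' @export
#' @examples
#' sc <- scenario_spec("NONE", "INTEGRATED", "IHC_NURSE", "IHC_DAYTIME")
#' simulate_scenario(sc, population_params(cohort_size = 300),
#'                   n_reps = 5, seed = 1)
simulate_scenario <- function(spec, pop = population_params(),
                              costs = cost_params(), n_reps = 100L,
                              seed = 1L, n_sites = 7L, profile = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  validate_population(pop)
  plan <- staffing_plan(spec, n_sites)
  if (is.null(profile)) profile <- screener_profile(spec$screener, costs)
  rates <- conditional_rates(profile, prevalence = pop$prevalence)
  fixed_training <- training_cost(plan$screeners_trained, costs)
  fixed_machines <- plan$machines_purchased * machine_annual_cost(costs)

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)

  cols <- c("screened", "tp", "fp", "fn", "tn", "total_cost", "prescreen",
            "staff", "travel", "parent_time", "machine_use", "rent",
            "downstream", "training", "machines")
  stats <- matrix(NA_real_, nrow = n_reps, ncol = length(cols),
                  dimnames = list(NULL, cols))
  for (j in seq_len(n_reps)) {
    coh <- generate_cohort(pop, rep_seeds[j])
    out <- screen_cohort(coh, spec, pop, costs, plan = plan, rates = rates)
    stats[j, ] <- rep_summary(out, fixed_training, fixed_machines)
  }

  means <- colMeans(stats)
  ratio <- stats[, "total_cost"] / pmax(stats[, "tp"], 1)
  sds <- c(apply(stats, 2, stats::sd), ce = stats::sd(ratio))
  components <- means[c("prescreen", "staff", "travel", "parent_time",
                        "machine_use", "rent", "downstream", "training",
                        "machines")]
  new_scenario_result(spec, plan, "SIMULATE", n_reps, as.integer(seed),
                      means, sds, components)
}

#' Closed-form expected outcome of one implementation scenario
#'
#' Children are independent, so every count and cost is a sum of per-stratum
#' expectations: expected screened children mix the attendance-plus-reminder
#' probability over regions; expected true positives, false positives and
#' missed cases follow from the conditional error rates; expected costs sum
#' stratum probabilities times stratum costs plus the fixed costs. No
#' randomness: this is both the verification oracle for
#' [simulate_scenario()] and the fast deterministic evaluation mode.
#'
#' @inheritParams simulate_scenario
#' @return A `ddh_scenario_result` with `mode = "EXPECTED"`, zero-width
#'   confidence interval and zero standard deviations.
#' @export
expected_scenario <- function(spec, pop = population_params(),
                              costs = cost_params(), n_sites = 7L,
                              profile = NULL) {
  validate_population(pop)
  plan <- staffing_plan(spec, n_sites)
  if (is.null(profile)) profile <- screener_profile(spec$screener, costs)
  rates <- conditional_rates(profile, prevalence = pop$prevalence)

  n <- pop$cohort_size
  e_treated <- n * pop$prescreen_treated
  e_referred <- n * (pop$prescreen_referral - pop$prescreen_treated)

  w_urban <- pop$attendance["URBAN"] +
    (1 - pop$attendance["URBAN"]) * pop$reattendance["URBAN"]
  w_rural <- pop$attendance["RURAL"] +
    (1 - pop$attendance["RURAL"]) * pop$reattendance["RURAL"]
  w_bar <- unname(pop$urban_share * w_urban + (1 - pop$urban_share) * w_rural)
  e_screened <- n * (1 - pop$prescreen_treated) * w_bar

  p <- pop$prevalence
  e_tp <- e_screened * p * (1 - rates$miss_given_affected)
  e_fn <- e_screened * p * rates$miss_given_affected
  e_fp <- e_screened * (1 - p) * rates$fp_given_healthy
  e_tn <- e_screened * (1 - p) * (1 - rates$fp_given_healthy)

  mean_dist <- mean(pop$distance_km_range)
  vis <- visit_overhead_costs(mean_dist, spec, costs)
  components <- c(
    prescreen = e_treated * costs$treat_first_consult +
      e_referred * costs$fp_visit_cost,
    staff = e_screened * exam_staff_cost(plan, spec, costs),
    travel = e_screened * vis$travel,
    parent_time = e_screened * vis$parent_time,
    machine_use = e_screened * vis$machine_use,
    rent = e_screened * vis$rent,
    downstream = e_tp * mean_treatment_cost(pop, costs) +
      e_fn * costs$missed_case_cost + e_fp * costs$fp_visit_cost,
    training = training_cost(plan$screeners_trained, costs),
    machines = plan$machines_purchased * machine_annual_cost(costs)
  )
  means <- c(screened = e_screened, tp = e_tp, fp = e_fp, fn = e_fn,
             tn = e_tn, total_cost = unname(sum(components)))
  sds <- c(stats::setNames(rep(0, length(means)), names(means)), ce = 0)
  new_scenario_result(spec, plan, "EXPECTED", 0L, NA_integer_, means, sds,
                      components)
}

#' Monte-Carlo evaluation of the current screening programme
#'
#' The comparator applies the current programme's per-screened-child rates
#' (true positives, false positives, missed cases) directly; only downstream
#' costs are incurred (the physical exam is part of the regular consultation).
#' Used for reporting context and optional incremental ratios.
#'
#' @inheritParams simulate_scenario
#' @param comparator a `ddh_comparator`; default [comparator_params()].
#' @return A `ddh_scenario_result` with `spec = NULL` and label `"current"`.
#' @export
simulate_current <- function(pop = population_params(), costs = cost_params(),
                             n_reps = 100L, seed = 1L,
                             comparator = comparator_params()) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  validate_population(pop)
  shares <- graf_shares(pop)
  graf_p <- if (sum(shares) > 0) shares / sum(shares) else rep(1 / 3, 3L)
  breaks <- cumsum(c(comparator$tp_rate, comparator$fp_rate,
                     comparator$missed_rate))

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)
  cols <- c("screened", "tp", "fp", "fn", "tn", "total_cost", "prescreen",
            "downstream")
  stats <- matrix(NA_real_, nrow = n_reps, ncol = length(cols),
                  dimnames = list(NULL, cols))
  for (j in seq_len(n_reps)) {
    coh <- generate_cohort(pop, rep_seeds[j])
    removed <- coh$prescreen == "TREATED"
    att <- attendance_draw(coh$region, pop)
    attended <- att$attended & !removed
    ns <- sum(attended)
    cls <- c("TP", "FP", "FN", "TN")[findInterval(stats::runif(ns),
                                                  breaks) + 1L]
    graf <- sample(GRAF_TYPES, ns, replace = TRUE, prob = graf_p)
    down <- sum(downstream_cost(cls, graf, costs))
    presc <- sum(removed) * costs$treat_first_consult +
      sum(coh$prescreen == "REFERRED") * costs$fp_visit_cost
    stats[j, ] <- c(ns, sum(cls == "TP"), sum(cls == "FP"), sum(cls == "FN"),
                    sum(cls == "TN"), presc + down, presc, down)
  }
  means <- colMeans(stats)
  ratio <- stats[, "total_cost"] / pmax(stats[, "tp"], 1)
  sds <- c(apply(stats, 2, stats::sd), ce = stats::sd(ratio))
  components <- c(prescreen = unname(means["prescreen"]),
                  downstream = unname(means["downstream"]))
  new_scenario_result(NULL, NULL, "SIMULATE", n_reps, as.integer(seed),
                      means, sds, components, label = "current")
}

#' Closed-form expected outcome of the current screening programme
#'
#' @inheritParams simulate_current
#' @return A `ddh_scenario_result` with `mode = "EXPECTED"`.
#' @export
expected_current <- function(pop = population_params(), costs = cost_params(),
                             comparator = comparator_params()) {
  validate_population(pop)
  n <- pop$cohort_size
  e_treated <- n * pop$prescreen_treated
  e_referred <- n * (pop$prescreen_referral - pop$prescreen_treated)
  w_urban <- pop$attendance["URBAN"] +
    (1 - pop$attendance["URBAN"]) * pop$reattendance["URBAN"]
  w_rural <- pop$attendance["RURAL"] +
    (1 - pop$attendance["RURAL"]) * pop$reattendance["RURAL"]
  w_bar <- unname(pop$urban_share * w_urban + (1 - pop$urban_share) * w_rural)
  e_screened <- n * (1 - pop$prescreen_treated) * w_bar

  e_tp <- e_screened * comparator$tp_rate
  e_fp <- e_screened * comparator$fp_rate
  e_fn <- e_screened * comparator$missed_rate
  e_tn <- e_screened - e_tp - e_fp - e_fn
  components <- c(
    prescreen = e_treated * costs$treat_first_consult +
      e_referred * costs$fp_visit_cost,
    downstream = e_tp * mean_treatment_cost(pop, costs) +
      e_fn * costs$missed_case_cost + e_fp * costs$fp_visit_cost
  )
  means <- c(screened = e_screened, tp = e_tp, fp = e_fp, fn = e_fn,
             tn = e_tn, total_cost = unname(sum(components)))
  sds <- c(stats::setNames(rep(0, length(means)), names(means)), ce = 0)
  new_scenario_result(NULL, NULL, "EXPECTED", 0L, NA_integer_, means, sds,
                      components, label = "current")
}

#' @export
print.ddh_scenario_result <- function(x, ...) {
  hdr <- if (is.null(x$spec)) "Current screening (comparator)"
  else sprintf("Scenario #%d: %s / %s / %s / %s", x$spec$canonical_id,
               x$spec$machines, x$spec$consultation, x$spec$screener,
               x$spec$location)
  cat(hdr, "\n")
  cat(sprintf("  mode: %s%s\n", x$mode,
              if (x$mode == "SIMULATE")
                sprintf(" (%d replications, seed %d)", x$n_reps, x$seed)
              else ""))
  cat(sprintf("  screened: %.1f   detected (TP): %.2f   FP: %.2f   missed: %.2f\n",
              x$mean_screened, x$mean_detected, x$mean_fp, x$mean_missed))
  cat(sprintf("  total cost: EUR %.0f\n", x$mean_total_cost))
  cat(sprintf("  cost per screen-detected child: EUR %.0f", x$ce_ratio))
  if (x$mode == "SIMULATE" && !anyNA(x$ce_ratio_ci))
    cat(sprintf("  (95%% CI %.0f-%.0f)", x$ce_ratio_ci[1], x$ce_ratio_ci[2]))
  cat("\n")
  invisible(x)
}
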