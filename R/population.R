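# Synthetic cohort: latent Graf hip status, urban/rural residence, travel
# distance, arrival over the programme horizon, and the pre-screening stage
# (children referred and treated before the three-month ultrasound exam).

GRAF_TYPES <- c("TYPE_2BC", "TYPE_D", "TYPE_34")
STATUS_LEVELS <- c("HEALTHY", GRAF_TYPES)

#' Population parameters for the synthetic cohort
#'
#' Defaults describe the implementation-study population: a cohort of 2,300
#' children visiting the infant health care centers over 18 months; 3.8% of
#' screened children affected by treatable hip dysplasia (Graf types 2b/c, D,
#' 3/4 in the printed mix, renormalized to the prevalence); two thirds of the
#' population in urban/suburban regions; attendance 85% urban / 90% rural with
#' re-attendance after one reminder of 80% / 90%; and a pre-screening stage in
#' which 0.61% of children are referred after an early consultation, 0.31% of
#' whom (of all children) are treated before the ultrasound exam and leave the
#' screening cohort.
#'
#' @param cohort_size number of children invited; default 2300.
#' @param horizon_months programme duration in months; default 18.
#' @param prevalence proportion of screened children with treatable DDH;
#'   default 0.038.
#' @param graf_mix named proportions for `TYPE_2BC`, `TYPE_D`, `TYPE_34`
#'   (defaults 0.014, 0.015, 0.005); renormalized to sum to `prevalence`.
#' @param urban_share proportion of children in urban regions; default 2/3.
#' @param attendance named first-invitation attendance rates,
#'   `c(URBAN = 0.85, RURAL = 0.90)`.
#' @param reattendance named after-reminder attendance rates,
#'   `c(URBAN = 0.80, RURAL = 0.90)`.
#' @param prescreen_referral proportion of all children referred at the first
#'   consultation, before ultrasound screening; default 0.0061.
#' @param prescreen_treated proportion of all children treated after that
#'   first consultation (a subset of the referred); default 0.0031.
#' @param distance_km_range travel distance to the IHC, uniform over this
#'   range in km; default `c(4, 7)`.
#' @return A validated list of class `ddh_population`.
#' @export
population_params <- function(cohort_size = 2300L,
                              horizon_months = 18,
                              prevalence = 0.038,
                              graf_mix = c(TYPE_2BC = 0.014,
                                           TYPE_D = 0.015,
                                           TYPE_34 = 0.005),
                              urban_share = 2 / 3,
                              attendance = c(URBAN = 0.85, RURAL = 0.90),
                              reattendance = c(URBAN = 0.80, RURAL = 0.90),
                              prescreen_referral = 0.0061,
                              prescreen_treated = 0.0031,
                              distance_km_range = c(4, 7)) {
  pop <- list(
    cohort_size = as.integer(cohort_size),
    horizon_months = horizon_months,
    prevalence = prevalence,
    graf_mix = graf_mix[GRAF_TYPES],
    urban_share = urban_share,
    attendance = attendance[c("URBAN", "RURAL")],
    reattendance = reattendance[c("URBAN", "RURAL")],
    prescreen_referral = prescreen_referral,
    prescreen_treated = prescreen_treated,
    distance_km_range = distance_km_range
  )
  validate_population(pop)
  class(pop) <- "ddh_population"
  pop
}

validate_population <- function(pop) {
  props <- c(pop$prevalence, pop$urban_share, pop$attendance,
             pop$reattendance, pop$prescreen_referral, pop$prescreen_treated,
             pop$graf_mix)
  if (anyNA(props) || any(props < 0) || any(props > 1))
    stop("all population proportions must lie in [0, 1]", call. = FALSE)
  if (pop$cohort_size < 1L)
    stop("cohort_size must be >= 1", call. = FALSE)
  if (pop$horizon_months <= 0)
    stop("horizon_months must be positive", call. = FALSE)
  if (pop$prescreen_treated > pop$prescreen_referral)
    stop("prescreen_treated cannot exceed prescreen_referral", call. = FALSE)
  if (pop$prevalence > 0 && sum(pop$graf_mix) <= 0)
    stop("graf_mix must have positive mass when prevalence > 0", call. = FALSE)
  if (diff(pop$distance_km_range) < 0 || any(pop$distance_km_range < 0))
    stop("distance_km_range must be a non-negative increasing range",
         call. = FALSE)
  invisible(pop)
}

# Graf shares rescaled so they sum to the configured prevalence; the printed
# type percentages (1.4/1.5/0.5) sum to 3.4%, not 3.8%, hence renormalization.
graf_shares <- function(pop) {
  if (pop$prevalence == 0) return(setNames(rep(0, 3L), GRAF_TYPES))
  pop$graf_mix / sum(pop$graf_mix) * pop$prevalence
}

#' Screening quality and wage per screener discipline
#'
#' False-positive and missed-case proportions are expressed per screened
#' child (not conditional on disease status); see [conditional_rates()] for
#' the conversion. Quality for the radiographic technician comes from the
#' earlier field study; the other disciplines were set by expert opinion.
#'
#' @param costs a `ddh_costs` object supplying the hourly wages
#'   (default [cost_params()]).
#' @return A data frame with one row per discipline: `discipline`,
#'   `wage_per_hour`, `fp_rate`, `miss_rate`.
#' @export
screener_profiles <- function(costs = cost_params()) {
  data.frame(
    discipline = SCREENER_LEVELS,
    wage_per_hour = c(costs$wage_physician, costs$wage_nurse,
                      costs$wage_rt, costs$wage_specialist),
    fp_rate = c(0.014, 0.015, 0.013, 0.006),
    miss_rate = c(0.006, 0.007, 0.006, 0.003),
    stringsAsFactors = FALSE
  )
}

screener_profile <- function(screener, costs = cost_params()) {
  prof <- screener_profiles(costs)
  prof[match(screener, prof$discipline), , drop = FALSE]
}

#' Convert per-screened-child error rates to conditional probabilities
#'
#' Quality tables give false positives and missed cases as proportions of all
#' screened children. The simulator needs them conditional on the latent
#' status: `miss_given_affected = miss_rate / prevalence` and
#' `fp_given_healthy = fp_rate / (1 - prevalence)`.
#'
#' @param fp_rate,miss_rate proportions of all screened children; a
#'   one-row data frame from [screener_profiles()] may be passed as
#'   `fp_rate` instead.
#' @param prevalence proportion of screened children affected.
#' @return Named list `miss_given_affected`, `fp_given_healthy`.
#' @export
#' @examples
#' conditional_rates(fp_rate = 0.013, miss_rate = 0.006, prevalence = 0.038)
conditional_rates <- function(fp_rate, miss_rate = NULL, prevalence) {
  if (is.data.frame(fp_rate)) {
    miss_rate <- fp_rate$miss_rate
    fp_rate <- fp_rate$fp_rate
  }
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  if (miss_rate > prevalence)
    stop("miss_rate exceeds prevalence: inconsistent parameters", call. = FALSE)
  if (fp_rate > 1 - prevalence)
    stop("fp_rate exceeds 1 - prevalence: inconsistent parameters",
         call. = FALSE)
  list(
    # at the boundaries the corresponding stratum is empty; rates are 0
    miss_given_affected = if (prevalence == 0) 0 else miss_rate / prevalence,
    fp_given_healthy = if (prevalence == 1) 0 else fp_rate / (1 - prevalence)
  )
}

#' Generate a synthetic cohort
#'
#' Draws `cohort_size` children with residence region, travel distance to the
#' IHC (uniform over `distance_km_range`), arrival month over the horizon and
#' a pre-screening disposition. A fraction `prescreen_treated` of children was
#' already detected and treated after an early consultation: these children
#' are true cases by construction (their Graf type is drawn from the mix) and
#' leave the screening cohort. A further `prescreen_referral -
#' prescreen_treated` were referred but not treated; they remain in the
#' cohort and incur one hospital visit. Latent hip status among the remaining
#' children is categorical with the configured prevalence, so prevalence is
#' the proportion of children reaching the screening stage who are affected.
#'
#' @param pop a `ddh_population`.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @return A data frame of class `ddh_cohort` with columns `id`, `region`,
#'   `true_status`, `distance_km_ihc`, `arrival_month`, `prescreen`
#'   (`"NONE"`, `"REFERRED"`, or `"TREATED"`).
#' @export
#' @examples
#' coh <- generate_cohort(population_params(cohort_size = 500), seed = 1)
#' table(coh$true_status)
generate_cohort <- function(pop, seed) {
  validate_population(pop)
  if (!missing(seed)) set.seed(as.integer(seed))
  n <- pop$cohort_size

  region <- c("RURAL", "URBAN")[(stats::runif(n) < pop$urban_share) + 1L]

  shares <- graf_shares(pop)
  breaks <- cumsum(c(1 - pop$prevalence, shares))
  true_status <- STATUS_LEVELS[findInterval(stats::runif(n), breaks) + 1L]

  # Pre-screening disposition, independent of the latent draw; treated
  # children are true cases detected early, so their type is re-drawn from
  # the Graf mix (the remaining cohort keeps the configured prevalence).
  u <- stats::runif(n)
  prescreen <- rep("NONE", n)
  prescreen[u < pop$prescreen_referral] <- "REFERRED"
  prescreen[u < pop$prescreen_treated] <- "TREATED"
  treated <- prescreen == "TREATED"
  if (any(treated)) {
    if (pop$prevalence > 0) {
      p <- shares / sum(shares)
      true_status[treated] <- sample(GRAF_TYPES, sum(treated),
                                     replace = TRUE, prob = p)
    } else {
      true_status[treated] <- "HEALTHY"
    }
  }

  structure(data.frame(
    id = seq_len(n),
    region = region,
    true_status = true_status,
    distance_km_ihc = stats::runif(n, pop$distance_km_range[1],
                                   pop$distance_km_range[2]),
    arrival_month = stats::runif(n, 0, pop$horizon_months),
    prescreen = prescreen,
    stringsAsFactors = FALSE
  ), class = c("ddh_cohort", "data.frame"))
}
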