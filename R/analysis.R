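# Cost-effectiveness analysis over the scenario set: CE ratios, rank-based
# quartile groups with level-frequency tables, extreme-scenario rankings, and
# one-way sensitivity sweeps.

#' Cost per screen-detected child
#'
#' @param total_cost total scenario cost, euros.
#' @param n_detected number of screen-detected (true positive) children.
#' @return Euros per detected child.
#' @export
#' @examples
#' ce_ratio(6462, 2)
ce_ratio <- function(total_cost, n_detected) {
  if (any(n_detected <= 0))
    stop("cost-effectiveness ratio undefined: no detected children",
         call. = FALSE)
  total_cost / n_detected
}

#' Tabulate a collection of scenario results
#'
#' @param results a list of `ddh_scenario_result` objects (scenario results,
#'   not the comparator).
#' @return A data frame with one row per scenario: canonical id, the four
#'   levels, counts, cost components, total cost, CE ratio and its CI.
#' @export
results_table <- function(results) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    if (is.null(r$spec))
      stop("results_table expects scenario results, not the comparator",
           call. = FALSE)
    comp <- as.list(r$components)
    names(comp) <- paste0("cost_", names(comp))
    c(list(
      canonical_id = r$spec$canonical_id,
      machines = r$spec$machines,
      consultation = r$spec$consultation,
      screener = r$spec$screener,
      location = r$spec$location,
      mode = r$mode,
      n_reps = r$n_reps,
      mean_screened = r$mean_screened,
      mean_detected = r$mean_detected,
      mean_fp = r$mean_fp,
      mean_missed = r$mean_missed,
      mean_total_cost = r$mean_total_cost,
      ce_ratio = r$ce_ratio,
      ce_lo = r$ce_ratio_ci[1],
      ce_hi = r$ce_ratio_ci[2]
    ), comp)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(df) <- NULL
  df
}

scenario_vars <- c("machines", "consultation", "screener", "location")

as_ce_table <- function(results) {
  if (is.data.frame(results)) {
    need <- c("canonical_id", "ce_ratio", scenario_vars)
    miss <- setdiff(need, names(results))
    if (length(miss))
      stop("results table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    results
  } else {
    results_table(results)
  }
}

#' Rank-based cost-effectiveness groups
#'
#' Sorts scenarios ascending by CE ratio (ties broken by canonical id) and
#' splits them into `n_groups` contiguous groups of (near-)equal size, labeled
#' `CE_A` (most cost-effective) through `CE_D`; with the full design of 72
#' scenarios each quartile holds 18. Level frequencies per experimental
#' variable are tabulated per group.
#'
#' @param results a list of `ddh_scenario_result` objects or a data frame as
#'   from [results_table()].
#' @param n_groups number of groups; default 4.
#' @return An object of class `ddh_quartiles`: `table` (the sorted scenario
#'   table with a `group` column), `ranges` (per group: n, min and max CE),
#'   and `level_frequencies` (long table: variable, level, group, count).
#' @export
quartile_groups <- function(results, n_groups = 4L) {
  df <- as_ce_table(results)
  n <- nrow(df)
  if (n < n_groups)
    stop("need at least ", n_groups, " scenario results", call. = FALSE)
  df <- df[order(df$ce_ratio, df$canonical_id), , drop = FALSE]
  sizes <- rep(n %/% n_groups, n_groups) +
    (seq_len(n_groups) <= n %% n_groups)
  labels <- paste0("CE_", LETTERS[seq_len(n_groups)])
  df$group <- rep(labels, times = sizes)
  rownames(df) <- NULL

  ranges <- do.call(rbind, lapply(labels, function(g) {
    ce <- df$ce_ratio[df$group == g]
    data.frame(group = g, n = length(ce), ce_min = min(ce), ce_max = max(ce))
  }))

  freq <- do.call(rbind, lapply(scenario_vars, function(v) {
    tab <- table(level = df[[v]], group = factor(df$group, levels = labels))
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("level", "group", "count")
    cbind(variable = v, out)
  }))
  rownames(freq) <- NULL

  structure(list(table = df, ranges = ranges, level_frequencies = freq),
            class = "ddh_quartiles")
}

#' @export
print.ddh_quartiles <- function(x, ...) {
  cat("Cost-effectiveness groups (cost per screen-detected child, EUR)\n")
  r <- x$ranges
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %s: %d scenarios, CE %.0f - %.0f\n",
                r$group[i], r$n[i], r$ce_min[i], r$ce_max[i]))
  invisible(x)
}

#' Most and least cost-effective scenarios
#'
#' @param results as in [quartile_groups()].
#' @param k number of scenarios at each extreme (default 5).
#' @return A list of class `ddh_extremes`: `top` (the `k` lowest CE ratios,
#'   ascending) and `bottom` (the `k` highest, descending), each a data frame
#'   carrying the level tuple and the ratio.
#' @export
rank_extremes <- function(results, k = 5L) {
  df <- as_ce_table(results)
  if (k > nrow(df) / 2)
    stop("k must not exceed half the number of results", call. = FALSE)
  df <- df[order(df$ce_ratio, df$canonical_id), , drop = FALSE]
  cols <- c("canonical_id", scenario_vars, "ce_ratio")
  top <- df[seq_len(k), cols, drop = FALSE]
  bottom <- df[rev(nrow(df) - seq_len(k) + 1L), cols, drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  structure(list(top = top, bottom = bottom, k = k), class = "ddh_extremes")
}

#' @export
print.ddh_extremes <- function(x, ...) {
  cat(sprintf("%d most cost-effective scenarios:\n", x$k))
  print(x$top)
  cat(sprintf("%d least cost-effective scenarios:\n", x$k))
  print(x$bottom)
  invisible(x)
}

# Resolve a parameter path like "costs.rent_per_child_external" or
# "pop.prevalence" (bare names are searched in costs, then pop).
set_param <- function(pop, costs, param_path, value) {
  parts <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    where <- parts[1]
    name <- parts[2]
  } else if (length(parts) == 1L) {
    name <- parts
    where <- if (name %in% names(costs)) "costs"
    else if (name %in% names(pop)) "pop" else NA_character_
  } else {
    where <- NA_character_
  }
  if (identical(where, "costs") && name %in% names(costs)) {
    costs[[name]] <- value
    validate_costs(costs)
  } else if (identical(where, "pop") && name %in% names(pop)) {
    pop[[name]] <- value
    validate_population(pop)
  } else {
    stop("unknown parameter path: ", param_path, call. = FALSE)
  }
  list(pop = pop, costs = costs)
}

#' One-way sensitivity sweep
#'
#' Re-evaluates scenarios while one numeric parameter steps through a grid of
#' values, all else held at its default. The deterministic expected-value
#' engine is used unless `mode = "SIMULATE"`.
#'
#' @param specs a list of `ddh_scenario` (default all 72).
#' @param pop,costs baseline parameters.
#' @param param_path parameter name, optionally qualified as
#'   `"pop.<name>"` or `"costs.<name>"`.
#' @param values numeric vector of values to sweep.
#' @param mode `"EXPECTED"` (default) or `"SIMULATE"`.
#' @param n_reps,seed used in `"SIMULATE"` mode.
#' @param n_sites sites served under `"MANY"` machines.
#' @return Data frame sorted by value then canonical id: `param`, `value`,
#'   `canonical_id`, the four levels, `ce_ratio`.
#' @export
#' @examples
#' sc <- enumerate_scenarios()[1:2]
#' one_way_sensitivity(sc, param_path = "missed_case_cost",
#'                     values = c(1000, 1217, 1500))
one_way_sensitivity <- function(specs = enumerate_scenarios(),
                                pop = population_params(),
                                costs = cost_params(),
                                param_path, values,
                                mode = c("EXPECTED", "SIMULATE"),
                                n_reps = 100L, seed = 1L, n_sites = 7L) {
  mode <- match.arg(mode)
  if (!is.numeric(values) || length(values) < 1L)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  rows <- list()
  for (v in sort(values)) {
    pc <- set_param(pop, costs, param_path, v)
    for (spec in specs) {
      res <- if (mode == "EXPECTED") {
        expected_scenario(spec, pc$pop, pc$costs, n_sites = n_sites)
      } else {
        simulate_scenario(spec, pc$pop, pc$costs, n_reps = n_reps,
                          seed = seed, n_sites = n_sites)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        param = param_path, value = v,
        canonical_id = spec$canonical_id,
        machines = spec$machines, consultation = spec$consultation,
        screener = spec$screener, location = spec$location,
        ce_ratio = res$ce_ratio, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$value, out$canonical_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Incremental cost-effectiveness against current screening
#'
#' Optional incremental mode: (scenario cost - comparator cost) divided by
#' (scenario detections - comparator detections). The headline measure of the
#' analysis remains the average cost per screen-detected child.
#'
#' @param result a `ddh_scenario_result` for a scenario.
#' @param current a `ddh_scenario_result` for the comparator.
#' @return Euros per additional detected child.
#' @export
incremental_ce <- function(result, current) {
  d <- result$mean_detected - current$mean_detected
  if (d == 0)
    stop("no additional detections: incremental ratio undefined",
         call. = FALSE)
  (result$mean_total_cost - current$mean_total_cost) / d
}
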