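# Orchestration: validated experiment configuration, the full 72-scenario
# run, result tables on disk, and the human-readable report. All randomness
# flows from one root seed, split deterministically per scenario, so results
# do not depend on evaluation order.

#' Experiment configuration
#'
#' Bundles and validates everything a full run needs. Every parameter
#' defaults to the study's values; see [population_params()] and
#' [cost_params()].
#'
#' @param pop a `ddh_population`.
#' @param costs a `ddh_costs`.
#' @param n_reps Monte-Carlo replications per scenario (default 100).
#' @param seed root seed for the whole experiment.
#' @param n_sites IHC sites served when machines are `"MANY"` (default 7).
#' @param mode `"SIMULATE"` (Monte-Carlo) or `"EXPECTED"` (closed form).
#' @param sensitivity list of one-way sweep blocks, each
#'   `list(param = <name>, values = <numeric vector>)`.
#' @return A validated list of class `ddh_config`.
#' @export
experiment_config <- function(pop = population_params(),
                              costs = cost_params(),
                              n_reps = 100L, seed = 1L, n_sites = 7L,
                              mode = c("SIMULATE", "EXPECTED"),
                              sensitivity = list()) {
  mode <- match.arg(mode)
  validate_population(pop)
  validate_costs(costs)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  for (blk in sensitivity) {
    if (is.null(blk$param) || is.null(blk$values))
      stop("each sensitivity block needs 'param' and 'values'", call. = FALSE)
    set_param(pop, costs, blk$param, blk$values[1]) # validates the path
  }
  structure(list(pop = pop, costs = costs, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), n_sites = as.integer(n_sites),
                 mode = mode, sensitivity = sensitivity),
            class = "ddh_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file may specify any subset of the keys under `population:`, `costs:`,
#' and the top-level keys `n_reps`, `seed`, `n_sites`, `mode`,
#' `sensitivity:`; unspecified values keep their defaults. A fully commented
#' defaults file ships with the package
#' (`system.file("extdata", "default-config.yaml", package = "hipscreen")`).
#'
#' @param path YAML file path.
#' @return A validated `ddh_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pop_args <- raw$population
  for (nm in c("graf_mix", "attendance", "reattendance", "distance_km_range"))
    if (!is.null(pop_args[[nm]])) pop_args[[nm]] <- unlist(pop_args[[nm]])
  pop <- do.call(population_params, pop_args %||% list())
  costs <- do.call(cost_params, raw$costs %||% list())
  sens <- lapply(raw$sensitivity %||% list(), function(b)
    list(param = b$param, values = as.numeric(unlist(b$values))))
  experiment_config(
    pop = pop, costs = costs,
    n_reps = raw$n_reps %||% 100L,
    seed = raw$seed %||% 1L,
    n_sites = raw$n_sites %||% 7L,
    mode = raw$mode %||% "SIMULATE",
    sensitivity = sens
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment configuration to a YAML file
#'
#' @param config a `ddh_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- list(
    population = lapply(unclass(config$pop), function(x)
      if (!is.null(names(x))) as.list(x) else x),
    costs = unclass(config$costs),
    n_reps = config$n_reps,
    seed = config$seed,
    n_sites = config$n_sites,
    mode = config$mode,
    sensitivity = config$sensitivity
  )
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full 72-scenario experiment
#'
#' Enumerates the factorial design, evaluates every scenario in the
#' configured mode, groups results into cost-effectiveness quartiles,
#' extracts the five most and least cost-effective scenarios, evaluates the
#' current-screening comparator, and runs any configured one-way sensitivity
#' sweeps. With `out_dir` set, writes the scenario-results table, quartile
#' ranges, level frequencies, extremes, comparator summary, sensitivity
#' table and a JSON run manifest (seed, parameter hash, package version).
#'
#' @param config a `ddh_config`; default [experiment_config()].
#' @param out_dir optional output directory (created if missing).
#' @param quiet suppress per-scenario progress messages (default TRUE).
#' @return An object of class `ddh_experiment` with elements `results`
#'   (data frame, one row per scenario, including the quartile group and the
#'   incremental ratio against the comparator), `quartiles`, `extremes`,
#'   `comparator`, `sensitivity`, `config`, `manifest`.
#' @export
#' @examples
#' cfg <- experiment_config(mode = "EXPECTED")
#' ex <- run_experiment(cfg)
#' ex$quartiles$ranges
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = TRUE) {
  stopifnot(inherits(config, "ddh_config"))
  specs <- enumerate_scenarios()
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, length(specs) + 1L)

  results <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    results[[i]] <- if (config$mode == "EXPECTED") {
      expected_scenario(specs[[i]], config$pop, config$costs,
                        n_sites = config$n_sites)
    } else {
      simulate_scenario(specs[[i]], config$pop, config$costs,
                        n_reps = config$n_reps, seed = seeds[i],
                        n_sites = config$n_sites)
    }
    if (!quiet)
      message(sprintf("scenario %2d/%d: CE = %.0f", i, length(specs),
                      results[[i]]$ce_ratio))
  }
  comparator <- if (config$mode == "EXPECTED") {
    expected_current(config$pop, config$costs)
  } else {
    simulate_current(config$pop, config$costs, n_reps = config$n_reps,
                     seed = seeds[length(seeds)])
  }

  quartiles <- quartile_groups(results_table(results))
  tab <- quartiles$table
  d <- tab$mean_detected - comparator$mean_detected
  tab$icer_vs_current <- ifelse(
    d == 0, NA_real_,
    (tab$mean_total_cost - comparator$mean_total_cost) / d)
  tab <- tab[order(tab$canonical_id), , drop = FALSE]
  rownames(tab) <- NULL
  extremes <- rank_extremes(tab, 5L)

  sens <- NULL
  if (length(config$sensitivity)) {
    sens <- do.call(rbind, lapply(config$sensitivity, function(blk)
      one_way_sensitivity(specs, config$pop, config$costs,
                          param_path = blk$param, values = blk$values,
                          mode = "EXPECTED", n_sites = config$n_sites)))
    rownames(sens) <- NULL
  }

  manifest <- list(
    package = "hipscreen",
    version = as.character(utils::packageVersion("hipscreen")),
    seed = config$seed,
    mode = config$mode,
    n_reps = if (config$mode == "EXPECTED") 0L else config$n_reps,
    n_sites = config$n_sites,
    n_scenarios = length(specs),
    parameter_hash = config_hash(config)
  )

  bundle <- structure(list(
    results = tab, quartiles = quartiles, extremes = extremes,
    comparator = comparator, sensitivity = sens, config = config,
    manifest = manifest
  ), class = "ddh_experiment")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(bundle$results, "scenario_results.csv")
  wcsv(bundle$quartiles$ranges, "quartile_ranges.csv")
  wcsv(bundle$quartiles$level_frequencies, "level_frequencies.csv")
  ext <- rbind(cbind(end = "most_cost_effective", rank = seq_len(bundle$extremes$k),
                     bundle$extremes$top),
               cbind(end = "least_cost_effective", rank = seq_len(bundle$extremes$k),
                     bundle$extremes$bottom))
  wcsv(ext, "extremes.csv")
  cmp <- bundle$comparator
  wcsv(data.frame(
    mode = cmp$mode, n_reps = cmp$n_reps,
    mean_screened = cmp$mean_screened, mean_detected = cmp$mean_detected,
    mean_fp = cmp$mean_fp, mean_missed = cmp$mean_missed,
    mean_total_cost = cmp$mean_total_cost, ce_ratio = cmp$ce_ratio
  ), "comparator.csv")
  if (!is.null(bundle$sensitivity)) wcsv(bundle$sensitivity, "sensitivity.csv")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable summary of a completed experiment
#'
#' Every number shown is taken from the bundle's tables; nothing is
#' recomputed here.
#'
#' @param bundle a `ddh_experiment` from [run_experiment()].
#' @param file optional path; when given the report is also written there.
#' @return The report lines, invisibly.
#' @export
write_report <- function(bundle, file = NULL) {
  stopifnot(inherits(bundle, "ddh_experiment"))
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  m <- bundle$manifest
  add("Ultrasound DDH screening: scenario experiment report")
  add("  %d scenarios, mode %s, seed %d, package %s %s",
      m$n_scenarios, m$mode, m$seed, m$package, m$version)
  add("")
  add("Cost-effectiveness groups (EUR per screen-detected child)")
  r <- bundle$quartiles$ranges
  for (i in seq_len(nrow(r)))
    add("  %s: %2d scenarios, CE %7.0f - %7.0f", r$group[i], r$n[i],
        r$ce_min[i], r$ce_max[i])
  add("")
  add("Level frequencies by group")
  f <- bundle$quartiles$level_frequencies
  for (v in unique(f$variable)) {
    add("  %s:", v)
    sub <- f[f$variable == v, ]
    for (lev in unique(sub$level)) {
      s <- sub[sub$level == lev, ]
      add("    %-24s %s", lev,
          paste(sprintf("%s=%d", s$group, s$count), collapse = "  "))
    }
  }
  add("")
  fmt_row <- function(row)
    sprintf("  #%02d  %-8s %-10s %-24s %-12s CE %7.0f",
            row$canonical_id, row$machines, row$consultation, row$screener,
            row$location, row$ce_ratio)
  add("Most cost-effective scenarios")
  for (i in seq_len(nrow(bundle$extremes$top)))
    L <- c(L, fmt_row(bundle$extremes$top[i, ]))
  add("Least cost-effective scenarios")
  for (i in seq_len(nrow(bundle$extremes$bottom)))
    L <- c(L, fmt_row(bundle$extremes$bottom[i, ]))
  add("")
  cmp <- bundle$comparator
  add("Current screening (comparator): detected %.2f, FP %.2f, missed %.2f,",
      cmp$mean_detected, cmp$mean_fp, cmp$mean_missed)
  add("  total cost EUR %.0f, CE %.0f", cmp$mean_total_cost, cmp$ce_ratio)
  if (!is.null(bundle$sensitivity)) {
    add("")
    add("One-way sensitivity sweeps")
    s <- bundle$sensitivity
    for (p in unique(s$param)) {
      sub <- s[s$param == p, ]
      for (v in unique(sub$value))
        add("  %s = %g: CE range %.0f - %.0f", p, v,
            min(sub$ce_ratio[sub$value == v]),
            max(sub$ce_ratio[sub$value == v]))
    }
  }
  cat(L, sep = "\n")
  if (!is.null(file)) writeLines(L, file)
  invisible(L)
}

#' @export
print.ddh_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("DDH screening scenario experiment: %d scenarios, mode %s\n",
              m$n_scenarios, m$mode))
  print(x$quartiles)
  cat("Most cost-effective: scenario #", x$extremes$top$canonical_id[1],
      sprintf(" (CE %.0f)\n", x$extremes$top$ce_ratio[1]), sep = "")
  invisible(x)
}

#' @export
summary.ddh_experiment <- function(object, ...) {
  write_report(object)
}

#' Level-frequency bar panels per experimental variable
#'
#' One panel per experimental variable showing, for each level, how its
#' scenarios distribute over the four cost-effectiveness groups.
#'
#' @param x a `ddh_experiment`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ddh_experiment <- function(x, ...) {
  f <- x$quartiles$level_frequencies
  old <- graphics::par(mfrow = c(2, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in unique(f$variable)) {
    sub <- f[f$variable == v, ]
    m <- stats::xtabs(count ~ group + level, data = sub)
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      main = v, las = 2, ylab = "scenarios",
                      args.legend = list(x = "topright", cex = 0.7), ...)
  }
  invisible(x)
}
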