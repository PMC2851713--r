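# Shared fixtures: study defaults plus a small cohort for cheap tests.

default_pop <- population_params()
default_costs <- cost_params()
small_pop <- population_params(cohort_size = 400L)

spec_of <- function(m, c, s, l) scenario_spec(m, c, s, l)

# A synthetic results table (not from the simulator) for partition tests.
fake_results <- function(ce) {
  n <- length(ce)
  specs <- enumerate_scenarios()[seq_len(n)]
  df <- as.data.frame(structure(specs, class = "ddh_scenario_set"))
  df$ce_ratio <- ce
  df
}
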