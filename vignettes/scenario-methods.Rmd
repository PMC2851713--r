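---
title: "Methods: scenario simulation for ultrasound DDH screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario simulation for ultrasound DDH screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipscreen)
```

## The question the model answers

General ultrasound (US) screening of infant hips at age three months detects
developmental dysplasia of the hip (DDH) earlier and with far fewer false
positives than the risk-factor/physical-examination programme currently run
at Dutch infant health care centers (IHC). How such a screening programme is
*organized*, however, changes its costs substantially: who scans, where,
when, with how many purchased machines, and whether the scan is folded into
the regular three-month consultation or requires a separate visit. hipscreen
evaluates every combination of these organizational choices — a full
factorial over four experimental variables with 3 × 2 × 4 × 3 = 72 cells —
and ranks the scenarios by **cost per screen-detected child** (the CE ratio:
total societal cost divided by the number of true positives, children
detected and treated within a year).

## The cohort model

Each scenario is evaluated on a synthetic cohort of 2,300 children arriving
over 18 months. Children are independent; no capacity constraints or queues
are modeled (resource competition is an explicit non-goal of this design
stage), which is why the Monte-Carlo engine (`simulate_scenario()`) has an
exact closed-form counterpart (`expected_scenario()`): every count and cost
is a sum of per-stratum expectations. The closed form serves both as the
verification oracle for the simulator and as the fast deterministic
evaluation mode used for ranking and sensitivity sweeps.

Per child the pathway is:

1. **Pre-screening.** Independently of everything else, 0.31% of children
   were already detected and treated after an early consultation (cost
   EUR 571 each) and leave the cohort; a further 0.30% (the referred-but-
   untreated remainder of the 0.61% referral rate) incur one hospital visit
   (EUR 97) and continue to screening. Treated children are true cases by
   construction — they were detected and treated — and their Graf type is
   drawn from the treatable mix. Because their removal does not touch the
   latent-status draw of the remaining children, the prevalence parameter is
   exactly the proportion of *screened* children who are affected, which is
   how the screening performance figures (3.2% true positives + 0.6% missed
   = 3.8%) are defined.
2. **Attendance.** First invitation is attended with the region's rate (85%
   urban, 90% rural; two thirds of children are urban, matching the two
   urban/suburban and one rural participating organizations); non-attenders
   get one reminder and attend with the re-attendance rate (80% urban, 90%
   rural). Never-attenders are not screened and incur no cost. Reminders
   themselves carry no administrative cost (none is priced anywhere).
3. **Latent status.** With probability 0.038 the child has treatable DDH;
   the Graf type (2b/c, D, 3/4) follows the printed shares 1.4 : 1.5 : 0.5.
   Those shares sum to 3.4%, not 3.8% — an internal inconsistency of the
   source tables — so the mix is renormalized to the configured prevalence;
   both numbers are configuration knobs.
4. **Test outcome.** Screener quality is given per screened child (false
   positives and missed cases as fractions of everyone screened), so the
   simulator converts to conditional probabilities:
   `miss_given_affected = miss_rate / prevalence` and
   `fp_given_healthy = fp_rate / (1 - prevalence)`. For the radiographic
   technician (fp 1.3%, missed 0.6%) at prevalence 0.038 these are 0.158 and
   0.0135. Detection is treated as detection-and-treatment within a year
   with probability one; no treatment-uptake loss is modeled.
5. **Costs.** Itemized per attended child (staff, travel, parent time,
   machine use, rent, downstream treatment), plus scenario-level fixed costs
   per replication: training of the scenario's screeners and one year's
   ownership of the purchased machines.

## Cost rules

All amounts are 2006 euros, societal perspective (parents' travel and time
count).

* **Staff.** The screener's hourly wage (physician 75, nurse 42, technician
  70, specialist 106) pro-rated to the ten-minute exam. In an *integrated*
  consultation with a technician or specialist screener, an IHC physician
  must also be present to run the regular consultation, adding their wage
  share; a delegating nurse replaces the physician's time and adds nothing.
  An *extra* consultation doubles the salary cost; evening sessions add 35%.
* **Parents.** One hour of productivity loss (EUR 36/h) for an integrated
  visit, two hours for an extra one; travel at EUR 0.20/km over the child's
  IHC distance (uniform 4–7 km) or a fixed 10 km for external locations,
  doubled for an extra consultation. The printed distances are charged as-is
  per visit (no separate return-trip doubling), since the km rate is applied
  directly to the 4–7 km range in the source.
* **Machines.** Purchase EUR 32,725 amortized over 5 years at 5% interest
  (annuity EUR 7,558.6, tabulated as 7,560), EUR 1,000/yr insurance, 8%
  maintenance: EUR 11,178 per machine-year, i.e. ~EUR 5 per child for one
  machine and 2,300 children. Internally the rounded-annuity convention is
  used so every audit total matches the printed figures, mirroring the
  training cost below. "Many machines" means one per IHC site with a default
  of seven sites (a configuration knob, `n_sites`); "limited" means one;
  "none" means no purchase, with ultrasound use billed at the hospital rate
  (EUR 61/h, pro-rated to ten minutes) per exam — the only printed price for
  non-owned ultrasound.
* **Training.** EUR 1,300 per trained screener (16 h × EUR 73 + EUR 130
  materials = 1,298, tabulated rounded); one screener per purchased machine,
  minimum one.
* **Downstream.** True positives cost their Graf type's treatment (2b/c
  EUR 897, D EUR 717, 3/4 EUR 2,043); missed cases EUR 1,217; false
  positives one hospital visit plus parental absence (EUR 61 + 36 = 97),
  applied to US screening identically to current screening.
* **Evening sessions.** The source states a 35% wage uplift *and* prints a
  flat EUR 5/child overhead; the flat fee is ≈35% of the average EUR 73 wage
  per ten-minute exam, i.e. the same quantity, so the uplift is applied and
  the flat fee is not (no double counting). `evening_flat_fee = TRUE`
  switches to the flat-fee variant.
* **External rent.** Never quantified in the source; default EUR 5 per
  child, configurable and worth sweeping (`one_way_sensitivity()`), since it
  moves only the 24 external-location scenarios.

The current-screening comparator applies the current programme's
per-screened-child rates directly (true positives 2.8%, false positives
16.5%, missed 0.9%) with downstream costs only — the physical exam is part
of the regular consultation. It is reported for context, and an optional
incremental ratio against it is provided; the headline measure remains the
average cost per screen-detected child.

## Design choices where the design was open

* **Scenario numbering.** The source's scenario IDs follow no recoverable
  rule, so a canonical mixed-radix numbering is defined (machines-major,
  location fastest) and all cross-scenario comparisons are made by level
  tuple, never by ID.
* **Quartiles by rank.** CE groups CE_A–CE_D are contiguous rank-based
  groups of 18 (sizes differ by at most one if the count is not divisible by
  four), matching "18 scenarios per group" exactly; ties (improbable with
  continuous costs) break by canonical id for determinism.
* **Replications.** The source does not state a replication count; the
  default is 100 with normal-approximation confidence intervals, and the
  acceptance checks run 200 replications per scenario, where the Monte-Carlo
  mean of total cost, TP, FP and FN must sit within 3 standard errors of the
  closed form for all 72 scenarios.
* **Randomness.** One root seed; per-scenario and per-replication seeds are
  split from it deterministically (`sample.int` on the seeded root stream),
  so results are bit-reproducible and independent of evaluation order.
* **Extra consultations** remove the physician-presence requirement, which
  concerns integrated consultations only.
* **Organizer.** Screening is IHC-organized whenever the screener is IHC
  staff *or* the location an IHC building; the converse ("externally
  organized" forcing an external organizer even for IHC staff) is not
  assumed.

## What the generator does and does not emulate

The synthetic cohort reproduces the study conditions: cohort size, horizon,
urban/rural mix, attendance and reminder behavior, prevalence and Graf mix,
pre-screening removal, and travel distances. It does **not** emulate
seasonal or spatial clustering of attendance, correlation between residence
and disease status, screener learning curves, capacity interactions between
children (queues, machine scheduling), or uncertainty in treatment
effectiveness. Passing tests therefore demonstrate internal correctness of
the costing and ranking machinery under the stated assumptions, not the
field performance of any scenario; scenario-level CE values depend on
unprinted inputs (external rent, the number of "many" machines, replication
counts), so only the *structure* of the ranking — which levels dominate the
best and worst quartiles — is expected to transfer.

## Problem sizes and numerical notes

The test suite evaluates all 72 scenarios at 200 replications of the
2,300-child cohort for the oracle-equivalence check, a 100,000-child cohort
for marginal-convergence and rate-recovery checks, and the deterministic
closed form for ranking checks; this keeps the full suite around a minute of
CPU. Degenerate parameterizations (no detectable children) raise an error
rather than returning an infinite ratio. The annuity uses the standard
closed form, cross-checked in the tests against an explicit amortization
schedule. Conditional rates at the prevalence boundaries (0 or 1) are
defined as zero for the empty stratum.

## Worked example

```{r example}
cfg <- experiment_config(mode = "EXPECTED")
ex <- run_experiment(cfg)
ex$quartiles$ranges
ex$extremes$top
```

A Monte-Carlo run of the best-ranked scenario with replication uncertainty:

```{r mc}
best <- scenario_from_id(ex$extremes$top$canonical_id[1])
simulate_scenario(best, n_reps = 50, seed = 1)
```
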