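# Experimental design: the four implementation variables and their levels.
# Level order follows the design table (variable A first, its level 1 first),
# which also fixes the canonical mixed-radix scenario numbering.

MACHINES_LEVELS <- c("MANY", "LIMITED", "NONE")
CONSULTATION_LEVELS <- c("INTEGRATED", "EXTRA")
SCREENER_LEVELS <- c("IHC_PHYSICIAN", "IHC_NURSE",
                     "RADIOGRAPHIC_TECHNICIAN", "MEDICAL_SPECIALIST")
LOCATION_LEVELS <- c("IHC_DAYTIME", "EXTERNAL", "IHC_EVENING")

#' Construct a screening implementation scenario
#'
#' A scenario is one cell of the full-factorial design over the four
#' experimental variables of the implementation study: number of portable
#' ultrasound machines purchased, whether the ultrasound exam is integrated
#' into the regular three-month consultation or requires an extra visit,
#' the discipline performing the scan, and the location/time of screening.
#'
#' @param machines `"MANY"` (one machine per infant health care site),
#'   `"LIMITED"` (a single machine), or `"NONE"` (use machines already
#'   available in external facilities such as obstetric centers).
#' @param consultation `"INTEGRATED"` (within the regular three-month visit)
#'   or `"EXTRA"` (a separate additional consultation).
#' @param screener `"IHC_PHYSICIAN"`, `"IHC_NURSE"`,
#'   `"RADIOGRAPHIC_TECHNICIAN"`, or `"MEDICAL_SPECIALIST"`.
#' @param location `"IHC_DAYTIME"`, `"EXTERNAL"` (rented building), or
#'   `"IHC_EVENING"` (evening sessions at the IHC).
#' @return An object of class `ddh_scenario`: a list with the four levels and
#'   the scenario's `canonical_id` (1--72) under the mixed-radix numbering
#'   (machines-major, then consultation, then screener, then location).
#' @seealso [enumerate_scenarios()], [scenario_from_id()], [staffing_plan()]
#' @export
#' @examples
#' scenario_spec("NONE", "INTEGRATED", "IHC_NURSE", "IHC_DAYTIME")
scenario_spec <- function(machines, consultation, screener, location) {
  machines <- match.arg(machines, MACHINES_LEVELS)
  consultation <- match.arg(consultation, CONSULTATION_LEVELS)
  screener <- match.arg(screener, SCREENER_LEVELS)
  location <- match.arg(location, LOCATION_LEVELS)
  spec <- list(
    machines = machines,
    consultation = consultation,
    screener = screener,
    location = location
  )
  spec$canonical_id <- scenario_id(spec)
  structure(spec, class = "ddh_scenario")
}

#' Canonical scenario number of a scenario
#'
#' Mixed-radix encoding with machines the most significant digit and
#' location the least: ids 1--72 enumerate location fastest.
#'
#' @param spec a `ddh_scenario` (or list with the four level fields).
#' @return Integer in 1..72.
#' @export
scenario_id <- function(spec) {
  m <- match(spec$machines, MACHINES_LEVELS)
  co <- match(spec$consultation, CONSULTATION_LEVELS)
  s <- match(spec$screener, SCREENER_LEVELS)
  l <- match(spec$location, LOCATION_LEVELS)
  if (anyNA(c(m, co, s, l))) stop("scenario has an unknown level", call. = FALSE)
  as.integer(((m - 1L) * 2L + (co - 1L)) * 12L + (s - 1L) * 3L + (l - 1L) + 1L)
}

#' Decode a canonical scenario number
#'
#' @param id integer in 1..72.
#' @return The `ddh_scenario` whose [scenario_id()] equals `id`.
#' @export
scenario_from_id <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 72L)
    stop("canonical scenario id must be a single integer in 1..72", call. = FALSE)
  z <- id - 1L
  l <- z %% 3L
  z <- z %/% 3L
  s <- z %% 4L
  z <- z %/% 4L
  co <- z %% 2L
  m <- z %/% 2L
  scenario_spec(MACHINES_LEVELS[m + 1L], CONSULTATION_LEVELS[co + 1L],
                SCREENER_LEVELS[s + 1L], LOCATION_LEVELS[l + 1L])
}

#' Enumerate all 72 implementation scenarios
#'
#' Returns the full factorial 3 x 2 x 4 x 3 design, ordered by canonical id.
#'
#' @return A list of 72 `ddh_scenario` objects, class `ddh_scenario_set`.
#'   Use [as.data.frame()] for a tabular view.
#' @export
#' @examples
#' length(enumerate_scenarios())
enumerate_scenarios <- function() {
  structure(lapply(seq_len(72L), scenario_from_id), class = "ddh_scenario_set")
}

#' @export
as.data.frame.ddh_scenario_set <- function(x, ...) {
  data.frame(
    canonical_id = vapply(x, function(s) s$canonical_id, integer(1)),
    machines = vapply(x, function(s) s$machines, character(1)),
    consultation = vapply(x, function(s) s$consultation, character(1)),
    screener = vapply(x, function(s) s$screener, character(1)),
    location = vapply(x, function(s) s$location, character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ddh_scenario <- function(x, ...) {
  cat(sprintf("DDH screening scenario #%d\n", x$canonical_id))
  cat(sprintf("  machines:     %s\n", x$machines))
  cat(sprintf("  consultation: %s\n", x$consultation))
  cat(sprintf("  screener:     %s\n", x$screener))
  cat(sprintf("  location:     %s\n", x$location))
  invisible(x)
}

#' @export
print.ddh_scenario_set <- function(x, ...) {
  cat(sprintf("Set of %d DDH screening scenarios (full factorial 3x2x4x3)\n",
              length(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (length(x) > 6L) cat("...\n")
  invisible(x)
}

#' Staffing and equipment consequences of a scenario
#'
#' Translates a scenario into its operational plan under the study's
#' assumptions: (1) screening is organized by the IHC whenever the screener
#' is IHC staff or the location an IHC building, otherwise externally;
#' (2) in an integrated consultation with a radiographic technician or a
#' medical specialist as screener, an IHC physician must be present at the
#' screening location to perform the regular consultation; (3) in an
#' integrated consultation with a nurse screener the physician delegates the
#' regular consultation tasks to the nurse.
#'
#' @param spec a `ddh_scenario`.
#' @param n_sites number of infant health care sites served when machines are
#'   `"MANY"` (one machine per site); default 7.
#' @return A list of class `ddh_staffing`: `machines_purchased`,
#'   `screeners_trained` (one per purchased machine, minimum one),
#'   `physician_present_at_exam`, `nurse_delegation`, `organizer`.
#' @export
#' @examples
#' staffing_plan(scenario_spec("MANY", "INTEGRATED",
#'                             "RADIOGRAPHIC_TECHNICIAN", "IHC_DAYTIME"))
staffing_plan <- function(spec, n_sites = 7L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1)
    stop("n_sites must be a single count >= 1", call. = FALSE)
  n_sites <- as.integer(n_sites)
  machines <- switch(spec$machines,
    MANY = n_sites,
    LIMITED = 1L,
    NONE = 0L
  )
  ihc_screener <- spec$screener %in% c("IHC_PHYSICIAN", "IHC_NURSE")
  ihc_building <- spec$location %in% c("IHC_DAYTIME", "IHC_EVENING")
  structure(list(
    machines_purchased = machines,
    screeners_trained = max(machines, 1L),
    physician_present_at_exam = spec$consultation == "INTEGRATED" &&
      spec$screener %in% c("RADIOGRAPHIC_TECHNICIAN", "MEDICAL_SPECIALIST"),
    nurse_delegation = spec$consultation == "INTEGRATED" &&
      spec$screener == "IHC_NURSE",
    organizer = if (ihc_screener || ihc_building) "IHC" else "EXTERNAL"
  ), class = "ddh_staffing")
}

#' @export
print.ddh_staffing <- function(x, ...) {
  cat("Staffing plan\n")
  cat(sprintf("  machines purchased:  %d\n", x$machines_purchased))
  cat(sprintf("  screeners trained:   %d\n", x$screeners_trained))
  cat(sprintf("  physician present:   %s\n", x$physician_present_at_exam))
  cat(sprintf("  nurse delegation:    %s\n", x$nurse_delegation))
  cat(sprintf("  organizer:           %s\n", x$organizer))
  invisible(x)
}

#' Write the scenario table to a delimited file
#'
#' One row per scenario with the canonical id and the four levels.
#'
#' @param path output file path (tab- or comma-separated by `sep`).
#' @param sep field separator, default `","`.
#' @return The data frame written, invisibly.
#' @export
write_scenario_table <- function(path, sep = ",") {
  df <- as.data.frame(enumerate_scenarios())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
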