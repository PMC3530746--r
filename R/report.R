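#' Load an exposure scenario from a YAML file
#'
#' The scenario file holds the population groups and the exposure context:
#' a `groups:` mapping keyed by group label with fields `size`, `bw_kg`,
#' `ir_dm3_day`, `ed_years`, `at_cancer_days`, `at_noncancer_days`, and a
#' `context:` block with `fi`, `ef`, `convention`,
#' `duration_matched_groups`. The packaged default scenario is at
#' `system.file("extdata", "scenario.yaml", package = "aquarisk")`.
#'
#' @param path Path to a scenario YAML file; `NULL` (default) returns the
#'   packaged [default_scenario()] groups and context.
#' @return A list with elements `groups` (tibble) and `context`
#'   ([exposure_context()]).
#' @export
load_scenario <- function(path = NULL) {
  if (is.null(path)) {
    sc <- default_scenario()
    return(list(groups = sc$groups, context = sc$context))
  }
  doc <- yaml::read_yaml(path)
  groups <- purrr::imap(doc$groups %||% list(), function(g, label) {
    tibble(
      group_label = label,
      size = as.numeric(g$size),
      bw_kg = as.numeric(g$bw_kg),
      ir_dm3_day = as.numeric(g$ir_dm3_day),
      ed_years = as.numeric(g$ed_years),
      at_cancer_days = as.numeric(g$at_cancer_days),
      at_noncancer_days = as.numeric(g$at_noncancer_days)
    )
  })
  groups <- validate_groups(bind_rows(groups))
  cx <- doc$context %||% list()
  context <- exposure_context(
    fi = cx$fi %||% 0.65,
    ef = cx$ef %||% 365,
    convention = cx$convention %||% "epa_lifetime",
    duration_matched_groups =
      unlist(cx$duration_matched_groups) %||% character()
  )
  list(groups = groups, context = context)
}

#' Write the full report bundle of an assessment
#'
#' Emits every table of a [assess_risk()] result as CSV at full numeric
#' precision — concentrations, screening, doses, cancer risks, population
#' burden, hazards — plus a machine-readable `summary.json` holding the
#' per-group cumulative risks and classifications, the whole-population
#' expected extra cancer cases, the per-group hazard indices, and every
#' parameter the run used (the audit trail of the conservative assessment).
#' Re-running the same deterministic assessment reproduces the bundle
#' byte-for-byte.
#'
#' @param assessment A [assess_risk()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(assessment, dir) {
  stopifnot(inherits(assessment, "risk_assessment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  write_concentration_summary(assessment$summaries, p("concentrations.csv"))
  readr::write_csv(assessment$screening, p("screening.csv"))
  readr::write_csv(assessment$doses, p("doses.csv"))
  readr::write_csv(assessment$risks, p("cancer_risk.csv"))
  readr::write_csv(assessment$burden, p("population_burden.csv"))
  readr::write_csv(assessment$hazards, p("hazard.csv"))

  totals <- filter(assessment$risks, .data$analyte_cas == "TOTAL")
  his <- filter(assessment$hazards, .data$analyte_cas == "TOTAL")
  summary <- list(
    elcr_tot = setNames(as.list(totals$elcr), totals$group_label),
    classification = setNames(as.list(as.character(totals$classification)),
                              totals$group_label),
    ecc_general_population = assessment$burden$ecc[
      assessment$burden$group_label == "general_population"],
    hazard_index = setNames(as.list(his$hq), his$group_label),
    screening_pass = all(assessment$screening$pass, na.rm = TRUE),
    parameters = assessment$params[setdiff(names(assessment$params), "groups")],
    groups = assessment$params$groups
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(p(c("concentrations.csv", "screening.csv", "doses.csv",
                "cancer_risk.csv", "population_burden.csv", "hazard.csv",
                "summary.json")))
}
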