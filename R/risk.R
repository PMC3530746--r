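#' Individual excess lifetime cancer risk from a dose
#'
#' Converts a daily dose into a unitless cancer probability via the oral
#' slope factor. The `"one_hit"` model (default) uses the exponential
#' low-dose carcinogenesis form `1 - exp(-dose * sf)`; the `"linear"` model
#' uses `dose * sf` (capped at 1), valid when the risk is below about 0.01;
#' `"auto"` uses the linear form when `dose * sf < 0.01` and the one-hit
#' form otherwise.
#'
#' @param dose Daily dose, mg/(kg*day), nonnegative (vectorised).
#' @param sf Oral cancer slope factor, (mg/(kg*day))^-1, positive.
#' @param model `"one_hit"` (default), `"linear"`, or `"auto"`.
#' @return Excess cancer probability in \[0, 1).
#' @export
#' @examples
#' cancer_risk(2.518e-6, 2.0)              # one-hit
#' cancer_risk(2.518e-6, 2.0, "linear")
cancer_risk <- function(dose, sf, model = c("one_hit", "linear", "auto")) {
  model <- match.arg(model)
  if (any(dose < 0)) abort("dose must be nonnegative")
  if (any(sf <= 0)) abort("slope factor must be positive")
  x <- dose * sf
  switch(model,
    one_hit = -expm1(-x),  # 1 - exp(-x), stable for small x
    linear = pmin(x, 1),
    auto = ifelse(x < 0.01, pmin(x, 1), -expm1(-x))
  )
}

#' Cumulative cancer risk over multiple carcinogens
#'
#' Adds per-substance excess risks, per the additivity rule for the
#' cumulative effect of carcinogens. A warning is raised when the sum
#' exceeds 1 (the additive approximation has broken down).
#'
#' @param risks Numeric vector of per-substance risks, each in \[0, 1).
#' @return The summed risk.
#' @export
cumulative_risk <- function(risks) {
  if (any(risks < 0) || any(risks >= 1)) {
    abort("each risk must lie in [0, 1)")
  }
  total <- sum(risks)
  if (total > 1) {
    warn("cumulative risk exceeds 1; additive approximation is not meaningful")
  }
  total
}

#' Expected extra cancer cases in a population
#'
#' Converts an individual excess lifetime cancer risk into an absolute
#' expected number of extra cancer cases, `ECC = ELCR * N`. The expectation
#' is kept real-valued; it is meaningful only for appropriately large
#' populations.
#'
#' @param elcr Individual excess risk in \[0, 1) (vectorised).
#' @param size Population size, persons, nonnegative.
#' @return Expected number of extra cancer cases.
#' @export
extra_cancer_cases <- function(elcr, size) {
  if (any(elcr < 0) || any(elcr >= 1)) abort("elcr must lie in [0, 1)")
  if (any(size < 0)) abort("population size must be nonnegative")
  elcr * size
}

#' Hazard quotient for noncarcinogenic effects
#'
#' `HQ = ADD / RfD`: the average daily dose relative to the chronic oral
#' reference dose. An HQ below 1 means the intake is below the level at
#' which noncancer effects are expected.
#'
#' @param add Average daily dose, mg/(kg*day), nonnegative (vectorised).
#' @param rfd Reference dose, mg/(kg*day), positive.
#' @return Dimensionless hazard quotient.
#' @export
hazard_quotient <- function(add, rfd) {
  if (any(add < 0)) abort("dose must be nonnegative")
  if (any(is.na(rfd)) || any(rfd <= 0)) abort("reference dose must be positive")
  add / rfd
}

#' Hazard index over multiple substances
#'
#' The aggregate noncancer hazard: the sum of hazard quotients. An HI above
#' 1 flags that harmful noncarcinogenic health effects may arise at the
#' given exposure.
#'
#' @param hqs Numeric vector of hazard quotients, each nonnegative.
#' @return The summed hazard index (0 for an empty input).
#' @export
hazard_index <- function(hqs) {
  if (any(hqs < 0)) abort("hazard quotients must be nonnegative")
  sum(hqs)
}

risk_levels <- c("negligible", "acceptable_range", "remediation_desirable",
                 "protective_measures_required")

#' Classify an excess cancer risk against acceptability bands
#'
#' Bins an individual excess lifetime cancer risk into the conventional
#' regulatory bands: below 1e-6 the risk is unconditionally acceptable
#' (negligible); between 1e-6 and 1e-4 it sits in the usually-assumed
#' acceptable range; between 1e-4 and 1e-3 remediation is desirable; at
#' 1e-3 and above protective measures are absolutely required. Bins are
#' half-open with the lower bound inclusive.
#'
#' @param elcr Excess risk in \[0, 1) (vectorised).
#' @return An ordered factor with levels `negligible < acceptable_range <
#'   remediation_desirable < protective_measures_required`.
#' @export
#' @examples
#' classify_risk(c(0, 1e-6, 5.855e-6, 2e-4, 1e-3))
classify_risk <- function(elcr) {
  if (any(elcr < 0) || any(elcr >= 1)) abort("elcr must lie in [0, 1)")
  cut(elcr, breaks = c(-Inf, 1e-6, 1e-4, 1e-3, Inf), labels = risk_levels,
      right = FALSE, ordered_result = TRUE)
}

# attach the slope factor in force for a given configuration
sf_in_force <- function(registry, sf_config) {
  switch(sf_config,
    table5 = select(registry, "analyte_cas", sf = "sf_oral"),
    as_published = mutate(select(registry, "analyte_cas"), sf = 2.0)
  )
}

#' Cancer-risk matrix over analytes and population groups
#'
#' Applies the dose-response model to every cell of a dose table and appends
#' a per-group cumulative-risk row (`analyte_cas = "TOTAL"`), with each
#' risk classified against the acceptability bands.
#'
#' Two named slope-factor configurations are available. `"table5"`
#' (default) uses each analyte's registry slope factor. `"as_published"`
#' applies the PCB-mixture slope factor 2.0 to all five analytes, the
#' configuration under which the packaged study's printed risk tables
#' reproduce exactly; see the methods vignette for the discrepancy between
#' the two.
#'
#' @param doses Output of [dose_table()].
#' @param registry Toxicity registry tibble (see
#'   [default_toxicity_registry()]). Analytes without a slope factor are
#'   skipped with a warning.
#' @param sf_config `"table5"` or `"as_published"`.
#' @param model Dose-response model passed to [cancer_risk()].
#' @return A tibble with columns `analyte_cas`, `analyte_name`,
#'   `group_label`, `elcr`, `classification`; per-group totals carry
#'   `analyte_cas = "TOTAL"`.
#' @export
risk_table <- function(doses, registry = default_toxicity_registry(),
                       sf_config = c("table5", "as_published"),
                       model = c("one_hit", "linear", "auto")) {
  sf_config <- match.arg(sf_config)
  model <- match.arg(model)
  validate_registry(registry)
  cells <- doses |>
    left_join(sf_in_force(registry, sf_config), by = "analyte_cas")
  no_sf <- is.na(cells$sf)
  if (any(no_sf)) {
    warn(sprintf("no slope factor for analyte(s), skipped from cancer risk: %s",
                 paste(unique(cells$analyte_cas[no_sf]), collapse = ", ")))
    cells <- cells[!no_sf, , drop = FALSE]
  }
  cells <- cells |>
    mutate(elcr = cancer_risk(.data$ladd_mg_kg_day, .data$sf, model)) |>
    select("analyte_cas", "analyte_name", "group_label", "elcr")
  totals <- cells |>
    group_by(.data$group_label) |>
    summarise(elcr = cumulative_risk(.data$elcr), .groups = "drop") |>
    mutate(analyte_cas = "TOTAL", analyte_name = "All pollutants")
  bind_rows(cells, totals) |>
    mutate(classification = classify_risk(.data$elcr))
}

#' Population burden: expected extra cancer cases
#'
#' Scales individual excess risks to absolute expected extra cancer cases
#' per (analyte, group) cell, with per-group totals
#' (`analyte_cas = "TOTAL"`) and the grand total over all groups and
#' analytes (`group_label = "general_population"`, the ECC for the whole
#' served population).
#'
#' @param risks Output of [risk_table()].
#' @param groups Population tibble supplying group sizes.
#' @return A tibble with columns `analyte_cas`, `analyte_name`,
#'   `group_label`, `ecc`.
#' @export
population_burden <- function(risks, groups = population_groups()) {
  groups <- validate_groups(groups)
  cells <- risks |>
    filter(.data$analyte_cas != "TOTAL") |>
    left_join(select(groups, "group_label", "size"), by = "group_label") |>
    mutate(ecc = extra_cancer_cases(.data$elcr, .data$size)) |>
    select("analyte_cas", "analyte_name", "group_label", "ecc")
  totals <- cells |>
    group_by(.data$group_label) |>
    summarise(ecc = sum(.data$ecc), .groups = "drop") |>
    mutate(analyte_cas = "TOTAL", analyte_name = "All pollutants")
  grand <- tibble(
    analyte_cas = "TOTAL", analyte_name = "All pollutants",
    group_label = "general_population", ecc = sum(cells$ecc)
  )
  bind_rows(cells, totals, grand)
}

#' Noncancer hazard matrix over analytes and population groups
#'
#' Computes the hazard quotient `ADD / RfD` for every cell of a dose table
#' and the per-group hazard index (`analyte_cas = "TOTAL"`), flagging any
#' HI above 1. Analytes lacking a reference dose are skipped from the HQ
#' matrix and the HI, with a prominent warning, since no quotient can be
#' formed.
#'
#' @param doses Output of [dose_table()].
#' @param registry Toxicity registry tibble supplying RfDs.
#' @return A tibble with columns `analyte_cas`, `analyte_name`,
#'   `group_label`, `hq` (the per-group HI rows carry
#'   `analyte_cas = "TOTAL"`), and `exceeds_unity`.
#' @export
hazard_table <- function(doses, registry = default_toxicity_registry()) {
  validate_registry(registry)
  cells <- doses |>
    left_join(select(registry, "analyte_cas", "rfd"), by = "analyte_cas")
  no_rfd <- is.na(cells$rfd)
  if (any(no_rfd)) {
    warn(sprintf(
      "no reference dose for analyte(s), excluded from HQ/HI: %s",
      paste(unique(cells$analyte_cas[no_rfd]), collapse = ", ")))
    cells <- cells[!no_rfd, , drop = FALSE]
  }
  cells <- cells |>
    mutate(hq = hazard_quotient(.data$add_mg_kg_day, .data$rfd)) |>
    select("analyte_cas", "analyte_name", "group_label", "hq")
  totals <- cells |>
    group_by(.data$group_label) |>
    summarise(hq = hazard_index(.data$hq), .groups = "drop") |>
    mutate(analyte_cas = "TOTAL", analyte_name = "All pollutants (HI)")
  bind_rows(cells, totals) |>
    mutate(exceeds_unity = .data$hq > 1)
}
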