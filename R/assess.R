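#' Run the full drinking-water risk assessment
#'
#' One call from raw monitoring records to a complete characterisation:
#' exposure-point concentrations, regulatory screening, the analyte-by-group
#' dose matrix (LADD and ADD), excess lifetime cancer risks with
#' classifications, expected extra cancer cases, and noncancer hazard
#' quotients and indices.
#'
#' @param records Tibble of monitoring records (see
#'   [read_monitoring_csv()] or [generate_campaign()]).
#' @param supply_sites Character vector of supply `site_id`s; defaults to
#'   the supply sites of [study_sites()].
#' @param groups Population tibble, see [population_groups()].
#' @param ctx An [exposure_context()].
#' @param registry Toxicity registry tibble.
#' @param sf_config Slope-factor configuration, see [risk_table()].
#' @param model Dose-response model, see [cancer_risk()].
#' @param censor_policy Below-LOQ substitution policy, see
#'   [summarize_concentrations()].
#' @param standards Regulatory standards, see [default_standards()].
#' @return An object of class `"risk_assessment"`: a list with components
#'   `summaries`, `screening`, `doses`, `risks`, `burden`, `hazards`, and
#'   `params` (every parameter in force, for the audit trail). Methods:
#'   [tidy()][tidy.risk_assessment()], [glance()][glance.risk_assessment()],
#'   [autoplot()][autoplot.risk_assessment()], `print()`.
#' @export
#' @examples
#' records <- generate_campaign(campaign_spec(cv = 0, n_dates = 1))
#' ra <- assess_risk(records, sf_config = "as_published")
#' glance(ra)
assess_risk <- function(records,
                        supply_sites = NULL,
                        groups = population_groups(),
                        ctx = exposure_context(),
                        registry = default_toxicity_registry(),
                        sf_config = c("table5", "as_published"),
                        model = c("one_hit", "linear", "auto"),
                        censor_policy = c("as_reported", "zero", "half_loq"),
                        standards = default_standards()) {
  sf_config <- match.arg(sf_config)
  model <- match.arg(model)
  censor_policy <- match.arg(censor_policy)
  if (is.null(supply_sites)) {
    sites <- study_sites()
    supply_sites <- sites$site_id[sites$supply]
  }
  summaries <- summarize_concentrations(records, supply_sites, censor_policy)
  screening <- screen_concentrations(summaries, standards)
  doses <- dose_table(summaries, groups, ctx)
  risks <- risk_table(doses, registry, sf_config, model)
  burden <- population_burden(risks, groups)
  hazards <- hazard_table(doses, registry)
  structure(
    list(
      summaries = summaries, screening = screening, doses = doses,
      risks = risks, burden = burden, hazards = hazards,
      params = list(
        supply_sites = supply_sites, censor_policy = censor_policy,
        sf_config = sf_config, model = model,
        fi = ctx$fi, ef = ctx$ef, convention = ctx$convention,
        duration_matched_groups = ctx$duration_matched_groups,
        groups = groups
      )
    ),
    class = "risk_assessment"
  )
}

#' Tidy an assessment into one row per (analyte, group) cell
#'
#' @param x A [assess_risk()] result.
#' @param ... Unused.
#' @return A tibble with columns `analyte_cas`, `analyte_name`,
#'   `group_label`, `ladd_mg_kg_day`, `add_mg_kg_day`, `elcr`,
#'   `classification`, `ecc`, `hq`; per-group totals carry
#'   `analyte_cas = "TOTAL"`.
#' @method tidy risk_assessment
#' @export
tidy.risk_assessment <- function(x, ...) {
  keys <- c("analyte_cas", "group_label")
  x$risks |>
    left_join(select(x$doses, dplyr::all_of(keys), "ladd_mg_kg_day",
                     "add_mg_kg_day"),
              by = keys) |>
    left_join(select(x$burden, dplyr::all_of(keys), "ecc"), by = keys) |>
    left_join(select(x$hazards, dplyr::all_of(keys), "hq"), by = keys) |>
    select("analyte_cas", "analyte_name", "group_label", "ladd_mg_kg_day",
           "add_mg_kg_day", "elcr", "classification", "ecc", "hq")
}

#' One-row summary of an assessment
#'
#' @param x A [assess_risk()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_analytes`, `n_groups`, `screening_pass`
#'   (all scopes compliant), `max_elcr_tot` (worst per-group cumulative
#'   risk), `worst_classification`, `ecc_general_population`, `max_hi`,
#'   `hi_exceeds_unity`.
#' @method glance risk_assessment
#' @export
glance.risk_assessment <- function(x, ...) {
  totals <- filter(x$risks, .data$analyte_cas == "TOTAL")
  his <- filter(x$hazards, .data$analyte_cas == "TOTAL")
  tibble(
    n_analytes = dplyr::n_distinct(x$doses$analyte_cas),
    n_groups = dplyr::n_distinct(x$doses$group_label),
    screening_pass = all(x$screening$pass, na.rm = TRUE),
    max_elcr_tot = max(totals$elcr),
    worst_classification = max(totals$classification),
    ecc_general_population =
      x$burden$ecc[x$burden$group_label == "general_population"],
    max_hi = max(his$hq),
    hi_exceeds_unity = any(his$exceeds_unity)
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "e", digits = 3)
  cat("Drinking-water risk assessment\n")
  cat(sprintf("  analytes: %d  groups: %d  sf_config: %s  model: %s  convention: %s\n",
              dplyr::n_distinct(x$doses$analyte_cas),
              dplyr::n_distinct(x$doses$group_label),
              x$params$sf_config, x$params$model, x$params$convention))
  cat(sprintf("  screening: %s\n",
              if (all(x$screening$pass, na.rm = TRUE)) "all standards met"
              else "EXCEEDANCE"))
  totals <- filter(x$risks, .data$analyte_cas == "TOTAL")
  for (i in seq_len(nrow(totals))) {
    cat(sprintf("  ELCR_tot %-14s %s (%s)\n", totals$group_label[i],
                fmt(totals$elcr[i]), as.character(totals$classification[i])))
  }
  ecc <- x$burden$ecc[x$burden$group_label == "general_population"]
  cat(sprintf("  expected extra cancer cases, whole population: %s\n", fmt(ecc)))
  his <- filter(x$hazards, .data$analyte_cas == "TOTAL")
  cat(sprintf("  hazard index range: %s - %s%s\n", fmt(min(his$hq)),
              fmt(max(his$hq)),
              if (any(his$exceeds_unity)) "  ** HI > 1 **" else ""))
  invisible(x)
}

#' Plot excess lifetime cancer risks per analyte and group
#'
#' Bar chart of the per-analyte ELCR within each population group, on a
#' log10 axis, with the unconditionally-acceptable (1e-6) and
#' remediation-desirable (1e-4) thresholds drawn as reference lines.
#'
#' @param object A [assess_risk()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_assessment
#' @export
autoplot.risk_assessment <- function(object, ...) {
  cells <- object$risks |>
    filter(.data$analyte_cas != "TOTAL", .data$elcr > 0) |>
    mutate(analyte = sub(" .*", "", .data$analyte_name))
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$analyte, y = .data$elcr,
                               fill = .data$group_label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(1e-6, 1e-4), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Excess lifetime cancer risk",
                  fill = "Population") +
    ggplot2::theme_minimal()
}
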