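#' Default toxicity registry
#'
#' Per-analyte dose-response constants for the packaged study pollutants:
#' oral cancer slope factor SF0 in (mg/(kg*day))^-1, chronic oral reference
#' dose RfD in mg/(kg*day), NOAEL where available, and the US EPA carcinogen
#' class. The PCB congener mixture is carried under the synthetic key
#' `"SUM-PCB"` because a single Aroclor-mixture slope factor applies to total
#' PCBs, not to individual congeners. gamma-HCH has not been assigned an EPA
#' carcinogen class (`"unclassified"`) but still carries a slope factor
#' (RAIS) used in risk computation.
#'
#' @return A tibble with columns `analyte_cas`, `analyte_name`,
#'   `analyte_class`, `carcinogen_class`, `sf_oral`, `rfd`, `noael`.
#' @export
#' @examples
#' default_toxicity_registry()
default_toxicity_registry <- function() {
  tibble::tribble(
    ~analyte_cas, ~analyte_name,                                   ~analyte_class, ~carcinogen_class, ~sf_oral, ~rfd,  ~noael,
    "SUM-PCB",    "Polychlorinated biphenyls",                     "PCB", "B2",           2.0,  2e-5, 0.007,
    "58-89-9",    "1,2,3,4,5,6-Hexachlorocyclohexane (gamma-HCH)", "COP", "unclassified", 1.10, 3e-4, 0.33,
    "72-55-9",    "p,p'-Dichlorodiphenyldichloroethylene (DDE)",   "COP", "B2",           0.34, 3e-3, NA_real_,
    "72-54-8",    "p,p'-Dichlorodiphenyl dichloroethane (DDD)",    "COP", "B2",           0.24, 9e-3, NA_real_,
    "50-29-3",    "p,p'-Dichlorodiphenyltrichloroethane (DDT)",    "COP", "B2",           0.34, 5e-4, 0.05
  )
}

validate_registry <- function(registry) {
  registry <- as_tibble(registry)
  needed <- c("analyte_cas", "analyte_name", "analyte_class",
              "carcinogen_class", "sf_oral", "rfd", "noael")
  missing <- setdiff(needed, names(registry))
  if (length(missing) > 0) {
    abort(sprintf("toxicity registry is missing field(s): %s",
                  paste(missing, collapse = ", ")),
          class = "aquarisk_format_error")
  }
  dup <- registry$analyte_cas[duplicated(registry$analyte_cas)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate analyte(s) in toxicity registry: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  for (col in c("sf_oral", "rfd", "noael")) {
    bad <- which(!is.na(registry[[col]]) & registry[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("nonpositive %s for analyte(s): %s", col,
                    paste(registry$analyte_cas[bad], collapse = ", ")))
    }
  }
  registry
}

#' Load a toxicity registry from a YAML file
#'
#' The registry file holds one block per analyte under `analytes:`, keyed by
#' CAS (or the synthetic `SUM-PCB` key), with fields `name`, `class`,
#' `carcinogen_class`, `sf_oral`, `rfd`, `noael` (absent constants omitted).
#' The packaged default registry is at
#' `system.file("extdata", "toxicity_registry.yaml", package = "aquarisk")`.
#'
#' @param path Path to a registry YAML file; `NULL` (default) returns
#'   [default_toxicity_registry()].
#' @return A validated registry tibble.
#' @export
load_toxicity_registry <- function(path = NULL) {
  if (is.null(path)) {
    return(validate_registry(default_toxicity_registry()))
  }
  doc <- yaml::read_yaml(path)
  entries <- doc$analytes %||% list()
  if (length(entries) == 0) {
    return(validate_registry(default_toxicity_registry()[0, ]))
  }
  rows <- purrr::imap(entries, function(e, cas) {
    tibble(
      analyte_cas = cas,
      analyte_name = e$name %||% cas,
      analyte_class = e$class %||% NA_character_,
      carcinogen_class = e$carcinogen_class %||% "unclassified",
      sf_oral = as.numeric(e$sf_oral %||% NA_real_),
      rfd = as.numeric(e$rfd %||% NA_real_),
      noael = as.numeric(e$noael %||% NA_real_)
    )
  })
  validate_registry(bind_rows(rows))
}

#' Default drinking-water regulatory standards
#'
#' The standards the measured concentrations are screened against: the US
#' EPA maximum contaminant level for total PCBs (0.0005 mg/dm3) and the EU
#' Council Directive 98/83/EC limits for any single pesticide
#' (0.0001 mg/dm3) and total pesticides (0.0005 mg/dm3).
#'
#' @return A tibble with columns `scope` (`"pcb_total"`,
#'   `"pesticide_single"`, `"pesticide_total"`), `limit_mg_dm3`, `authority`.
#' @export
default_standards <- function() {
  tibble::tribble(
    ~scope,             ~limit_mg_dm3, ~authority,
    "pcb_total",        5e-4,          "US EPA MCL",
    "pesticide_single", 1e-4,          "EU 98/83/EC",
    "pesticide_total",  5e-4,          "EU 98/83/EC"
  )
}

#' Screen exposure-point concentrations against drinking-water standards
#'
#' Compares the PCB class total against the PCB MCL, each individual
#' pesticide against the single-pesticide limit, and the COP class total
#' against the total-pesticide limit. Measured concentrations (ng/dm3) are
#' converted to mg/dm3 for the comparison. A concentration exactly equal to
#' its limit complies: the limit is the maximum permitted level.
#'
#' @param summaries Output of [summarize_concentrations()].
#' @param standards Standards tibble; defaults to [default_standards()]. A
#'   missing scope is reported as not evaluated, with a warning.
#' @return A tibble with one row per comparison: `scope`, `analyte_name`,
#'   `measured_mg_dm3`, `limit_mg_dm3`, `authority`, `pass` (logical; `NA`
#'   when not evaluated).
#' @export
screen_concentrations <- function(summaries, standards = default_standards()) {
  get_limit <- function(scope) {
    row <- standards[standards$scope == scope, , drop = FALSE]
    if (nrow(row) == 0) {
      warn(sprintf("no standard for scope '%s'; not evaluated", scope))
      tibble(limit_mg_dm3 = NA_real_, authority = NA_character_)
    } else {
      row[1, c("limit_mg_dm3", "authority")]
    }
  }

  pcb <- get_limit("pcb_total")
  single <- get_limit("pesticide_single")
  total <- get_limit("pesticide_total")

  pesticides <- filter(summaries, .data$analyte_class %in% "COP")
  out <- bind_rows(
    tibble(scope = "pcb_total",
           analyte_name = "Total PCBs",
           measured_mg_dm3 = as_mg_dm3(class_total(summaries, "PCB")),
           limit_mg_dm3 = pcb$limit_mg_dm3, authority = pcb$authority),
    tibble(scope = "pesticide_single",
           analyte_name = pesticides$analyte_name,
           measured_mg_dm3 = as_mg_dm3(pesticides$cross_site_mean),
           limit_mg_dm3 = single$limit_mg_dm3, authority = single$authority),
    tibble(scope = "pesticide_total",
           analyte_name = "Total pesticides",
           measured_mg_dm3 = as_mg_dm3(class_total(summaries, "COP")),
           limit_mg_dm3 = total$limit_mg_dm3, authority = total$authority)
  )
  mutate(out, pass = .data$measured_mg_dm3 <= .data$limit_mg_dm3)
}
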