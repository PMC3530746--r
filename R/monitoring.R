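#' Packaged analyte catalogue
#'
#' The 17 analytes monitored in the packaged well-water study: 13
#' polychlorinated biphenyl (PCB) congeners and 4 chloroorganic pesticides
#' (COP: gamma-HCH and the DDT family). Each analyte is identified by its CAS
#' number; the class drives aggregation (PCB congeners are totalled before
#' dose calculation, pesticides are carried individually).
#'
#' @return A tibble with columns `analyte_cas`, `analyte_name`,
#'   `analyte_class` (`"PCB"` or `"COP"`), and `loq_ng_dm3` (limit of
#'   quantification; 1 ng/dm3 for all analytes except DDE, 5 ng/dm3).
#' @export
#' @examples
#' pollutant_catalogue()
pollutant_catalogue <- function() {
  tibble::tribble(
    ~analyte_cas,  ~analyte_name,                                        ~analyte_class, ~loq_ng_dm3,
    "37680-65-2",  "PCB18 2,2',5-trichlorobiphenyl",                     "PCB", 1,
    "38444-84-7",  "PCB20 2,3,3'-trichlorobiphenyl",                     "PCB", 1,
    "7012-37-5",   "PCB28 2,4,4'-trichlorobiphenyl",                     "PCB", 1,
    "41464-39-5",  "PCB44 2,2',3,5'-tetrachlorobiphenyl",                "PCB", 1,
    "35693-99-3",  "PCB52 2,2',5,5'-tetrachlorobiphenyl",                "PCB", 1,
    "37680-73-2",  "PCB101 2,2',4,5,5'-pentachlorobiphenyl",             "PCB", 1,
    "31508-00-6",  "PCB118 2,3',4,4',5-pentachlorobiphenyl",             "PCB", 1,
    "32598-14-4",  "PCB105 2,3,3',4,4'-pentachlorobiphenyl",             "PCB", 1,
    "35065-27-1",  "PCB153 2,2',4,4',5,5'-hexachlorobiphenyl",           "PCB", 1,
    "35065-28-2",  "PCB138 2,2',3,4,4',5'-hexachlorobiphenyl",           "PCB", 1,
    "35065-30-6",  "PCB170 2,2',3,3',4,4',5-heptachlorobiphenyl",        "PCB", 1,
    "35065-29-3",  "PCB180 2,2',3,4,4',5,5'-heptachlorobiphenyl",        "PCB", 1,
    "35694-08-7",  "PCB194 2,2',3,3',4,4',5,5'-octachlorobiphenyl",      "PCB", 1,
    "58-89-9",     "1,2,3,4,5,6-Hexachlorocyclohexane (gamma-HCH)",      "COP", 1,
    "72-55-9",     "p,p'-Dichlorodiphenyldichloroethylene (DDE)",        "COP", 5,
    "72-54-8",     "p,p'-Dichlorodiphenyl dichloroethane (DDD)",         "COP", 1,
    "50-29-3",     "p,p'-Dichlorodiphenyltrichloroethane (DDT)",         "COP", 1
  )
}

monitoring_columns <- c(
  "site_id", "sample_date", "analyte_cas", "analyte_name",
  "value_ng_dm3", "below_loq", "loq_ng_dm3"
)

#' Validate a tibble of monitoring records
#'
#' Checks the invariants every concentration record must satisfy:
#' nonnegative values, positive limits of quantification, and censored
#' (below-LOQ) values strictly below their LOQ. Used by both
#' [read_monitoring_csv()] and the synthetic campaign generator.
#'
#' @param records A data frame with the monitoring columns `site_id`,
#'   `sample_date`, `analyte_cas`, `analyte_name`, `value_ng_dm3`,
#'   `below_loq`, `loq_ng_dm3`.
#' @return The records as a tibble, invisibly unchanged, or an error naming
#'   the first offending column or row.
#' @export
validate_monitoring_records <- function(records) {
  records <- as_tibble(records)
  missing <- setdiff(monitoring_columns, names(records))
  if (length(missing) > 0) {
    abort(sprintf("monitoring data is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "aquarisk_format_error")
  }
  records$below_loq <- as.logical(records$below_loq)
  bad <- which(is.na(records$value_ng_dm3) | records$value_ng_dm3 < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or missing concentration in row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "aquarisk_validation_error")
  }
  bad <- which(!is.finite(records$loq_ng_dm3) | records$loq_ng_dm3 <= 0)
  if (length(bad) > 0) {
    abort(sprintf("nonpositive limit of quantification in row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "aquarisk_validation_error")
  }
  bad <- which(records$below_loq & records$value_ng_dm3 >= records$loq_ng_dm3)
  if (length(bad) > 0) {
    abort(sprintf("below-LOQ record with value >= LOQ in row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "aquarisk_validation_error")
  }
  records
}

#' Read a monitoring CSV file
#'
#' Reads raw per-sample analyte concentrations in the package's monitoring
#' dialect: a UTF-8 CSV with header
#' `site_id,sample_date,analyte_cas,analyte_name,value_ng_dm3,below_loq,loq_ng_dm3`,
#' ISO-8601 dates and 0/1 censoring flags. Concentrations are in ng/dm3.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated concentration records, one row per
#'   determination, with `sample_date` parsed to `Date` and `below_loq`
#'   logical. An empty data section yields a zero-row tibble with a warning.
#' @export
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' readr::write_csv(
#'   tibble::tibble(site_id = "well_I", sample_date = as.Date("2010-04-01"),
#'                  analyte_cas = "37680-65-2", analyte_name = "PCB18",
#'                  value_ng_dm3 = 2.44, below_loq = 0L, loq_ng_dm3 = 1),
#'   csv)
#' read_monitoring_csv(csv)
read_monitoring_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("monitoring file does not exist: %s", path))
  }
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      sample_date = readr::col_date(),
      analyte_cas = readr::col_character(),
      analyte_name = readr::col_character(),
      value_ng_dm3 = readr::col_double(),
      below_loq = readr::col_character(),  # 0/1 or TRUE/FALSE
      loq_ng_dm3 = readr::col_double()
    )
  )
  missing <- setdiff(monitoring_columns, names(records))
  if (length(missing) > 0) {
    abort(sprintf("monitoring CSV %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "aquarisk_format_error")
  }
  flag <- tolower(trimws(records$below_loq))
  bad <- which(!flag %in% c("0", "1", "true", "false", "t", "f"))
  if (length(bad) > 0) {
    abort(sprintf("unparseable below_loq flag in row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "aquarisk_format_error")
  }
  records$below_loq <- flag %in% c("1", "true", "t")
  if (nrow(records) == 0) {
    warn(sprintf("monitoring CSV %s has an empty data section", path))
  }
  validate_monitoring_records(records)
}

apply_censor_policy <- function(records, censor_policy) {
  switch(censor_policy,
    as_reported = records$value_ng_dm3,
    zero = ifelse(records$below_loq, 0, records$value_ng_dm3),
    half_loq = ifelse(records$below_loq, records$loq_ng_dm3 / 2,
                      records$value_ng_dm3)
  )
}

#' Summarise monitoring records into exposure-point concentrations
#'
#' Computes the per-site mean concentration of every analyte and the
#' cross-site exposure-point concentration: the unweighted arithmetic mean of
#' the per-site means over the designated supply sites. Non-supply sites
#' (e.g. a river used only for surveillance) contribute per-site means but
#' are excluded from the exposure-point concentration, because risk is
#' computed for water actually drawn for consumption.
#'
#' Censored (below-LOQ) values are, by default, used as reported
#' (`as_reported`): very low determinations are retained rather than blanked
#' out. The `zero` and `half_loq` substitution policies are provided for
#' sensitivity analyses of the censoring treatment.
#'
#' @param records A tibble of monitoring records (see
#'   [read_monitoring_csv()]).
#' @param supply_sites Character vector of `site_id`s that feed the drinking
#'   water supply. Must be nonempty.
#' @param censor_policy One of `"as_reported"` (default), `"zero"`,
#'   `"half_loq"`.
#' @param catalogue Analyte catalogue tibble used to attach
#'   `analyte_class`; defaults to [pollutant_catalogue()]. Analytes absent
#'   from the catalogue get class `NA` with a warning.
#' @return A tibble with one row per analyte: `analyte_cas`, `analyte_name`,
#'   `analyte_class`, `cross_site_mean` (ng/dm3), `n_supply_samples`, and a
#'   nested `sites` list-column of per-site tibbles
#'   (`site_id`, `mean_ng_dm3`, `n`, `supply`).
#' @export
summarize_concentrations <- function(records,
                                     supply_sites,
                                     censor_policy = c("as_reported", "zero",
                                                       "half_loq"),
                                     catalogue = pollutant_catalogue()) {
  censor_policy <- match.arg(censor_policy)
  if (length(supply_sites) == 0) {
    abort("`supply_sites` must name at least one site")
  }
  records <- validate_monitoring_records(records)
  records$.value <- apply_censor_policy(records, censor_policy)

  per_site <- records |>
    group_by(.data$analyte_cas, .data$analyte_name, .data$site_id) |>
    summarise(mean_ng_dm3 = mean(.data$.value), n = n(), .groups = "drop") |>
    mutate(supply = .data$site_id %in% supply_sites)

  out <- per_site |>
    group_by(.data$analyte_cas, .data$analyte_name) |>
    summarise(
      cross_site_mean = if (any(.data$supply)) {
        mean(.data$mean_ng_dm3[.data$supply])
      } else 0,
      n_supply_samples = sum(.data$n[.data$supply]),
      at_supply = any(.data$supply),
      .groups = "drop"
    )
  if (any(!out$at_supply)) {
    warn(sprintf(
      "analyte(s) observed at no supply site (exposure concentration set to 0): %s",
      paste(out$analyte_cas[!out$at_supply], collapse = ", ")))
  }
  out$at_supply <- NULL

  out <- out |>
    left_join(select(catalogue, "analyte_cas", "analyte_class"),
              by = "analyte_cas")
  if (anyNA(out$analyte_class)) {
    warn(sprintf("analyte(s) not in the catalogue (class unknown): %s",
                 paste(out$analyte_cas[is.na(out$analyte_class)],
                       collapse = ", ")))
  }

  nested <- per_site |>
    tidyr::nest(sites = c("site_id", "mean_ng_dm3", "n", "supply"))
  out |>
    left_join(select(nested, "analyte_cas", "sites"), by = "analyte_cas") |>
    # present analytes in catalogue order (PCB congeners first), extras last
    arrange(match(.data$analyte_cas, catalogue$analyte_cas)) |>
    select("analyte_cas", "analyte_name", "analyte_class",
           "cross_site_mean", "n_supply_samples", "sites")
}

#' Total concentration of a pollutant class
#'
#' Sums the cross-site exposure-point concentrations over all analytes of a
#' class. The PCB total is the concentration the mixture slope factor and
#' reference dose apply to; the COP total is compared against the total
#' pesticide drinking-water standard.
#'
#' @param summaries Output of [summarize_concentrations()].
#' @param analyte_class `"PCB"` or `"COP"`.
#' @return Total concentration in ng/dm3 (0 for a class with no analytes).
#' @export
class_total <- function(summaries, analyte_class) {
  valid <- c("PCB", "COP")
  if (!is.character(analyte_class) || length(analyte_class) != 1 ||
      !analyte_class %in% valid) {
    abort(sprintf("unknown analyte class; valid classes: %s",
                  paste(valid, collapse = ", ")))
  }
  rows <- summaries$analyte_class %in% analyte_class
  sum(summaries$cross_site_mean[rows])
}

#' Write a concentration summary as CSV
#'
#' Emits the per-analyte summary in a wide layout mirroring the monitoring
#' report tables: analyte name, CAS, one column of mean concentration per
#' site, and the cross-site exposure-point mean, all in ng/dm3.
#'
#' @param summaries Output of [summarize_concentrations()].
#' @param path Output CSV path.
#' @return The wide tibble that was written, invisibly.
#' @export
write_concentration_summary <- function(summaries, path) {
  wide <- summaries |>
    select("analyte_cas", "analyte_name", "cross_site_mean", "sites") |>
    tidyr::unnest("sites") |>
    select(-"n", -"supply") |>
    tidyr::pivot_wider(names_from = "site_id", values_from = "mean_ng_dm3",
                       names_prefix = "mean_") |>
    relocate("cross_site_mean", .after = dplyr::last_col())
  readr::write_csv(wide, path)
  invisible(wide)
}
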