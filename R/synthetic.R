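#' Mean pollutant concentrations of the packaged well-water study
#'
#' The per-site mean concentrations (ng/dm3) observed during the packaged
#' five-month monitoring campaign at three deep supply wells and one
#' surveillance river in a district near Wroclaw. These means are the
#' package's reference inputs: fed through the pipeline they reproduce the
#' study's dose, risk and hazard tables, and they parameterise the default
#' synthetic campaign.
#'
#' Cells reported as absent or below the limit of quantification at a site
#' are carried as 0.
#'
#' @return A long tibble with columns `analyte_cas`, `analyte_name`,
#'   `site_id` (`well_I`, `well_II`, `well_III`, `river`), `mean_ng_dm3`.
#' @export
#' @examples
#' study_well_means()
study_well_means <- function() {
  wells <- tibble::tribble(
    ~analyte_cas, ~well_I, ~well_II, ~well_III, ~river,
    "37680-65-2",    2.44,   285.87,    131.33,  44.31,
    "38444-84-7",    0.78,    15.29,      0,    672.74,
    "7012-37-5",   128.23,     6.27,    241.62,   0,
    "41464-39-5",  167.65,     8.56,    118.66, 485.27,
    "35693-99-3",    0,        0.14,    179.46,   0,
    "37680-73-2",    0,        3.44,      8.53,   2.18,
    "31508-00-6",    6.12,     1.17,      0,      0,
    "32598-14-4",    0.03,     7.85,      3.21,   1.46,
    "35065-27-1",    0,        1.67,      7.22,   6.74,
    "35065-28-2",    7.62,     4.13,      4.02,   8.54,
    "35065-30-6",    5.43,     8.07,      0.69,   2.13,
    "35065-29-3",    0,        0.11,      0,      0,
    "35694-08-7",    0,        0,         0.24,   7.34,
    "58-89-9",       3.26,    98.17,     65.74, 153.86,
    "72-55-9",       6.21,     4.84,      0,      0.02,
    "72-54-8",      10.48,     2.85,      4.65,   7.48,
    "50-29-3",      14.39,     6.65,      3.31,   6.63
  )
  wells |>
    left_join(select(pollutant_catalogue(), "analyte_cas", "analyte_name"),
              by = "analyte_cas") |>
    tidyr::pivot_longer(c("well_I", "well_II", "well_III", "river"),
                        names_to = "site_id", values_to = "mean_ng_dm3") |>
    select("analyte_cas", "analyte_name", "site_id", "mean_ng_dm3")
}

#' Default site roster of the packaged study
#'
#' @return A tibble with `site_id` and `supply` (the river is surveillance
#'   only and excluded from exposure-point concentrations).
#' @export
study_sites <- function() {
  tibble(
    site_id = c("well_I", "well_II", "well_III", "river"),
    supply = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Specification of a synthetic monitoring campaign
#'
#' Describes a repeated-sampling campaign: which sites are visited, the
#' target per-site mean of every analyte, the sampling cadence, the
#' relative dispersion of individual determinations, and the per-analyte
#' limits of quantification. Defaults emulate the packaged study: ten
#' fortnightly sampling dates over five months at three supply wells plus a
#' river, per-site target means pinned to [study_well_means()], LOQ
#' 1 ng/dm3 (5 ng/dm3 for DDE), and a coefficient of variation of 0.3 for
#' individual determinations.
#'
#' @param sites Tibble with `site_id` and `supply`, see [study_sites()].
#' @param means Long tibble of target means, see [study_well_means()].
#' @param cv Coefficient of variation of individual determinations around
#'   the target mean (0 makes every draw equal to the mean).
#' @param n_dates Number of sampling dates per site.
#' @param cadence_days Days between consecutive sampling dates.
#' @param start_date First sampling date.
#' @param loq Tibble with `analyte_cas` and `loq_ng_dm3`; defaults to the
#'   catalogue limits.
#' @param seed Integer seed making the campaign reproducible.
#' @return A list of class `"campaign_spec"`.
#' @export
campaign_spec <- function(sites = study_sites(),
                          means = study_well_means(),
                          cv = 0.3,
                          n_dates = 10,
                          cadence_days = 14,
                          start_date = as.Date("2010-04-05"),
                          loq = select(pollutant_catalogue(), "analyte_cas",
                                       "loq_ng_dm3"),
                          seed = 1L) {
  if (cv < 0) abort("`cv` must be nonnegative")
  if (n_dates < 1) abort("`n_dates` must be at least 1")
  if (any(means$mean_ng_dm3 < 0)) abort("target means must be nonnegative")
  if (any(loq$loq_ng_dm3 <= 0)) abort("limits of quantification must be positive")
  structure(
    list(sites = as_tibble(sites), means = as_tibble(means), cv = cv,
         n_dates = as.integer(n_dates), cadence_days = cadence_days,
         start_date = as.Date(start_date), loq = as_tibble(loq),
         seed = as.integer(seed)),
    class = "campaign_spec"
  )
}

# run code under a seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic monitoring campaign
#'
#' Draws one determination per (site, analyte, sampling date). Values come
#' from a log-normal distribution parameterised so that its mean equals the
#' target per-site mean and its coefficient of variation equals the spec's
#' `cv` — concentrations are nonnegative and right-skewed, which the
#' log-normal captures; with `cv = 0` every draw equals the target mean
#' exactly, and a zero target mean yields the constant 0. Draws below the
#' analyte's limit of quantification are flagged `below_loq` with the drawn
#' value retained, mirroring a laboratory that reports trace determinations
#' rather than blanking them.
#'
#' The campaign is deterministic under the spec's seed, and the caller's
#' RNG state is left untouched.
#'
#' @param spec A [campaign_spec()].
#' @return A validated tibble of monitoring records in the package's
#'   monitoring dialect, with the seed recorded in the `campaign_seed`
#'   attribute.
#' @export
#' @examples
#' records <- generate_campaign(campaign_spec(cv = 0, n_dates = 2))
#' dplyr::count(records, site_id)
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  dates <- spec$start_date + spec$cadence_days * (seq_len(spec$n_dates) - 1)
  grid <- spec$means |>
    dplyr::inner_join(spec$sites, by = "site_id") |>
    cross_join(tibble(sample_date = dates)) |>
    left_join(spec$loq, by = "analyte_cas")

  values <- with_preserved_seed(spec$seed, {
    m <- grid$mean_ng_dm3
    if (spec$cv == 0) {
      m
    } else {
      s2 <- log(1 + spec$cv^2)
      v <- numeric(length(m))
      pos <- m > 0
      v[pos] <- rlnorm(sum(pos), meanlog = log(m[pos]) - s2 / 2,
                       sdlog = sqrt(s2))
      v
    }
  })

  records <- grid |>
    mutate(value_ng_dm3 = values,
           below_loq = values < .data$loq_ng_dm3) |>
    select("site_id", "sample_date", "analyte_cas", "analyte_name",
           "value_ng_dm3", "below_loq", "loq_ng_dm3") |>
    arrange(.data$site_id, .data$sample_date, .data$analyte_cas)
  records <- validate_monitoring_records(records)
  attr(records, "campaign_seed") <- spec$seed
  records
}

#' Packaged default exposure scenario
#'
#' The complete scenario of the packaged study in one call: the three
#' population groups with their sizes and exposure parameters, the exposure
#' context (FI 0.65, EF 365 days/year, EPA lifetime averaging), and the
#' default toxicity registry.
#'
#' @return A list with elements `groups`, `context`, `registry`.
#' @export
#' @examples
#' sc <- default_scenario()
#' sum(sc$groups$size)
default_scenario <- function() {
  list(
    groups = population_groups(),
    context = exposure_context(),
    registry = default_toxicity_registry()
  )
}
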