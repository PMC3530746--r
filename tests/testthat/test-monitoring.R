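make_records <- function(values, site = "well_I", cas = "37680-65-2",
                         name = "PCB18", below_loq = FALSE, loq = 1) {
  tibble::tibble(
    site_id = site, sample_date = as.Date("2010-04-05") + seq_along(values),
    analyte_cas = cas, analyte_name = name, value_ng_dm3 = values,
    below_loq = below_loq, loq_ng_dm3 = loq
  )
}

test_that("monitoring CSV round-trips through the documented dialect", {
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_records(c(2.44, 0.5), below_loq = c(FALSE, TRUE)), csv)
  rec <- read_monitoring_csv(csv)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$value_ng_dm3[1], 2.44)
  expect_s3_class(rec$sample_date, "Date")
  expect_identical(rec$below_loq, c(FALSE, TRUE))
})

test_that("empty data sections warn and yield an empty record set", {
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_records(numeric(0)), csv)
  expect_warning(rec <- read_monitoring_csv(csv), "empty data section")
  expect_equal(nrow(rec), 0)
})

test_that("validation rejects malformed records with informative errors", {
  rec <- make_records(c(1, 2))
  expect_error(validate_monitoring_records(rec[, -5]),
               "missing column.*value_ng_dm3")
  bad <- rec; bad$value_ng_dm3[2] <- -1
  expect_error(validate_monitoring_records(bad), "row\\(s\\): 2")
  bad <- rec; bad$loq_ng_dm3[1] <- 0
  expect_error(validate_monitoring_records(bad), "quantification")
  # censored value must lie strictly below its LOQ
  bad <- make_records(c(0.5, 1.5), below_loq = TRUE)
  expect_error(validate_monitoring_records(bad), "below-LOQ")
  ok <- make_records(0.5, below_loq = TRUE)
  expect_silent(validate_monitoring_records(ok))
})

test_that("per-site and cross-site means reproduce the study tables", {
  sup <- c("well_I", "well_II", "well_III")
  smry <- summarize_concentrations(study_records(), sup)
  # every printed cross-site average, to the printed 2 decimals
  expect_equal(round(smry$cross_site_mean[match(names(expected_cross_site),
                                                smry$analyte_cas)], 2),
               unname(expected_cross_site))
  # per-site means equal the input well means (single determination each)
  pcb18 <- tidyr::unnest(smry[smry$analyte_cas == "37680-65-2", ], "sites")
  wells <- study_well_means()
  expect_equal(
    pcb18$mean_ng_dm3[match(c("well_I", "well_II", "well_III"),
                            pcb18$site_id)],
    wells$mean_ng_dm3[wells$analyte_cas == "37680-65-2" &
                        wells$site_id != "river"])
  # the river is excluded from the exposure-point mean
  expect_false(any(tidyr::unnest(smry, "sites")$supply[
    tidyr::unnest(smry, "sites")$site_id == "river"]))
})

test_that("class totals are additive and match the printed study totals", {
  sup <- c("well_I", "well_II", "well_III")
  smry <- summarize_concentrations(study_records(), sup)
  pcb <- class_total(smry, "PCB")
  cop <- class_total(smry, "COP")
  # unrounded totals agree with the printed 451.96 / 73.53 within rounding
  expect_equal(pcb, 451.96, tolerance = 5e-5)
  expect_equal(cop, 73.53, tolerance = 2e-4)
  # additivity to machine precision
  expect_identical(pcb, sum(smry$cross_site_mean[smry$analyte_class == "PCB"]))
  expect_identical(cop + pcb, class_total(smry, "PCB") +
                     class_total(smry, "COP"))
  expect_error(class_total(smry, "metals"), "valid classes")
  expect_equal(class_total(smry[smry$analyte_class == "PCB", ], "COP"), 0)
})

test_that("summarize is invariant to record order", {
  rec <- study_records(n_dates = 3)
  sup <- c("well_I", "well_II", "well_III")
  shuffled <- rec[sample(nrow(rec)), ]
  a <- summarize_concentrations(rec, sup)
  b <- summarize_concentrations(shuffled, sup)
  expect_equal(a$cross_site_mean, b$cross_site_mean)
  expect_equal(a$analyte_cas, b$analyte_cas)
})

test_that("censor policies substitute exactly and order as expected", {
  set.seed(42)
  loq <- 2
  for (n_cens in c(0, 5, 12)) {
    n <- 20
    vals <- c(runif(n_cens, 0, loq * 0.99), runif(n - n_cens, loq, 10))
    rec <- make_records(vals, below_loq = c(rep(TRUE, n_cens),
                                            rep(FALSE, n - n_cens)),
                        loq = loq)
    m <- purrr::map_dbl(
      c("as_reported", "zero", "half_loq"),
      function(p) summarize_concentrations(rec, "well_I", p)$cross_site_mean)
    names(m) <- c("as_reported", "zero", "half_loq")
    # zero and half-LOQ means differ by exactly (n_cens/n) * loq/2
    expect_equal(m[["half_loq"]] - m[["zero"]], n_cens / n * loq / 2)
    # ordering: zero <= half_loq; as_reported depends on the censored values
    expect_lte(m[["zero"]], m[["half_loq"]])
    # brute-force recomputation of each policy
    uncensored <- if (n_cens > 0) vals[-seq_len(n_cens)] else vals
    expect_equal(m[["zero"]], mean(c(rep(0, n_cens), uncensored)))
    expect_equal(m[["as_reported"]], mean(vals))
  }
})

test_that("analytes seen only at non-supply sites get a zero exposure mean", {
  rec <- make_records(5, site = "river")
  expect_warning(smry <- summarize_concentrations(rec, "well_I"),
                 "no supply site")
  expect_equal(smry$cross_site_mean, 0)
})

test_that("summary CSV writer mirrors the per-site table layout", {
  csv <- withr::local_tempfile(fileext = ".csv")
  sup <- c("well_I", "well_II", "well_III")
  smry <- summarize_concentrations(study_records(), sup)
  wide <- write_concentration_summary(smry, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(names(back),
               c("analyte_cas", "analyte_name", "mean_river", "mean_well_I",
                 "mean_well_II", "mean_well_III", "cross_site_mean"))
  expect_equal(nrow(back), 17)
  expect_equal(back$cross_site_mean, wide$cross_site_mean)
})
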