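test_that("one-hit and linear dose-response behave as the models prescribe", {
  expect_equal(cancer_risk(2.518e-6, 2.0, "one_hit"), 5.035e-6,
               tolerance = 1e-3)
  expect_equal(cancer_risk(0, 2.0, "one_hit"), 0)
  expect_equal(cancer_risk(0, 2.0, "linear"), 0)
  # dose * sf = ln 2 gives exactly one-half under the one-hit model
  expect_equal(cancer_risk(log(2), 1, "one_hit"), 0.5)
  # auto switches from linear to one-hit at risk 0.01
  expect_identical(cancer_risk(0.004, 1, "auto"), 0.004)
  expect_identical(cancer_risk(0.5, 1, "auto"), 1 - exp(-0.5))
  expect_error(cancer_risk(-1, 2), "nonnegative")
  expect_error(cancer_risk(1, 0), "positive")
})

test_that("one-hit risk is bounded above by linear with a gap at most x^2/2", {
  x <- c(1e-8, 1e-4, 0.005, 0.01, 0.1, 0.5, 1)
  one_hit <- cancer_risk(x, 1, "one_hit")
  linear <- cancer_risk(x, 1, "linear")
  expect_true(all(one_hit <= linear))
  gap <- linear - one_hit
  expect_true(all(gap <= x^2 / 2))
  # series lower bound on the gap for small x
  small <- x[x < 0.1]
  expect_true(all((linear - one_hit)[x < 0.1] >=
                    small^2 / 2 - small^3 / 6 - 1e-15))
})

test_that("cumulative risk adds per-substance risks", {
  adult_risks <- expected_elcr[, "adults"]
  expect_equal(cumulative_risk(adult_risks), 5.855e-6, tolerance = 5e-4)
  expect_equal(cumulative_risk(0.3), 0.3)
  set.seed(3)
  r <- runif(6, 0, 0.1)
  expect_equal(cumulative_risk(r), cumulative_risk(sample(r)))
  expect_warning(cumulative_risk(c(0.6, 0.7)), "exceeds 1")
  expect_error(cumulative_risk(c(0.5, 1)), "\\[0, 1\\)")
})

test_that("extra cancer cases scale individual risk by population size", {
  expect_equal(extra_cancer_cases(5.855e-6, 8140), 4.766e-2, tolerance = 5e-4)
  expect_equal(extra_cancer_cases(0.1, 0), 0)
  expect_error(extra_cancer_cases(1.2, 10), "\\[0, 1\\)")
})

test_that("hazard quotient and hazard index reproduce the study cells", {
  expect_equal(hazard_quotient(5.875e-6, 2e-5), 0.29375, tolerance = 1e-3)
  expect_equal(hazard_quotient(1.055e-7, 5e-4), 2.110e-4, tolerance = 1e-3)
  expect_equal(hazard_quotient(0, 1), 0)
  expect_equal(hazard_index(expected_hq[, "children_7_17"]), 0.3222,
               tolerance = 1e-3)
  expect_equal(hazard_index(numeric(0)), 0)
  set.seed(5)
  h <- runif(10)
  expect_equal(hazard_index(h), sum(h))
  expect_error(hazard_quotient(1, NA_real_), "positive")
})

test_that("risk classification uses half-open bands with inclusive lower bounds", {
  expect_equal(as.character(classify_risk(c(0, 5e-7))),
               c("negligible", "negligible"))
  expect_equal(as.character(classify_risk(1e-6)), "acceptable_range")
  expect_equal(as.character(classify_risk(5.855e-6)), "acceptable_range")
  expect_equal(as.character(classify_risk(1e-4)), "remediation_desirable")
  expect_equal(as.character(classify_risk(c(1e-3, 0.5))),
               rep("protective_measures_required", 2))
  # ordered and exhaustive over [0, 1)
  lv <- classify_risk(c(0, 1e-6, 1e-4, 1e-3))
  expect_true(is.ordered(lv))
  expect_false(anyNA(classify_risk(seq(0, 0.999, length.out = 100))))
})

test_that("elcr, ecc, hq are nondecreasing in dose", {
  doses <- sort(c(0, 10^seq(-8, -1, length.out = 20)))
  expect_true(!is.unsorted(cancer_risk(doses, 2.0, "one_hit")))
  expect_true(!is.unsorted(cancer_risk(doses, 2.0, "auto")))
  expect_true(!is.unsorted(extra_cancer_cases(cancer_risk(doses, 2), 1000)))
  expect_true(!is.unsorted(hazard_quotient(doses, 2e-5)))
})

test_that("the as_published configuration makes every ELCR about twice its LADD", {
  smry <- summarize_concentrations(study_records(),
                                   c("well_I", "well_II", "well_III"))
  dt <- dose_table(smry)
  rt <- risk_table(dt, sf_config = "as_published", model = "one_hit")
  cells <- dplyr::inner_join(
    dplyr::filter(rt, analyte_cas != "TOTAL"), dt,
    by = c("analyte_cas", "group_label"))
  expect_equal(cells$elcr / cells$ladd_mg_kg_day, rep(2, nrow(cells)),
               tolerance = 1e-4)
})

test_that("table5 slope factors give lower pesticide risks than the published uniform 2.0", {
  smry <- summarize_concentrations(study_records(),
                                   c("well_I", "well_II", "well_III"))
  dt <- dose_table(smry)
  pub <- risk_table(dt, sf_config = "as_published")
  t5 <- risk_table(dt, sf_config = "table5")
  key <- c("analyte_cas", "group_label")
  joined <- dplyr::inner_join(pub, t5, by = key,
                              suffix = c("_pub", "_t5"))
  pest <- joined[!joined$analyte_cas %in% c("SUM-PCB", "TOTAL"), ]
  expect_true(all(pest$elcr_t5 < pest$elcr_pub))
  pcb <- joined[joined$analyte_cas == "SUM-PCB", ]
  expect_equal(pcb$elcr_t5, pcb$elcr_pub)
})

test_that("population burden conserves additivity to machine precision", {
  smry <- summarize_concentrations(study_records(),
                                   c("well_I", "well_II", "well_III"))
  rt <- risk_table(dose_table(smry), sf_config = "as_published")
  pb <- population_burden(rt)
  cells <- pb[!pb$analyte_cas %in% "TOTAL", ]
  gen <- pb$ecc[pb$group_label == "general_population"]
  expect_equal(gen, sum(cells$ecc))
  for (g in unique(cells$group_label)) {
    expect_equal(pb$ecc[pb$analyte_cas == "TOTAL" & pb$group_label == g],
                 sum(cells$ecc[cells$group_label == g]))
  }
})

test_that("analytes without a reference dose are excluded from HI with a warning", {
  smry <- summarize_concentrations(study_records(),
                                   c("well_I", "well_II", "well_III"))
  dt <- dose_table(smry)
  reg <- default_toxicity_registry()
  reg$rfd[reg$analyte_cas == "58-89-9"] <- NA_real_
  expect_warning(ht <- hazard_table(dt, reg), "58-89-9")
  expect_false("58-89-9" %in% ht$analyte_cas)
  # HI is the sum over the remaining analytes
  full <- suppressWarnings(hazard_table(dt))
  g <- "adults"
  expect_lt(ht$hq[ht$analyte_cas == "TOTAL" & ht$group_label == g],
            full$hq[full$analyte_cas == "TOTAL" & full$group_label == g])
})
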