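# Frozen reference values of the packaged well-water study, used across the
# suite. Group order everywhere: children 0-6, children 7-17, adults.

group_order <- c("children_0_6", "children_7_17", "adults")

# analyte order of the dose/risk/hazard matrices: PCB mixture then pesticides
analyte_order <- c("SUM-PCB", "58-89-9", "72-55-9", "72-54-8", "50-29-3")

# printed cross-site mean concentrations (ng/dm3), to 2 decimals
expected_cross_site <- c(
  "37680-65-2" = 139.88, "38444-84-7" = 5.36, "7012-37-5" = 125.37,
  "41464-39-5" = 98.29, "35693-99-3" = 59.87, "37680-73-2" = 3.99,
  "31508-00-6" = 2.43, "32598-14-4" = 3.70, "35065-27-1" = 2.96,
  "35065-28-2" = 5.26, "35065-30-6" = 4.73, "35065-29-3" = 0.04,
  "35694-08-7" = 0.08,
  "58-89-9" = 55.72, "72-55-9" = 3.68, "72-54-8" = 5.99, "50-29-3" = 8.12
)

# lifetime average daily doses, mg/(kg*day): analytes x groups
expected_ladd <- matrix(
  c(5.036e-07, 1.004e-06, 2.518e-06,
    6.209e-08, 1.237e-07, 3.105e-07,
    4.104e-09, 8.179e-09, 2.052e-08,
    6.678e-09, 1.331e-08, 3.339e-08,
    9.044e-09, 1.802e-08, 4.522e-08),
  nrow = 5, byrow = TRUE, dimnames = list(analyte_order, group_order)
)

# duration-matched average daily doses, mg/(kg*day)
expected_add <- matrix(
  c(5.875e-06, 6.386e-06, 5.875e-06,
    7.244e-07, 7.874e-07, 7.244e-07,
    4.788e-08, 5.205e-08, 4.788e-08,
    7.791e-08, 8.469e-08, 7.791e-08,
    1.055e-07, 1.147e-07, 1.055e-07),
  nrow = 5, byrow = TRUE, dimnames = list(analyte_order, group_order)
)

# excess lifetime cancer risks under the published configuration
# (uniform slope factor 2.0, one-hit model)
expected_elcr <- matrix(
  c(1.007e-06, 2.007e-06, 5.035e-06,
    1.242e-07, 2.474e-07, 6.209e-07,
    8.208e-09, 1.636e-08, 4.104e-08,
    1.336e-08, 2.661e-08, 6.678e-08,
    1.809e-08, 3.604e-08, 9.043e-08),
  nrow = 5, byrow = TRUE, dimnames = list(analyte_order, group_order)
)
expected_elcr_tot <- c(children_0_6 = 1.171e-06, children_7_17 = 2.333e-06,
                       adults = 5.855e-06)

# expected extra cancer cases per (analyte, group) and totals
expected_ecc <- matrix(
  c(9.406e-04, 4.106e-03, 4.099e-02,
    1.160e-04, 5.063e-04, 5.054e-03,
    7.666e-06, 3.346e-05, 3.341e-04,
    1.247e-05, 5.445e-05, 5.436e-04,
    1.689e-05, 7.374e-05, 7.361e-04),
  nrow = 5, byrow = TRUE, dimnames = list(analyte_order, group_order)
)
expected_ecc_tot <- c(children_0_6 = 1.094e-03, children_7_17 = 4.774e-03,
                      adults = 4.766e-02)
expected_ecc_gen <- 5.34e-02
expected_ecc_gen_duration_matched <- 0.091

# hazard quotients and indices (chronic reference doses)
expected_hq <- matrix(
  c(2.938e-01, 3.193e-01, 2.938e-01,
    2.415e-03, 2.625e-03, 2.415e-03,
    1.596e-05, 1.735e-05, 1.596e-05,
    8.657e-06, 9.410e-06, 8.657e-06,
    2.110e-04, 2.294e-04, 2.110e-04),
  nrow = 5, byrow = TRUE, dimnames = list(analyte_order, group_order)
)
expected_hi <- c(children_0_6 = 2.964e-01, children_7_17 = 3.222e-01,
                 adults = 2.964e-01)

# deterministic campaign whose summaries equal the study's per-well means
study_records <- function(n_dates = 1) {
  generate_campaign(campaign_spec(cv = 0, n_dates = n_dates))
}

# pull a dose/risk/hazard table column into the matrix layout above
as_cell_matrix <- function(tbl, value_col) {
  cells <- tbl[tbl$analyte_cas != "TOTAL", ]
  out <- matrix(NA_real_, nrow = length(analyte_order),
                ncol = length(group_order),
                dimnames = list(analyte_order, group_order))
  for (i in seq_len(nrow(cells))) {
    out[cells$analyte_cas[i], cells$group_label[i]] <- cells[[value_col]][i]
  }
  out
}

expect_rel_within <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected) + 1e-300),
              label = sprintf("max relative deviation %.3g within %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-300)), tol))
}
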