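tdm_fixture <- local({
  out <- NULL
  function() {
    if (is.null(out)) {
      reg <- calibrated_default_system()$registry
      pop <- mini_pop(3, seed = 31, registry = reg)
      spec <- synthetic_cohort_spec(
        "young", n_150 = 8, n_300 = 6, gsd = 1.8,
        contamination = list(strong_cyp2d6_or_ppi_comedication = 0.1,
                             missing_concentration = 0.1,
                             immediate_release = 0.07,
                             recent_dose_change = 0.07,
                             documentation_bias = 0.07),
        seed = 13)
      out <<- list(reg = reg, pop = pop, spec = spec,
                   data = generate_tdm_dataset(spec, reg, pop))
    }
    out
  }
})

test_that("clean cohorts pass every exclusion filter", {
  fx <- tdm_fixture()
  spec0 <- synthetic_cohort_spec("young", n_150 = 5, n_300 = 3, gsd = 1.5,
                                 seed = 2)
  d <- generate_tdm_dataset(spec0, fx$reg, fx$pop)
  expect_equal(nrow(d$records), 8L)
  flt <- apply_exclusion_filters(d$records)
  expect_equal(nrow(flt$kept), 8L)
  expect_equal(nrow(flt$reasons), 0L)
  expect_true(all(d$ground_truth$planted_rule == "none"))
})

test_that("noise-free records equal the simulated troughs exactly", {
  fx <- tdm_fixture()
  spec1 <- synthetic_cohort_spec("young", n_150 = 4, n_300 = 0, gsd = 1,
                                 seed = 9)
  d <- generate_tdm_dataset(spec1, fx$reg, fx$pop)
  # records are dose-scaled; normalizing back recovers the exact simulated
  # trough of the individual at its sampling day
  expect_equal(normalize_dose(d$records$c_tr_ven, d$records$ven_dose),
               d$ground_truth$true_trough_ven, tolerance = 1e-12)
  expect_equal(normalize_dose(d$records$c_tr_odv, d$records$ven_dose),
               d$ground_truth$true_trough_odv, tolerance = 1e-12)
})

test_that("planted violations are recovered exactly and filters are idempotent", {
  fx <- tdm_fixture()
  d <- fx$data
  flt <- apply_exclusion_filters(d$records)
  planted <- d$ground_truth[d$ground_truth$planted_rule != "none", ]
  # every contaminated record is rejected for exactly its planted rule
  expect_setequal(flt$reasons$patient_id, planted$patient_id)
  m <- merge(flt$reasons, planted, by = "patient_id")
  expect_equal(m$rule, m$planted_rule)
  # no clean record is rejected
  clean <- d$ground_truth$patient_id[d$ground_truth$planted_rule == "none"]
  expect_true(all(clean %in% flt$kept$patient_id))
  # idempotence
  flt2 <- apply_exclusion_filters(flt$kept)
  expect_identical(flt2$kept, flt$kept)
  expect_equal(nrow(flt2$reasons), 0L)
})

test_that("cohort sizes follow the study collective by default", {
  sy <- synthetic_cohort_spec("young")
  se <- synthetic_cohort_spec("elderly")
  expect_equal(sy$n_150 + sy$n_300, 57L)  # 35 + 22
  expect_equal(se$n_150 + se$n_300, 13L)  # 8 + 5
})

test_that("evaluation block reproduces the median prediction error form", {
  # constructed cell: observed parent median 169, simulated median 144
  records <- data.frame(
    patient_id = 1:3, age = 40, sex = "f", weight = 70, height = 170,
    ven_dose = 225, bup_dose = 150, days_since_bup_change = 12,
    c_tr_ven = c(160, 169, 180), c_tr_odv = c(120, 149, 170),
    comedications = "", formulation = "extended",
    days_since_ven_change = 10, documentation_ok = TRUE)
  sim <- data.frame(ven = rep(144, 25), odv = rep(126, 25))
  sim$am <- sim$ven + sim$odv; sim$mr <- sim$odv / sim$ven
  ev <- evaluate_tdm(records, sim)
  expect_equal(round(ev$pe_median_pct[ev$quantity == "VEN"], 1), -14.8)
  # identical medians give zero prediction error
  sim2 <- data.frame(ven = rep(169, 25), odv = rep(149, 25))
  sim2$am <- sim2$ven + sim2$odv; sim2$mr <- sim2$odv / sim2$ven
  ev2 <- evaluate_tdm(records, sim2)
  expect_equal(ev2$pe_median_pct[ev2$quantity == "VEN"], 0)
  expect_error(evaluate_tdm(records[0, ], sim), "empty")
})

test_that("a model-generated cohort is self-consistent at low noise", {
  fx <- tdm_fixture()
  spec <- synthetic_cohort_spec("young", n_150 = 0, n_300 = 500,
                                gsd = 1.05, seed = 17)
  d <- generate_tdm_dataset(spec, fx$reg, fx$pop)
  flt <- apply_exclusion_filters(d$records)
  sim <- population_troughs(fx$reg, rep(fx$pop, 7)[1:21], 300)
  ev <- evaluate_tdm(flt$kept, sim)
  for (q in c("VEN", "ODV", "AM"))
    expect_lt(abs(ev$pe_median_pct[ev$quantity == q]), 5)
  expect_gte(ev$pct_in_5_95[ev$quantity == "VEN"], 50)
})
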