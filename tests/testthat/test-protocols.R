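test_that("protocol construction encodes the study designs", {
  p300 <- build_protocol("ddi_300", fix_registry())
  bup <- Filter(function(d) d$compound == "BUP", p300$doses)[[1]]
  expect_equal(bup$end_day - bup$start_day + 1, 14)  # 14 days combination
  expect_equal(bup$amount, 300)
  expect_equal(p300$baseline_day, 4)
  expect_equal(p300$effect_day, 18)

  m <- build_protocol("mddi", fix_registry())
  itra <- Filter(function(d) d$compound == "CYP3A4I", m$doses)[[1]]
  expect_equal(itra$schedule, "bid")
  expect_equal(m$compare_days, c(4, 17, 27))
  reg7 <- add_cyp3a4_inhibitor(fix_registry())
  regs <- protocol_regimens(m, reg7)
  tt <- vapply(flatten_regimens(regs[[3]]), function(e) e$time, numeric(1))
  expect_equal(unique(diff(sort(tt)))[1], 12)  # 12 h dosing interval

  alone <- build_protocol("ven_alone", fix_registry())
  expect_length(alone$doses, 1L)
  expect_length(alone$compare_days, 0L)
  expect_error(build_protocol("nope"))
})

test_that("trough sampling day caps at ten days of concomitant use", {
  expect_equal(trough_sampling_day(14), 10)
  expect_equal(trough_sampling_day(7), 7)
  expect_equal(trough_sampling_day(10), 10)
  expect_equal(trough_sampling_day(c(3, 25)), c(3, 10))
  expect_error(trough_sampling_day(0), ">= 1")
})

test_that("dose normalization is linear in the administered dose", {
  expect_equal(normalize_dose(100, 150), 150)
  expect_equal(normalize_dose(77, 225), 77)
  expect_equal(normalize_dose(80, 300), 60)
  expect_error(normalize_dose(10, 0), "dose")
})

test_that("interaction reports are internally consistent and dose-monotone", {
  reg <- calibrated_default_system()$registry
  pop <- mini_pop(3, seed = 21, registry = reg)
  r150 <- run_ddi_study(build_protocol("ddi_150", reg), pop, reg,
                        seed = 21, dt_out_h = 0.5)
  r300 <- run_ddi_study(build_protocol("ddi_300", reg), pop, reg,
                        seed = 21, dt_out_h = 0.5)

  # stored changes recompute exactly from the stored exposures
  for (r in list(r150, r300)) {
    tab <- r$table
    base <- tab[tab$day == 4, ]
    eff <- tab[tab$day == 18, ]
    for (an in c("VEN", "ODV", "AM")) {
      expect_identical(
        eff$auc_change_pct[eff$analyte == an],
        relative_change(eff$auc[eff$analyte == an],
                        base$auc[base$analyte == an]))
    }
    expect_identical(r$changes$mr_auc_change_pct,
                     relative_change(r$changes$mr_auc_effect,
                                     r$changes$mr_auc_baseline))
  }

  # a higher perpetrator dose produces a larger parent exposure change
  ch <- function(r, an) r$table$auc_change_pct[r$table$day == 18 &
                                               r$table$analyte == an]
  expect_gt(ch(r300, "VEN"), ch(r150, "VEN"))
  expect_lt(ch(r300, "ODV"), ch(r150, "ODV"))

  # pre-perpetrator phase equals the no-perpetrator run
  alone <- run_ddi_study(build_protocol("ven_alone", reg), pop, reg,
                         seed = 21, dt_out_h = 0.5)
  i4 <- which(r300$median_profiles$time_h <= 96)
  expect_equal(r300$median_profiles$VEN[i4], alone$median_profiles$VEN[i4],
               tolerance = 1e-6)
  expect_true(all(is.na(alone$table$auc_change_pct)))
  expect_null(alone$changes)
})

test_that("median active-moiety troughs stay in the therapeutic range", {
  reg <- calibrated_default_system()$registry
  for (stratum in c("young", "elderly")) {
    pop <- sample_population(
      stratum_population_spec(stratum, n = 3, seed = 5), reg)
    for (prot in c("ddi_150", "ddi_300")) {
      r <- run_ddi_study(build_protocol(prot, reg), pop, reg, seed = 5,
                         dt_out_h = 0.5)
      expect_gte(r$changes$am_trough_baseline, 100)
      expect_lte(r$changes$am_trough_baseline, 400)
      expect_gte(r$changes$am_trough_effect, 100)
      expect_lte(r$changes$am_trough_effect, 400)
      expect_equal(r$changes$verdict_effect, "therapeutic")
    }
  }
})
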