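test_that("competitive inhibition scales the apparent Michaelis constant", {
  # half-saturation without inhibitors
  expect_equal(mm_inhibited_rate(cu = 23.2, kcat = 29.16, e_amount = 2,
                                 km = 23.2), 29.16 * 2 / 2)
  # one inhibitor at its ki halves the linear-range rate
  v0 <- mm_inhibited_rate(0.001, 10, 1, 100)
  v1 <- mm_inhibited_rate(0.001, 10, 1, 100,
                          list(c(iu = 0.3, ki = 0.3)))
  expect_equal(v1 / v0, 0.5, tolerance = 1e-4)
  # plug-in oracle with the venlafaxine O-demethylation constants and an
  # inhibitor load summing to 9
  inh <- list(c(iu = 0.46, ki = 0.46), c(iu = 3.28, ki = 0.41))
  s <- 0.46 / 0.46 + 3.28 / 0.41
  expect_equal(s, 9)
  cu <- 0.5; e <- 0.8
  expect_equal(mm_inhibited_rate(cu, 29.16, e, 23.2, inh),
               29.16 * e * cu / (23.2 * (1 + 9) + cu), tolerance = 1e-12)
  expect_error(mm_inhibited_rate(1, 1, 1, km = 0))
})

test_that("zero dosing leaves the all-zero state a fixed point", {
  reg <- load_registry(bare_config(clint = 0.1, renal = 0.05))
  sys <- assemble(reg, fix_individual())
  res <- simulate_system(sys, list(), t_end_h = 24)
  expect_true(all(res$conc == 0))
  expect_true(all(res$organ_conc_um == 0))
})

test_that("an iv bolus without elimination conserves the amount in body", {
  reg <- load_registry(bare_config())  # no processes, no renal clearance
  sys <- assemble(reg, fix_individual())
  res <- simulate_system(sys, list(dose_event("X", 10, 0, "iv_bolus")),
                         t_end_h = 48)
  dosed <- 10 * 1000 / 250
  body <- apply(res$organ_conc_um[, , "X"], 1, function(cc) {
    v <- sys$V
    sum(cc[1:4] * v[1:4]) + sum(cc[5:12] * v[5:12] * sys$Kp[, "X"])
  })
  expect_true(all(abs(body - dosed) < 1e-6 * dosed))
})

test_that("linear hepatic elimination matches the well-stirred closed form", {
  clint <- 0.08  # 1/min
  reg <- load_registry(bare_config(clint = clint))
  ind <- fix_individual()
  sys <- assemble(reg, ind, partitions = unit_partitions(reg))
  res <- simulate_system(sys, regimen(list(dose_event("X", 10, 0,
                                                      reg$formulations$X))),
                         t_end_h = 400, dt_out_h = 0.1)
  auc_sim <- nca(res$time_h, res$conc_um[, "X"], c(0, 400))$auc  # uM*h
  # independent closed form for an oral dose of a drug eliminated only in
  # the liver: every absorbed molecule is cleared hepatically, so the
  # plasma AUC equals Dose / (fu * CLint) with CLint = clint * Vliver
  fu <- 0.5
  cl_int <- clint * ind$organ_volumes[["liver"]]
  auc_oracle <- (10 * 1000 / 250) / (fu * cl_int * 60)  # uM*h
  expect_equal(auc_sim, auc_oracle, tolerance = 1e-3)
})

test_that("oral dosing conserves mass through dissolution and absorption", {
  reg <- fix_registry()
  sys <- assemble(reg, fix_individual())
  res <- simulate_system(sys, regimen_qd("VEN", 225, 1, 1,
                                         reg$formulations$VEN),
                         t_end_h = 72)
  expect_lt(abs(res$mass_balance_rel_error), 1e-3)
})

test_that("steady state is reached within days and troughs stabilize", {
  reg <- fix_registry()
  sys <- assemble(reg, fix_individual())
  res <- simulate_system(sys, regimen_qd("VEN", 225, 1, 18,
                                         reg$formulations$VEN),
                         t_end_h = 432, dt_out_h = 0.5)
  trough <- function(day, cmp) {
    i <- max(which(res$time_h <= 24 * day + 1e-9))
    res$conc[i, cmp]
  }
  expect_lt(abs(trough(18, "VEN") / trough(17, "VEN") - 1), 0.02)
  expect_lt(abs(trough(18, "ODV") / trough(17, "ODV") - 1), 0.02)
  # near-steady state already by day 4 of once-daily intake
  expect_lt(abs(trough(4, "VEN") / trough(18, "VEN") - 1), 0.10)
})

test_that("poor metabolizers are insensitive to the CYP2D6 inhibitor", {
  reg <- load_registry(cyp2d6_phenotype = "pm")
  sys <- assemble(reg, fix_individual())
  with_bup <- simulate_system(
    sys, protocol_regimens(build_protocol("ddi_300", reg), reg),
    t_end_h = 432, dt_out_h = 0.5)
  without <- simulate_system(
    sys, regimen_qd("VEN", 225, 1, 18, reg$formulations$VEN),
    t_end_h = 432, dt_out_h = 0.5)
  a1 <- nca(with_bup$time_h, with_bup$conc[, "VEN"], c(408, 432))$auc
  a0 <- nca(without$time_h, without$conc[, "VEN"], c(408, 432))$auc
  expect_lt(abs(a1 / a0 - 1), 0.005)
})

test_that("doubling every inhibition constant weakens the interaction", {
  reg <- calibrated_default_system()$registry
  ind <- fix_individual()
  prot <- build_protocol("ddi_300", reg)
  run <- function(r) simulate_system(assemble(r, ind),
                                     protocol_regimens(prot, r),
                                     t_end_h = 432, dt_out_h = 0.5)
  reg2 <- reg
  for (k in seq_along(reg2$inhibitions))
    reg2$inhibitions[[k]]$ki <- reg2$inhibitions[[k]]$ki * 2
  r1 <- run(reg); r2 <- run(reg2)
  eff <- c(408, 432)
  expect_lt(nca(r2$time_h, r2$conc[, "VEN"], eff)$auc,
            nca(r1$time_h, r1$conc[, "VEN"], eff)$auc)
  expect_gt(nca(r2$time_h, r2$conc[, "ODV"], eff)$auc,
            nca(r1$time_h, r1$conc[, "ODV"], eff)$auc)
})

test_that("exposure is dose-proportional in the linear range", {
  reg <- fix_registry()
  sys <- assemble(reg, fix_individual())
  f <- reg$formulations$VEN
  r1 <- simulate_system(sys, regimen_qd("VEN", 1, 1, 4, f), t_end_h = 96,
                        dt_out_h = 0.5)
  r2 <- simulate_system(sys, regimen_qd("VEN", 0.5, 1, 4, f), t_end_h = 96,
                        dt_out_h = 0.5)
  a1 <- nca(r1$time_h, r1$conc[, "VEN"], c(72, 96))$auc
  a2 <- nca(r2$time_h, r2$conc[, "VEN"], c(72, 96))$auc
  expect_equal(a1 / a2, 2, tolerance = 0.02)
})
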