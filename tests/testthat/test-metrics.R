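test_that("active moiety is the flow-weighted mass combination", {
  organs <- c("art", "bon", "fat", "mus", "skn")
  fq <- setNames(c(5.6, 0.28, 0.28, 0.95, 0.28), organs)
  cc <- setNames(rep(1, 5), organs)
  z <- setNames(rep(0, 5), organs)
  # metabolite zero: weighted mean of a constant times the parent mass
  expect_equal(active_moiety(2 * cc, z, fq), 2 * 277.4)
  # 1 uM of both compounds everywhere
  expect_equal(active_moiety(cc, cc, fq), 540.78, tolerance = 1e-10)
  # linearity and invariance to uniform flow rescaling
  expect_equal(active_moiety(3 * cc, 2 * cc, fq),
               3 * 277.4 + 2 * 263.38, tolerance = 1e-10)
  expect_equal(active_moiety(cc, cc, 10 * fq), active_moiety(cc, cc, fq))
  expect_error(active_moiety(cc[-1], cc, fq), "organ set")
})

test_that("active moiety matches a brute-force weighted mean", {
  set.seed(99)
  organs <- paste0("o", 1:5)
  for (rep in 1:20) {
    fq <- setNames(runif(5, 0.1, 5), organs)
    cp <- setNames(runif(5, 0, 3), organs)
    cm <- setNames(runif(5, 0, 3), organs)
    oracle <- 277.4 * sum(fq * cp) / sum(fq) +
      263.38 * sum(fq * cm) / sum(fq)
    expect_equal(active_moiety(cp, cm, fq), oracle, tolerance = 1e-12)
  }
  # the unnormalized literal reading keeps the raw flow-weighted sum
  fq <- setNames(rep(2, 5), organs)
  cp <- setNames(rep(1, 5), organs)
  cm <- setNames(rep(0, 5), organs)
  expect_equal(active_moiety(cp, cm, fq, am_raw_sum = TRUE),
               277.4 * sum(fq))
})

test_that("relative change reproduces printed prediction errors", {
  expect_equal(round(relative_change(144, 169), 1), -14.8)
  expect_equal(relative_change(5, 5), 0)
  expect_equal(report_round(relative_change(6197, 2949), "percent"), 110)
  expect_error(relative_change(1, 0), "zero")
})

test_that("bias and precision summaries behave and bound each other", {
  expect_equal(summarize_pe(c(10, -10)), list(mpe = 0, mape = 10))
  expect_equal(summarize_pe(-14.8), list(mpe = -14.8, mape = 14.8))
  set.seed(4)
  pe <- runif(1000, -80, 120)
  s <- summarize_pe(pe)
  expect_equal(s$mpe, mean(pe))
  expect_equal(s$mape, mean(abs(pe)))
  for (i in 1:25) {
    x <- rnorm(sample(1:40, 1), sd = 30)
    s <- summarize_pe(x)
    expect_gte(s$mape, abs(s$mpe))
  }
  expect_error(summarize_pe(numeric(0)), "empty")
})

test_that("metabolic ratios match the printed table values", {
  expect_equal(round(mr_auc(7086, 2949), 2), 2.40)
  expect_equal(round(mr_auc(3775, 7681), 2), 0.49)
  expect_equal(mr_auc(0, 5), 0)
  expect_error(mr_auc(1, 0), "AUC")
})

test_that("non-compartmental analysis matches closed forms", {
  tt <- seq(0, 24, by = 0.25)
  n <- nca(tt, rep(3, length(tt)), c(0, 24))
  expect_equal(n$auc, 72)
  expect_equal(n$cmax, 3)
  expect_equal(n$cmin, 3)
  # mono-exponential oracle at the default grid
  k <- 0.2
  cc <- 10 * exp(-k * tt)
  n <- nca(tt, cc, c(0, 24))
  expect_equal(n$auc, 10 / k * (1 - exp(-k * 24)), tolerance = 5e-4)
  # single interior peak: tmax at the grid maximum
  cc2 <- dnorm(tt, 6, 2)
  expect_equal(nca(tt, cc2, c(0, 24))$tmax, 6)
  # additivity over adjacent intervals
  a1 <- nca(tt, cc, c(0, 10))$auc
  a2 <- nca(tt, cc, c(10, 24))$auc
  expect_equal(a1 + a2, nca(tt, cc, c(0, 24))$auc, tolerance = 1e-12)
  # trough immediately before the next dose
  n <- nca(tt, cc, c(0, 12), dose_times_h = c(0, 12, 24))
  expect_equal(n$ctrough, 10 * exp(-k * 12), tolerance = 1e-9)
  expect_error(nca(tt, cc, c(30, 40)), "support")
})

test_that("fold-error fractions count pairs within the range", {
  expect_equal(fold_error_fraction(c(1, 2, 3), c(1, 2, 3), 1.25), 100)
  expect_equal(fold_error_fraction(c(1, 3), c(1, 1), 2), 50)
  set.seed(7)
  pred <- runif(500, 0.1, 10); obs <- runif(500, 0.1, 10)
  r <- pred / obs
  expect_equal(fold_error_fraction(pred, obs, 2),
               100 * mean(r >= 0.5 & r <= 2))
  # non-decreasing in the fold limit
  folds <- c(1.25, 1.5, 2, 3, 5)
  fr <- vapply(folds, function(f) fold_error_fraction(pred, obs, f),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_error(fold_error_fraction(1, 0, 2), "observed")
})

test_that("percentile coverage uses closed 5th-95th percentile bands", {
  sim <- 1:100
  obs <- c(rep(50, 33), 1000, 1000)  # 33 of 35 inside
  expect_equal(round(percentile_coverage(obs, sim), 1), 94.3)
  expect_equal(percentile_coverage(rep(median(sim), 10), sim), 100)
  expect_equal(percentile_coverage(rep(max(sim) + 1, 5), sim), 0)
  expect_error(percentile_coverage(1, 1:10), "small")
})

test_that("inhibition strength classification uses regulatory cutoffs", {
  expect_equal(classify_ddi(2.31), "moderate")
  expect_equal(classify_ddi(5.0), "strong")
  expect_equal(classify_ddi(1.0), "none")
  expect_equal(classify_ddi(1.25), "weak")
  expect_equal(classify_ddi(2.0), "moderate")
  expect_equal(classify_ddi(0.5), "none")
})

test_that("reference-range verdicts respect the documented boundaries", {
  expect_equal(reference_range_verdict(335), "therapeutic")
  expect_equal(reference_range_verdict(100), "therapeutic")
  expect_equal(reference_range_verdict(400), "therapeutic")
  expect_equal(reference_range_verdict(401), "supratherapeutic")
  expect_equal(reference_range_verdict(800), "supratherapeutic")
  expect_equal(reference_range_verdict(801), "toxic")
  expect_equal(reference_range_verdict(0), "subtherapeutic")
})
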