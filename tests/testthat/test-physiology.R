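test_that("reference adult reproduces the standard-European anthropometry", {
  ind <- reference_individual(30, "m", 73, 176)
  expect_equal(round(ind$bmi, 2), 23.57)
  expect_equal(sum(ind$blood_flows), ind$cardiac_output, tolerance = 1e-9)
  expect_true(all(ind$organ_volumes > 0))
  expect_true(all(ind$blood_flows > 0))
})

test_that("organ volumes scale linearly in body weight", {
  a <- reference_individual(30, "m", 73, 176)
  b <- reference_individual(30, "m", 146, 176)
  expect_equal(unname(b$organ_volumes), unname(2 * a$organ_volumes),
               tolerance = 1e-12)
  # allometric flow scaling follows weight^0.75
  expect_equal(b$cardiac_output / a$cardiac_output, 2^0.75,
               tolerance = 1e-12)
  b_lin <- reference_individual(30, "m", 146, 176, flow_scaling = "linear")
  expect_equal(b_lin$cardiac_output / a$cardiac_output, 2, tolerance = 1e-12)
})

test_that("filtration and cardiac output decline with age past 40", {
  young <- reference_individual(30, "m", 73, 176)
  old <- reference_individual(70, "m", 73, 176)
  expect_lt(old$gfr, young$gfr)
  expect_lt(old$cardiac_output, young$cardiac_output)
  # closed form of the linear decline: 0.7 %/yr (GFR), 0.5 %/yr (CO)
  expect_equal(old$gfr / young$gfr, 1 - 0.007 * 30, tolerance = 1e-12)
  expect_equal(old$cardiac_output / young$cardiac_output, 1 - 0.005 * 30,
               tolerance = 1e-12)
  ages <- seq(30, 100, by = 10)
  gfr <- vapply(ages, function(a)
    reference_individual(a, "m", 73, 176)$gfr, numeric(1))
  expect_true(all(diff(gfr) <= 0))
  expect_error(reference_individual(10, "m", 40, 140), "age")
  expect_error(reference_individual(30, "m", 500, 176), "weight")
})

test_that("population sampling respects ranges, sex ratio and anchor", {
  spec <- population_spec(25, c(20, 63), c(52, 140), c(152, 193),
                          fraction_female = 0.58, seed = 42,
                          median_anchor = list(age = 50, sex = "f",
                                               weight = 90, height = 171))
  pop <- sample_population(spec)
  expect_length(pop, 25L)
  ages <- vapply(pop, function(i) i$age, numeric(1))
  wts <- vapply(pop, function(i) i$weight, numeric(1))
  expect_true(all(ages >= 20 & ages <= 63))
  expect_true(all(wts >= 52 & wts <= 140))
  expect_equal(sum(vapply(pop, function(i) i$sex, character(1)) == "f"),
               round(25 * 0.58))
  expect_equal(pop[[1]]$age, 50)
  expect_equal(pop[[1]]$weight, 90)
  # flow balance on every sampled individual
  for (ind in pop)
    expect_equal(sum(ind$blood_flows), ind$cardiac_output,
                 tolerance = 1e-9 * ind$cardiac_output)
})

test_that("degenerate ranges give exactly the specified demographics", {
  spec <- population_spec(1, c(40, 40), c(80, 80), c(170, 170),
                          fraction_female = 0, seed = 5)
  ind <- sample_population(spec)[[1]]
  expect_equal(ind$age, 40)
  expect_equal(ind$weight, 80)
  expect_equal(ind$height, 170)
  expect_equal(ind$sex, "m")
})

test_that("population sampling is seed-deterministic", {
  s <- function(seed) stratum_population_spec("young", n = 8, seed = seed)
  p1 <- sample_population(s(1), fix_registry())
  p1b <- sample_population(s(1), fix_registry())
  p2 <- sample_population(s(2), fix_registry())
  expect_identical(p1, p1b)
  w1 <- vapply(p1[-1], function(i) i$weight, numeric(1))
  w2 <- vapply(p2[-1], function(i) i$weight, numeric(1))
  expect_false(isTRUE(all.equal(w1, w2)))
  # kinetic variability multipliers are part of the deterministic draw
  expect_identical(p1[[3]]$kcat_multipliers, p1b[[3]]$kcat_multipliers)
  expect_true(all(p1[[3]]$kcat_multipliers > 0))
})
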