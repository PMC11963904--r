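test_that("combined pressure and saturation match hand evaluation", {
  # worked by hand from the transformation formulas
  expect_equal(combined_partial_pressure(10, 0.8, 0.05, 0.01),
               10 + (10 / 0.8) * 0.05 / 0.94, tolerance = 1e-12)
  expect_equal(combined_partial_pressure(10, 0.8, 0.05, 0.01), 10.66489,
               tolerance = 1e-6)
  expect_equal(combined_saturation(0.9, 0.05, 0.01),
               (0.9 * 0.94 + 0.05) / 0.99, tolerance = 1e-12)
  expect_equal(combined_saturation(0.9, 0.05, 0.01), 0.9050505,
               tolerance = 1e-6)
  expect_equal(combined_saturation(1, 0, 0), 1)
})

test_that("transformations are identities without dyshaemoglobins", {
  p <- c(0.7, 3, 7, 20, 44)
  so2 <- c(0.12, 0.5, 0.867, 0.99, 0.999)
  expect_identical(combined_partial_pressure(p, so2, 0, 0), p)
  expect_identical(combined_saturation(so2, 0, 0), so2)
  expect_identical(saturation_to_so2(so2, 0, 0), so2)
})

test_that("combined saturation round-trips through its inverse", {
  grid <- expand.grid(SO2 = c(0.1, 0.5, 0.867, 0.99),
                      FCOHb = c(0, 0.03, 0.1),
                      FMetHb = c(0, 0.01, 0.05))
  s <- combined_saturation(grid$SO2, grid$FCOHb, grid$FMetHb)
  back <- saturation_to_so2(s, grid$FCOHb, grid$FMetHb)
  expect_equal(back, grid$SO2, tolerance = 1e-12)
})

test_that("degenerate haemoglobin fractions raise domain errors", {
  expect_error(combined_partial_pressure(10, 0, 0.05, 0.01), "SO2")
  expect_error(combined_partial_pressure(10, 0.9, 0.6, 0.4), "FCOHb")
  expect_error(combined_saturation(0.9, 0, 1), "FMetHb")
  expect_error(saturation_to_so2(0.5, 0.6, 0.5), "FCOHb")
  expect_error(displacement_ac(7.4, -1), "PCO2")
  expect_error(odc_forward(-1, 0, 37), "p must be positive")
})

test_that("displacement terms vanish at reference and scale as printed", {
  ref <- displacement_ac(7.40, 5.33, 0, 0, 5)
  expect_equal(ref$ac, 0, tolerance = 1e-15)
  expect_equal(unlist(ref[c("a1", "a2", "a3", "a4", "a5")]),
               c(a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0),
               tolerance = 1e-15)

  acid <- displacement_ac(7.20, 5.33, 0)
  expect_equal(acid$a1, 0.176, tolerance = 1e-12)
  expect_equal(acid$ac, 0.176, tolerance = 1e-12)

  over <- displacement_ac(7.40, 5.33, 0, a4_override = -0.3)
  expect_equal(over$ac, -0.3, tolerance = 1e-15)
  expect_equal(over$a6, 0)

  # additivity holds off reference too
  dt <- displacement_ac(7.1, 8, 0.01, 0.02, 6)
  expect_equal(dt$ac, dt$a1 + dt$a2 + dt$a3 + dt$a4 + dt$a5,
               tolerance = 1e-15)
})

test_that("forward curve hits the reference point and hand-computed shift", {
  expect_equal(odc_forward(7, 0, 37), 0.867, tolerance = 1e-12)
  expect_equal(sa_predict(7.40, 5.33, 0, T_cel = 37, p = 7,
                          a4_override = 0), 0.867, tolerance = 1e-12)
  # a = 0.176 (acidosis): hand evaluation through the Hill-plot chain
  expect_equal(odc_forward(7, 0.176, 37), 0.794787, tolerance = 1e-6)
  # fever shifts the curve rightwards: lower saturation at the same p
  expect_lt(odc_forward(7, 0, 39), 0.867)
})

test_that("hidden-term override composes through sa_predict", {
  a4 <- ground_truth_a4(1)
  expect_equal(a4, -0.30, tolerance = 1e-12)
  dt <- displacement_ac(7.40, 5.33, 0, a4_override = a4)
  expect_equal(dt$a, -0.30, tolerance = 1e-12)
  s <- sa_predict(7.40, 5.33, 0, T_cel = 37, p = c(1, 7, 30),
                  a4_override = ground_truth_a4(c(1, 7, 30)))
  expect_true(all(s > 0 & s < 1))
})

test_that("curve is strictly increasing in p across displacement range", {
  p <- exp(seq(log(0.5), log(45), length.out = 400))
  for (a in c(-2, -0.55, 0, 1, 2)) {
    s <- odc_forward(p, a, 37)
    expect_true(all(diff(s) > 0), info = paste("a =", a))
  }
})

test_that("saturation shifts with pH, PCO2 and temperature in the clinical directions", {
  eps <- 1e-4
  base <- sa_predict(7.40, 5.33, 0, T_cel = 37, p = 7)
  dpH <- sa_predict(7.40 + eps, 5.33, 0, T_cel = 37, p = 7) - base
  dCO2 <- sa_predict(7.40, 5.33 + eps, 0, T_cel = 37, p = 7) - base
  dT <- sa_predict(7.40, 5.33, 0, T_cel = 37 + eps, p = 7) - base
  expect_gt(dpH, 0)
  expect_lt(dCO2, 0)
  expect_lt(dT, 0)
})

test_that("odc_curve sweeps both saturation scales and honours shifts", {
  p_grid <- sort(c(7, exp(seq(log(0.5), log(45), length.out = 100))))
  ref <- odc_curve(7.40, 5.33, p_grid = p_grid, a4_provider = 0)
  expect_equal(ref$s[ref$p == 7], 0.867, tolerance = 1e-9)
  expect_true(all(diff(ref$s) > 0))
  expect_equal(ref$s, ref$SO2)  # no dyshaemoglobins

  alk <- odc_curve(7.60, 5.33, p_grid = p_grid, a4_provider = 0)
  expect_true(all(alk$s > ref$s))

  fun <- odc_curve(7.40, 5.33, p_grid = p_grid,
                   a4_provider = function(X) ground_truth_a4(X[, "p"]))
  expect_true(all(fun$s > 0 & fun$s < 1))
  expect_error(odc_curve(7.40, 5.33, p_grid = numeric(0)), "non-empty")
  expect_error(odc_curve(7.40, 5.33, p_grid = c(3, 2, 5)), "increasing")
})

test_that("blood gas records validate their physiological invariants", {
  rec <- blood_gas_record(7.4, 5.33, 37, 12, 0.95)
  expect_s3_class(rec, "blood_gas_record")
  expect_equal(rec$cDPG, 5)
  expect_error(blood_gas_record(7.4, 5.33, 37, 12, 1.2), "SO2")
  expect_error(blood_gas_record(7.4, 5.33, 37, -1, 0.9), "pO2")
  expect_error(blood_gas_record(7.4, 5.33, 37, 12, 0.9,
                                FCOHb = 0.7, FMetHb = 0.4), "FCOHb")
})

test_that("derived reference logit matches the stored saturation constant", {
  cst <- sa_constants()
  expect_equal(cst$y0, log(cst$s0 / (1 - cst$s0)), tolerance = 1e-15)
  expect_equal(stats::plogis(cst$y0), cst$s0, tolerance = 1e-15)
})
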