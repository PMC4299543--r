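test_that("cascade simulation obeys limits and conservation", {
  ## no activator, no autocatalysis: flat at Tr0
  flat <- simulateCascade(cascadeParams(kAuto = 0, kEp = 0, Tg0 = 2,
                                        Tr0 = 10), seq(0, 60, 5))
  expect_equal(tcValue(flat), rep(10, 13), tolerance = 1e-9)

  ## complete activation limit: Tr -> Tg0 + Tr0
  p <- cascadeParams(kAuto = 1.545, Tg0 = 2, Tr0 = 10)
  tc <- simulateCascade(p, c(0, 1, 5, 20, 80))
  expect_equal(tail(tcValue(tc), 1), 2010, tolerance = 1e-5)
  expect_true(all(diff(tcValue(tc)) >= -1e-9))  # monotone non-decreasing

  ## mass conservation from the full state
  st <- simulateCascade(p, seq(0, 20, 0.5), full = TRUE)
  expect_lt(max(abs(st$Tg + st$Tr - 2.01)), 1e-6)

  ## initial secant on a fine grid reproduces the closed-form initial rate
  fine <- simulateCascade(p, c(0, 1e-4))
  secant <- diff(tcValue(fine)) / 1e-4
  expect_equal(secant, initialActivationRate(p), tolerance = 0.01)
  expect_equal(initialActivationRate(p), 30.9, tolerance = 1e-9)

  expect_error(simulateCascade(p, c(1, 2)), "start at 0")
  expect_error(cascadeParams(kAuto = -1), "non-negative|>= 0")
})

test_that("activator-only cascade matches the exponential closed form", {
  p <- cascadeParams(kAuto = 0, kEp = 43.2, Tg0 = 2, Tr0 = 10, EP0 = 1)
  t <- seq(0, 120, 1)
  got <- tcValue(simulateCascade(p, t))
  want <- epClosedForm(43.2, 2, 10, 1, t)
  expect_lt(max(abs(got - want)) * 1e-3, 1e-6)  # compared in umol/L
})

test_that("activity/concentration conversions are exact unit arithmetic", {
  sp <- enzymeSpec("toy", molarMass = 20000, specificActivity = 50)
  expect_equal(activityToConcentration(0, sp), 0)
  expect_equal(activityToConcentration(1, sp), 1000)  # 1 umol/L in nmol/L
  expect_equal(concentrationToActivity(activityToConcentration(2.7, sp), sp),
               2.7, tolerance = 1e-12)
  dead <- enzymeSpec("dead", molarMass = 20000, specificActivity = 0)
  expect_error(activityToConcentration(1, dead), "zero specific activity")
  expect_error(enzymeSpec("bad", molarMass = 0, specificActivity = 5),
               "molarMass")
})

test_that("activation-rate estimation finds the initial linear slope", {
  t <- seq(0, 10, 0.5)
  lin <- timeCourse(t, 5 * t, "nmol_per_L")
  est <- estimateActivationRate(lin, totalZymogen = 2000)
  expect_equal(activationRate(est), 5)
  expect_equal(est@r2, 1)

  const <- timeCourse(t, rep(7, length(t)), "nmol_per_L")
  expect_equal(activationRate(estimateActivationRate(const)), 0)

  ## activity input converts through the enzyme spec first
  sp <- enzymeSpec("toy", molarMass = 25000, specificActivity = 69)
  act <- timeCourse(t, concentrationToActivity(5 * t, sp), "U_per_mL")
  expect_equal(activationRate(estimateActivationRate(act, spec = sp,
                                                     totalZymogen = 2000)),
               5, tolerance = 1e-9)
  expect_error(estimateActivationRate(act), "EnzymeSpec")

  ## noiseless autocatalytic course on an early dense grid: slope within 2%
  ## of the generating initial rate (the signal e-folds in ~0.3 min, so the
  ## window must be early)
  p <- cascadeParams(kAuto = 1.545, Tg0 = 2, Tr0 = 10)
  early <- simulateCascade(p, seq(0, 0.01, 0.001))
  estw <- estimateActivationRate(early, totalZymogen = 2010)
  expect_equal(activationRate(estw), 30.9, tolerance = 0.02)

  ## degenerate: the first window already violates the conversion cap
  steep <- timeCourse(c(0, 1, 2, 3), c(0, 500, 1000, 1500), "nmol_per_L")
  expect_error(estimateActivationRate(steep, totalZymogen = 2000,
                                      maxConversion = 0.1),
               "no qualifying")
})

test_that("cascade constant is recovered from noiseless courses", {
  p <- cascadeParams(kAuto = 1.545, Tg0 = 2, Tr0 = 10)
  tc <- simulateCascade(p, seq(0, 5, 0.2))
  fit <- fitCascade(tc, Tg0 = 2, Tr0 = 10)
  expect_equal(fit@kAuto, 1.545, tolerance = 0.01)

  ## activator-driven course with both constants
  p2 <- cascadeParams(kAuto = 0.3, kEp = 43.2, Tg0 = 2, Tr0 = 10, EP0 = 1)
  tc2 <- simulateCascade(p2, seq(0, 40, 2))
  fit2 <- fitCascade(tc2, Tg0 = 2, Tr0 = 10, EP0 = 1, fitKEp = TRUE)
  expect_equal(fit2@kAuto, 0.3, tolerance = 0.02)
  expect_equal(fit2@kEp, 43.2, tolerance = 0.02)
})

test_that("Michaelis-Menten fitting is exact on noiseless data", {
  ## half-saturation identity: fitted curve passes Vmax/2 at S = Km
  d <- genMMData(km = 50, kcat = 100, e0 = 1, c(5, 20, 50, 120, 300))
  f <- fitMM(d)
  expect_equal(mmKm(f), 50, tolerance = 1e-6)
  vAtKm <- mmKcat(f) * 1e-3 * mmKm(f) / (mmKm(f) + mmKm(f))
  expect_equal(vAtKm, 0.5 * mmKcat(f) * 1e-3, tolerance = 1e-9)

  ## round-trip at the wild-type-like parameter point
  dwt <- genMMData(78.0, 324.1, 1, c(10, 25, 50, 100, 200, 400))
  fwt <- fitMM(dwt)
  expect_equal(mmKm(fwt), 78.0, tolerance = 1e-3)
  expect_equal(mmKcat(fwt), 324.1, tolerance = 1e-3)

  expect_error(fitMM(mmDataset(c(10, 10, 20), c(1, 1, 2), 1)), "4 distinct")
  expect_error(mmParams(km = -5, kcat = 10), "> 0")
})

test_that("catalytic efficiency and fold differences are simple ratios", {
  eff <- catalyticEfficiency(mmParams(km = 129.8, kcat = 489.0))
  expect_equal(eff, 489.0 / 129.8, tolerance = 1e-12)
  expect_equal(foldDifference(3, 3), 1)
  expect_error(foldDifference(1, 0), "zero denominator")
})

test_that("time-course and velocity CSV files round-trip", {
  tc <- timeCourse(c(0, 5, 10), c(0.1, 0.5, 0.9), "U_per_mL")
  f <- tempfile(fileext = ".csv")
  writeTimeCourseCSV(tc, f)
  back <- readTimeCourseCSV(f)
  expect_equal(tcTime(back), tcTime(tc))
  expect_equal(tcValue(back), tcValue(tc))
  expect_equal(tcUnit(back), "U_per_mL")
  unlink(f)

  d <- genMMData(78, 324.1, 1, c(10, 50, 200))
  g <- tempfile(fileext = ".csv")
  writeMMCSV(d, g)
  back2 <- readMMCSV(g, e0 = 1)
  expect_equal(back2@substrate, d@substrate)
  expect_equal(back2@velocity, d@velocity)
  unlink(g)
})
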