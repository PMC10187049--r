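so <- soralisParams()
lp <- lparacaseiParams()

test_that("Monod growth rate matches hand-evaluated values", {
  # at Sg = KSg with saturating oxygen the rate is half-maximal
  expect_equal(monodMu(so, Sg = so@KSg, So = 1e6), so@muMax / 2,
               tolerance = 1e-6)
  # hand evaluation at the standard bulk conditions
  expect_equal(monodMu(so, Sg = 2, So = 0.0064),
               0.32 * (2 / 3.756) * (0.0064 / 0.006592), tolerance = 1e-12)
  expect_equal(monodMu(so, Sg = 2, So = 0.0064), 0.16543, tolerance = 1e-4)
  # zero substrate shuts growth off entirely
  expect_identical(monodMu(so, 0, 0.0064), 0)
  expect_identical(monodMu(lp, 2, 0), 0)
  expect_error(monodMu(so, -1, 1), ">= 0")
})

test_that("Monod rate is monotone and bounded", {
  Sg <- seq(0, 5, by = 0.25)
  mu <- monodMu(so, Sg, So = 0.0064)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu >= 0 & mu <= so@muMax))
  mu2 <- monodMu(so, 2, seq(0, 0.01, by = 5e-4))
  expect_true(all(diff(mu2) > 0))
})

test_that("inhibition factor has its defining half-effect point", {
  expect_identical(inhibitionFactor(0, 0.0025), 1)
  expect_equal(inhibitionFactor(0.0025, 0.0025), 0.5)
  expect_equal(inhibitionFactor(3 * 0.0025, 0.0025), 0.25)
  expect_lt(inhibitionFactor(1e6, 0.0025), 1e-8)
  I <- seq(0, 0.02, by = 0.001)
  expect_true(all(diff(inhibitionFactor(I, 0.0025)) < 0))
  expect_error(inhibitionFactor(-0.1, 0.0025), ">= 0")
  # combined identity: Sg = KSg, saturating oxygen, I = KI -> muMax/4
  expect_equal(monodMu(so, so@KSg, 1e9) * inhibitionFactor(so@KI, so@KI),
               so@muMax / 4, tolerance = 1e-6)
})

test_that("effective growth rate wires variants correctly", {
  solutes <- c(glucose = 2, oxygen = 0.0064, inhibitor = 0.0025)
  base <- monodMu(so, 2, 0.0064)
  expect_equal(effectiveMu(so, solutes, "COMPETITION"), base)
  expect_equal(effectiveMu(so, solutes, "INHIBITION"), base * 0.5)
  # L. paracasei carries no KI and is never inhibited
  expect_equal(effectiveMu(lp, solutes, "INHIBITION"),
               monodMu(lp, 2, 0.0064))
  # independent substrates: each species reads its own carbon field
  sol2 <- c(substrate1 = 2, substrate2 = 0.5, oxygen = 0.0064)
  expect_equal(effectiveMu(so, sol2, "INDEPENDENT_SUBSTRATES",
                           carbon = "substrate1"),
               monodMu(so, 2, 0.0064))
  expect_equal(effectiveMu(lp, sol2, "INDEPENDENT_SUBSTRATES",
                           carbon = "substrate2"),
               monodMu(lp, 0.5, 0.0064))
  expect_error(effectiveMu(so, c(glucose = 2, oxygen = 0.0064),
                           "INHIBITION"), "inhibitor")
  expect_lte(effectiveMu(so, solutes, "INHIBITION"),
             monodMu(so, 2, 0.0064))
})

test_that("biomass update follows exact exponential growth and the capsule split", {
  # zero growth leaves masses untouched
  up <- biomassStep(100, 5, mu = 0, dt = 1, so)
  expect_equal(up$biomass_fg, 100)
  expect_equal(up$capsule_fg, 5)
  # X = 100 fg at mu = 0.32/h over 1 h: Delta = 100 (e^0.32 - 1) = 37.713 fg
  delta <- 100 * (exp(0.32) - 1)
  up <- biomassStep(100, 0, mu = 0.32, dt = 1, so)
  expect_equal(up$biomass_fg, 100 + 0.8 * delta, tolerance = 1e-12)
  expect_equal(up$capsule_fg, 0.2 * delta, tolerance = 1e-12)
  expect_equal(up$biomass_fg - 100 + up$capsule_fg, delta, tolerance = 1e-12)
  expect_equal(0.8 * delta, 30.170, tolerance = 1e-4)
  expect_equal(0.2 * delta, 7.5426, tolerance = 1e-4)
  # with EPS off all produced mass goes to biomass
  up2 <- biomassStep(100, 0, mu = 0.32, dt = 1, so, epsActive = FALSE)
  expect_equal(up2$biomass_fg, 100 + delta, tolerance = 1e-12)
  expect_equal(up2$capsule_fg, 0)
  expect_error(biomassStep(100, 0, mu = 0.1, dt = 0, so), "dt")
})

test_that("solute rates follow the yields and first-order production", {
  r <- soluteRates(so, mu = 0.16, biomass_fg = 100, "COMPETITION")
  expect_equal(r$carbon, -48)   # yield -3
  expect_equal(r$oxygen, -32)   # yield -2
  expect_equal(r$inhibitor, 0)
  r2 <- soluteRates(lp, mu = 0.1, biomass_fg = 100, "INHIBITION")
  expect_equal(r2$inhibitor, 0.3 * 0.7 * 100)
  expect_equal(r2$surfactant, 0)  # variant does not activate surfactant
  r3 <- soluteRates(lp, mu = 0, biomass_fg = 100, "INHIBITION_SURFACTANT")
  # production is first-order in biomass, not growth-coupled
  expect_equal(r3$carbon, 0)
  expect_equal(r3$inhibitor, 21)
  expect_equal(r3$surfactant, 0.4 * 0.7 * 100)
})
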