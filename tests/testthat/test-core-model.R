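test_that("arrhenius adjustment honours its identities and oracle value", {
  # reference-temperature identity and zero activation energy
  expect_equal(arrheniusAdjust(404.9, 79430, 25), 404.9)
  expect_equal(arrheniusAdjust(100, 0, 40), 100)
  # frozen value from an independent single-line transcription of the form
  expect_equal(arrheniusAdjust(404.9, 79430, 35), 1145.3969641711,
               tolerance = 1e-10)
  # strictly increasing in temperature for positive Ea
  tl <- seq(0, 45, by = 2.5)
  expect_true(all(diff(arrheniusAdjust(42.75, 37830, tl)) > 0))
  expect_error(arrheniusAdjust(NaN, 100, 25), "finite")
  expect_error(arrheniusAdjust(-5, 100, 25), "positive")
})

test_that("peaked Arrhenius peaks at kopt and matches the formula oracle", {
  expect_equal(peakedArrhenius(100, 313.15, 60000, 2e5, 313.15), 100)
  # frozen value from an independent transcription of the peaked form
  expect_equal(peakedArrhenius(100, 313.15, 60000, 2e5, 293.15),
               29.5860154376, tolerance = 1e-10)
  # unimodality: strictly below kopt anywhere off the optimum
  tl <- seq(273.15, 330.15, by = 0.5)
  f <- peakedArrhenius(100, 313.15, 60000, 2e5, tl)
  expect_true(all(f[abs(tl - 313.15) > 1e-9] < 100))
  expect_error(peakedArrhenius(100, 313.15, 2e5, 2e5, 300), "ea < hd")
  expect_error(peakedArrhenius(100, 40, 6e4, 2e5, 30), "Kelvin")
})

test_that("peaked form collapses to simple Arrhenius for huge Hd and distant Topt", {
  # normalise at 25 C so the shapes are compared
  ea <- 65000; topt <- 360; hd <- 1e7
  tl <- seq(5, 35, by = 1)
  ref <- peakedArrhenius(100, topt, ea, hd, 25 + 273.15)
  shape_peaked <- peakedArrhenius(100, topt, ea, hd, tl + 273.15) / ref
  shape_simple <- arrheniusAdjust(1, ea, tl)
  expect_equal(shape_peaked, shape_simple, tolerance = 1e-6)
})

test_that("Rubisco-limited assimilation obeys compensation and saturation", {
  kat <- tobaccoAt(25)
  expect_equal(fvcbAc(50, kat$gammastar, 210000, kat$kc, kat$ko,
                      kat$gammastar, 1), -1)
  expect_equal(fvcbAc(50, 1e9, 210000, kat$kc, kat$ko, kat$gammastar, 1),
               49, tolerance = 1e-3)
  # frozen formula-evaluation oracle at Ci = 300, tobacco constants, 25 C
  expect_equal(fvcbAc(50, 300, 210000, 404.9, 278400, 42.75, 1),
               11.7311116354, tolerance = 1e-10)
  ci <- seq(50, 2000, by = 10)
  expect_true(all(diff(fvcbAc(50, ci, 210000, kat$kc, kat$ko,
                              kat$gammastar, 1)) > 0))
  expect_error(fvcbAc(-1, 300, 210000, kat$kc, kat$ko, kat$gammastar, 1),
               "non-negative")
})

test_that("electron transport takes the lower quadratic root", {
  expect_equal(electronTransport(100, q = 0), 0)
  # frozen lower root from the quadratic formula
  expect_equal(electronTransport(100, q = 1800, alpha = 0.24, theta = 0.85),
               95.8959034996, tolerance = 1e-10)
  # theta -> 0 degenerates to the rectangular hyperbola
  aq <- 0.24 * 1800
  expect_equal(electronTransport(100, theta = 0),
               aq * 100 / (aq + 100))
  expect_equal(electronTransport(100, theta = 1e-12),
               aq * 100 / (aq + 100), tolerance = 1e-6)
  # bounded by both light supply and capacity; saturates to jmax
  for (jm in c(30, 100, 250)) {
    J <- electronTransport(jm, q = 700)
    expect_lt(J, min(0.24 * 700, jm))
    expect_gt(J, 0)
  }
  expect_equal(electronTransport(80, q = 1e8), 80, tolerance = 1e-3)
})

test_that("RuBP-regeneration-limited assimilation matches its limits and oracle", {
  expect_equal(fvcbAj(80, 42.75, 42.75, 1), -1)
  expect_equal(fvcbAj(80, 1e9, 42.75, 1), 19, tolerance = 1e-3)
  expect_equal(fvcbAj(80, 300, 42.75, 1), 12.3463035019, tolerance = 1e-10)
})

test_that("net assimilation is the strict minimum with a labelled limitation", {
  kat <- tobaccoAt(25)
  # above the compensation point the scarce capacity limits; below it the
  # branches swap roles, so the limit identities are asserted on Ci > Gamma*
  ci <- 0.72 * CA_SEQ
  ci <- ci[ci > kat$gammastar]
  hi_v <- fvcbAnet(1e6, 100, ci, kc = kat$kc, ko = kat$ko,
                   gammastar = kat$gammastar, rl = 1)
  expect_true(all(hi_v$limiting == "Aj"))
  expect_equal(hi_v$anet, hi_v$aj)
  hi_j <- fvcbAnet(50, 1e6, ci, kc = kat$kc, ko = kat$ko,
                   gammastar = kat$gammastar, rl = 1)
  expect_true(all(hi_j$limiting == "Ac"))
  expect_equal(hi_j$anet, hi_j$ac)
})

test_that("Ac/Aj crossover from bisection agrees with a fine grid scan", {
  kat <- tobaccoAt(25)
  f <- function(ci) {
    with(kat, fvcbAc(50, ci, 210000, kc, ko, gammastar, 1) -
           fvcbAj(electronTransport(100), ci, gammastar, 1))
  }
  cross_bisect <- uniroot(f, c(kat$gammastar + 1, 2000), tol = 1e-10)$root
  grid <- seq(kat$gammastar + 1, 2000, by = 0.1)
  cross_grid <- grid[which.min(abs(f(grid)))]
  expect_lt(abs(cross_bisect - cross_grid), 0.1)
  # and Anet is continuous, non-decreasing in Ci across the crossover
  an <- fvcbAnet(50, 100, grid, kc = kat$kc, ko = kat$ko,
                 gammastar = kat$gammastar, rl = 1)$anet
  expect_true(all(diff(an) > -1e-12))
  expect_lt(max(abs(diff(an))), 0.1)
})

test_that("quadratic thermal response optimum follows the closed form", {
  opt <- toptFromQuadratic(-0.02, 1.0, 2.0)
  expect_equal(opt$topta, 25.0)
  expect_equal(opt$aopt, 14.5)
  expect_error(toptFromQuadratic(0.01, 1, 0), "optimum")
  # maximum property on random concave parabolas
  set.seed(42)
  for (i in 1:20) {
    a <- -runif(1, 0.005, 0.1); b <- runif(1, -2, 2); cc <- runif(1, -5, 5)
    opt <- toptFromQuadratic(a, b, cc)
    expect_gt(opt$aopt, quadraticAgrowth(a, b, cc, opt$topta + 0.1))
    expect_gt(opt$aopt, quadraticAgrowth(a, b, cc, opt$topta - 0.1))
  }
})
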