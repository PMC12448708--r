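test_that("the generator is fully deterministic from (config, seed)", {
  cfg <- tinyConfig(seed = 5)
  s1 <- generateStudy(cfg)
  s2 <- generateStudy(cfg)
  expect_identical(s1, s2)
  t1 <- assignTrueParameters(cfg)
  t2 <- assignTrueParameters(cfg)
  expect_identical(t1, t2)
  # byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeGasExchange(s1, f1); writeGasExchange(s2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("row counts follow the design arithmetic", {
  cfg <- studyConfig(seed = 1, n_trees = 2, years = c(2019, 2021),
                     species = c("a_sp", "b_sp"))
  st <- generateStudy(cfg)
  expect_equal(nrow(st), 2 * 2 * 6 * 2 * 4 * 12)
  expect_setequal(unique(st$tgrow), c("0T", "4T", "8T"))
  expect_setequal(unique(st$cgrow), c("AC", "EC"))
})

test_that("neutral effect sizes leave all treatments at the shared baseline", {
  cfg <- tinyConfig(seed = 8, tree_sd_frac = 0,
                    kopt_mult = c("0T" = 1, "4T" = 1, "8T" = 1))
  truth <- assignTrueParameters(cfg)
  expect_equal(length(unique(round(truth$kopt_v, 9))), 1)
  expect_equal(length(unique(round(truth$kopt_j, 9))), 1)
})

test_that("warming multipliers reach their configured ratio on average", {
  rats <- vapply(1:40, function(s) {
    truth <- assignTrueParameters(studyConfig(seed = s, n_trees = 4,
                                              years = 2019,
                                              species = "black_spruce"))
    mean(truth$kopt_v[truth$tgrow == "8T"]) /
      mean(truth$kopt_v[truth$tgrow == "0T"])
  }, 0)
  expect_lt(abs(mean(rats) - 0.70), 0.02)
})

test_that("noise-free curves are monotone non-decreasing in Ca", {
  cfg <- tinyConfig(seed = 9, noise_sd = 0)
  st <- generateStudy(cfg)
  key <- paste(st$tree_id, st$tleaf)
  for (k in unique(key)[1:8]) {
    cv <- st[key == k, ]
    cv <- cv[order(cv$ca), ]
    expect_true(all(diff(cv$anet) > -1e-9))
  }
})

test_that("the noiseless study round-trips through the fitting pipeline", {
  cfg <- studyConfig(seed = 10, n_trees = 1, years = 2019,
                     species = "tamarack", noise_sd = 0, tree_sd_frac = 0)
  st <- generateStudy(cfg)
  truth <- attr(st, "truth")
  fits <- fitStudyACi(st, estimate_rl = TRUE)
  expect_true(all(fits$accepted))
  th <- fitStudyThermal(fits)
  m <- merge(th, truth, by = "tree_id", suffixes = c("", ".true"))
  expect_lt(max(abs(m$kopt_v / m$kopt_v.true - 1)), 0.02)
  expect_lt(max(abs((m$topt_v + 273.15) - m$topt_v.true)), 0.3)
  expect_lt(max(abs(m$ea_v / m$ea_v.true - 1)), 0.05)
})

test_that("injected corruption is rejected exactly, whole-curve missingness is seeded", {
  cfg <- studyConfig(seed = 4, n_trees = 3, years = 2019,
                     species = "jack_pine", corrupt_fraction = 0.05)
  st <- generateStudy(cfg)
  bad <- attr(st, "corrupt_curves")
  expect_gt(length(bad), 0)
  fits <- fitStudyACi(st)
  rejected <- paste(fits$tree_id, fits$tleaf, sep = "@")[
    grepl("negative Ci", fits$reasons)]
  expect_setequal(rejected, bad)

  st0 <- generateStudy(tinyConfig(seed = 5))
  expect_identical(injectMissingness(st0, 0), st0)
  m1 <- injectMissingness(st0, 0.3, seed = 2)
  m2 <- injectMissingness(st0, 0.3, seed = 2)
  expect_identical(m1, m2)
  # whole curves only: every surviving curve keeps its 12 steps
  key <- paste(m1$tree_id, m1$year, m1$tleaf)
  expect_true(all(table(key) == 12))
  # unbalanced cells emerge
  n_per_cell <- tapply(m1$tree_id, paste(m1$tgrow, m1$cgrow, m1$tleaf),
                       function(x) length(unique(x)))
  expect_gte(length(unique(n_per_cell)), 2)
  expect_error(injectMissingness(st0, 0.7), "rate")
})
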