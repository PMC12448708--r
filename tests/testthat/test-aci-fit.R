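test_that("noiseless forward-model curves are recovered essentially exactly", {
  for (v in c(20, 200)) for (j in c(50, 100)) {
    fit <- fitACi(makeCurve(vcmax = v, jmax = j, rl = 1))
    expect_lt(abs(fit$vcmax / v - 1), 0.005)
    expect_lt(abs(fit$jmax / j - 1), 0.005)
  }
  # a high Jmax/Vcmax ratio must not trap the multi-start in a local minimum
  fit <- fitACi(makeCurve(vcmax = 20, jmax = 100, rl = 1))
  expect_lt(abs(fit$vcmax / 20 - 1), 0.005)
  expect_lt(abs(fit$jmax / 100 - 1), 0.005)
})

test_that("fixed-RL mode recovers capacities with RL taken from kinetics", {
  fit <- fitACi(makeCurve(vcmax = 60, jmax = 110, rl = 1),
                estimate_rl = FALSE, rl_fixed = 1)
  expect_false(fit$rl_estimated)
  expect_equal(fit$rl, 1)
  expect_lt(abs(fit$vcmax / 60 - 1), 0.005)
})

test_that("fits are deterministic and report limiting states per point", {
  curve <- makeCurve(50, 100, 1, noise_sd = 0.5, seed = 11)
  f1 <- fitACi(curve); f2 <- fitACi(curve)
  expect_identical(f1$vcmax, f2$vcmax)
  expect_identical(f1$jmax, f2$jmax)
  expect_length(f1$limiting_state, nrow(curve))
  expect_true(all(f1$limiting_state %in% c("Ac", "Aj")))
  # on a clean curve: mid-range Ci carboxylation-limited, top step
  # regeneration-limited (fitACi keeps points in measurement order)
  clean <- makeCurve(50, 100, 1)
  fc <- fitACi(clean)
  expect_equal(fc$limiting_state[clean$ca == 300], "Ac")
  expect_equal(fc$limiting_state[which.max(clean$ci)], "Aj")
})

test_that("a curve with no high-Ci points flags jmax as unidentifiable", {
  curve <- makeCurve(50, 100, 1, ca = c(50, 100, 150, 200, 250, 270))
  fit <- fitACi(curve)
  expect_true("jmax_unidentifiable" %in% fit$flags)
})

test_that("curves with too few points are unfittable", {
  expect_error(fitACi(makeCurve(ca = c(100, 300, 600, 1200))), "unfittable")
})

test_that("NLS solution sits within one grid cell of an exhaustive search", {
  curve <- makeCurve(50, 100, 1, ca = c(50, 150, 300, 600, 1200, 2000),
                     noise_sd = 0.4, seed = 3)
  fit <- fitACi(curve, estimate_rl = FALSE, rl_fixed = 1)
  grid <- gridSearchACi(curve, seq(30, 70, by = 0.25),
                        seq(60, 140, by = 0.25), rl = 1)
  expect_lte(abs(fit$vcmax - grid[["vcmax"]]), 0.25)
  expect_lte(abs(fit$jmax - grid[["jmax"]]), 0.25)
})

test_that("QC enforces the curve-rejection rules with enumerated reasons", {
  clean <- makeCurve(50, 100, 1)
  ok <- qcFilter(fitACi(clean), clean)
  expect_true(ok$qc$accepted)
  expect_length(ok$qc$reasons, 0)

  # out-of-range parameters
  low <- makeCurve(5, 40, 0.5)
  fit_low <- qcFilter(fitACi(low), low)
  expect_false(fit_low$qc$accepted)
  expect_true(any(grepl("below 10", fit_low$qc$reasons)))

  # a single negative Ci point condemns the curve
  neg <- clean; neg$ci[3] <- -12
  fit_neg <- qcFilter(fitACi(neg), neg)
  expect_false(fit_neg$qc$accepted)
  expect_true(any(grepl("negative Ci", fit_neg$qc$reasons)))

  # idempotent: re-applying the verdict changes nothing
  twice <- qcFilter(fit_neg, neg)
  expect_identical(twice$qc, fit_neg$qc)
})

test_that("operating point lands on the growth-CO2 step", {
  curve <- makeCurve(50, 100, 1)
  op_ac <- extractOperatingPoint(curve, "AC")
  # the 400 step appears twice; the later (post-recovery) step must win
  expect_equal(op_ac$target_ca, 400)
  expect_equal(op_ac$agrowth, curve$anet[7])
  op_ec <- extractOperatingPoint(curve, "EC")
  expect_equal(op_ec$target_ca, 800)
  expect_equal(op_ec$agrowth, curve$anet[curve$ca == 800])
  expect_gt(op_ec$ci_over_ca, 0)
  expect_lt(op_ec$ci_over_ca, 1.2)
  no400 <- curve[!curve$ca %in% c(400), ]
  expect_error(extractOperatingPoint(no400, "AC"), "missing operating point")
})
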