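test_that("total PVR converts the pressure gradient to CGS", {
  expect_equal(
    total_pvr(rhc_record(mPAP = 21, sPAP = 30, dPAP = 15, PAWP = 11, CO = 5)),
    160
  )
  # Table-style CTEPH medians: (38 - 9)/5.15 WU in CGS
  cteph <- rhc_record(mPAP = 38, sPAP = 63, dPAP = 17, PAWP = 9, CO = 5.15, HR = 75)
  expect_equal(total_pvr(cteph), (38 - 9) / 5.15 * 80, tolerance = 1e-12)
  expect_error(
    total_pvr(rhc_record(mPAP = 10, sPAP = 20, dPAP = 5, PAWP = 10, CO = 5)),
    "PAWP"
  )
})

test_that("inconsistent supplied PVR is rejected", {
  expect_error(
    rhc_record(
      mPAP = 38, sPAP = 63, dPAP = 17, PAWP = 9, CO = 5.15,
      HR = 75, PVR = 12
    ),
    "inconsistent"
  )
})

test_that("resistance distribution follows the inverse diameter power law", {
  expect_equal(distribute_resistance(c(1, 1), 1), c(2, 2))
  # worked two-outlet example, exponent 2.25
  r <- distribute_resistance(c(2, 1), 1, exponent = 2.25)
  s <- 2^2.25 + 1
  expect_equal(r, c(s / 2^2.25, s), tolerance = 1e-12)
  expect_equal(r[1], 1.21022, tolerance = 1e-5)
  expect_equal(r[2], 5.75683, tolerance = 1e-5)
  expect_equal(1 / sum(1 / r), 1, tolerance = 1e-12)
  # exponent 0: equal split regardless of diameters
  expect_equal(distribute_resistance(c(3, 0.5, 1), 6, exponent = 0), rep(18, 3))
  expect_error(distribute_resistance(numeric(0), 1), "non-empty")
})

test_that("distributed resistances recombine in parallel to the total", {
  set.seed(101)
  for (i in 1:100) {
    d <- stats::runif(sample(2:12, 1), 0.2, 4)
    R <- stats::runif(1, 10, 2000)
    e <- stats::runif(1, 0, 4)
    r <- distribute_resistance(d, R, e)
    expect_lt(abs(1 / sum(1 / r) - R) / R, 1e-10)
  }
})

test_that("compliance is distributed by diameter squared and conserved", {
  expect_equal(distribute_compliance(c(2, 1), 5), c(4, 1))
  expect_equal(distribute_compliance(rep(1, 4), 1), rep(0.25, 4))
  set.seed(102)
  for (i in 1:100) {
    d <- stats::runif(sample(2:12, 1), 0.2, 4)
    C <- stats::runif(1, 1e-4, 1e-2)
    expect_equal(sum(distribute_compliance(d, C)), C, tolerance = 1e-12)
  }
})

test_that("RCR assembly splits resistance by the proximal fraction", {
  rcr <- assemble_rcr(c(100, 200), c(1e-4, 2e-4),
    outlet_ids = c("a", "b"),
    rp_fraction = 0.1, distal_pressure = 10
  )
  expect_equal(rcr$Rp, c(10, 20))
  expect_equal(rcr$Rd, c(90, 180))
  expect_equal(rcr$Rp + rcr$Rd, c(100, 200))
  expect_equal(attr(rcr, "distal_pressure"), 10 * 1333.22)
  rc <- assemble_rcr(100, 1e-4, "a", rp_fraction = 0)
  expect_equal(rc$Rp, 0)
  expect_error(assemble_rcr(100, 1e-4, "a", rp_fraction = 1), "rp_fraction")
})

test_that("RCR files round-trip with distal pressure and comments", {
  rcr <- assemble_rcr(c(120, 300), c(1e-4, 5e-5),
    outlet_ids = c("s2", "s3"),
    distal_pressure = 9
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_rcr(rcr, path, comments = "tuned to synthetic record")
  back <- read_rcr(path)
  expect_equal(back$Rp, rcr$Rp, tolerance = 1e-12)
  expect_equal(back$Rd, rcr$Rd, tolerance = 1e-12)
  expect_equal(back$C, rcr$C, tolerance = 1e-12)
  expect_equal(attr(back, "distal_pressure"), attr(rcr, "distal_pressure"))
})

test_that("tuning converges immediately at a fixed point", {
  # with a negligible segment resistance the initial guess R = (mPAP-PAWP)/CO
  # already reproduces the target mean pressure: one iteration, scale 1
  tree <- single_segment_tree(length_cm = 1e-8, diameter_cm = 2)
  rhc <- rhc_record(mPAP = 20, PAWP = 8, CO = 5, HR = 60)
  fit <- tune_rcr(tree, rhc)
  expect_true(fit$report$converged)
  expect_equal(fit$report$iterations, 1L)
  # full tree: re-tuning a record set to the achieved values stays converged
  tree2 <- generate_tree(2.3, n_generations = 2, seed = 1)
  fit1 <- tune_rcr(tree2, table2_control_rhc())
  rhc2 <- rhc_record(
    mPAP = fit1$report$achieved_mPAP,
    sPAP = fit1$report$achieved_mPAP + fit1$report$achieved_pulse_pressure / 2,
    dPAP = fit1$report$achieved_mPAP - fit1$report$achieved_pulse_pressure / 2,
    PAWP = 10, CO = 5.20, HR = 75
  )
  fit2 <- tune_rcr(tree2, rhc2)
  expect_true(fit2$report$converged)
})

test_that("single-outlet steady tuning recovers the closed-form resistance", {
  tree <- single_segment_tree(length_cm = 1e-6, diameter_cm = 2)
  rhc <- rhc_record(mPAP = 20, PAWP = 8, CO = 5, HR = 60) # no sPAP/dPAP: mean-only tuning
  fit <- tune_rcr(tree, rhc)
  expect_true(fit$report$converged)
  # mean relation: mPAP - PAWP = Q_mean * (Rseg + Rp + Rd)
  R_closed <- (20 - 8) * 1333.22 / (5 * 16.6667)
  expect_equal(fit$rcr$Rp + fit$rcr$Rd, R_closed,
    tolerance = 0.02
  )
})

test_that("tuning hits Table-2-style control targets within tolerance", {
  tree <- generate_tree(2.3, n_generations = 3, seed = 3)
  fit <- tune_rcr(tree, table2_control_rhc())
  expect_true(fit$report$converged)
  expect_lt(abs(fit$report$achieved_mPAP - 18.0) / 18.0, 0.02)
  expect_lt(abs(fit$report$achieved_pulse_pressure - 16.0) / 16.0, 0.02)
})

test_that("final total resistance is monotone in the target mPAP", {
  tree <- generate_tree(2.5, n_generations = 2, seed = 2)
  totals <- sapply(c(16, 20, 26, 34), function(m) {
    rhc <- rhc_record(
      mPAP = m, sPAP = m + 9, dPAP = m - 5, PAWP = 8,
      CO = 5.2, HR = 75
    )
    fit <- tune_rcr(tree, rhc)
    expect_true(fit$report$converged)
    1 / sum(1 / (fit$rcr$Rp + fit$rcr$Rd))
  })
  expect_true(all(diff(totals) > 0))
})

test_that("tuning recovers targets generated by a ground-truth RCR set", {
  tree <- generate_tree(2.4, n_generations = 2, seed = 8)
  leaf <- outlets(tree)
  truth <- assemble_rcr(
    distribute_resistance(leaf$diameter_cm, 150),
    distribute_compliance(leaf$diameter_cm, 2.5e-3),
    outlet_ids = leaf$id, distal_pressure = 9
  )
  inflow <- make_inflow(5.4, 72)
  sol <- solve_hemodynamics(tree, truth, inflow)
  target <- summarize_pressures(sol)
  rhc <- rhc_record(
    mPAP = target$mPAP, sPAP = target$sPAP, dPAP = target$dPAP,
    PAWP = 9, CO = 5.4, HR = 72
  )
  fit <- tune_rcr(tree, rhc)
  expect_true(fit$report$converged)
  expect_lt(abs(fit$report$achieved_mPAP - target$mPAP) / target$mPAP, 0.02)
  pp_t <- target$sPAP - target$dPAP
  expect_lt(abs(fit$report$achieved_pulse_pressure - pp_t) / pp_t, 0.02)
})
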