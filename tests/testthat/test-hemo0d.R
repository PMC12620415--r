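test_that("inflow waveform has the analytic peak and exact mean", {
  wf <- make_inflow(5, 60, systolic_fraction = 0.35)
  co_cgs <- 5 * 16.6667
  q_peak_analytic <- co_cgs * pi * 1 / (2 * 0.35)
  expect_equal(max(wf$flow_cm3_s), q_peak_analytic, tolerance = 1e-3)
  expect_equal(mean(wf$flow_cm3_s), co_cgs, tolerance = 1e-9)
  # long-systole limit: peak approaches CO * pi / 2
  wf2 <- make_inflow(5, 60, systolic_fraction = 0.999, n_samples = 20000)
  expect_equal(max(wf2$flow_cm3_s), co_cgs * pi / 2, tolerance = 5e-3)
  expect_error(make_inflow(5, 60, systolic_fraction = 1.2), "systolic_fraction")
})

test_that("segment resistance follows Poiseuille's law", {
  b <- blood_model() # 0.0035 Pa.s = 0.035 poise
  expect_equal(segment_resistance(b, length = 5, diameter = 2), 1.4 / pi, tolerance = 1e-12)
  r1 <- segment_resistance(b, 5, 1)
  expect_equal(segment_resistance(b, 5, 2), r1 / 16, tolerance = 1e-12)
  expect_equal(segment_resistance(b, 0, 2), 0)
})

test_that("steady solve reproduces the DC Windkessel pressure exactly", {
  tree <- single_segment_tree(length_cm = 1e-4, diameter_cm = 2)
  rcr <- assemble_rcr(100, 1e-4, "s1", rp_fraction = 0.1, distal_pressure = 10)
  Q <- 83.333
  sol <- solve_hemodynamics(tree, rcr, constant_inflow(Q), max_cycles = 40)
  expect_true(sol$converged)
  expect_gte(sol$cycles_run, 6)
  expected <- Q * (100 + segment_resistance(blood_model(), 1e-4, 2)) + 10 * 1333.22
  expect_equal(mean(sol$pressure["s1", ]), expected, tolerance = 1e-6)
})

test_that("symmetric outlets carry identical flows at every time point", {
  tree <- generate_tree(2.5, n_generations = 1, asymmetry = 0)
  leaf <- outlets(tree)
  rcr <- assemble_rcr(
    distribute_resistance(leaf$diameter_cm, 160),
    distribute_compliance(leaf$diameter_cm, 3e-3),
    outlet_ids = leaf$id, distal_pressure = 10
  )
  sol <- solve_hemodynamics(tree, rcr, make_inflow(5.2, 75))
  expect_equal(sol$flow[leaf$id[1], ], sol$flow[leaf$id[2], ], tolerance = 1e-10)
})

test_that("sinusoidal drive matches the analytic Windkessel impedance", {
  tree <- single_segment_tree(length_cm = 1e-6, diameter_cm = 2)
  Rp <- 10
  Rd <- 90
  C <- 1e-3
  rcr <- assemble_rcr(100, C, "s1", rp_fraction = 0.1, distal_pressure = 0)
  w <- 2 * pi # period 1 s
  sol <- solve_hemodynamics(tree, rcr, sinusoidal_inflow(80, 20),
    max_cycles = 60, periodicity_tol = 1e-6
  )
  amp <- (max(sol$pressure["s1", ]) - min(sol$pressure["s1", ])) / 2
  Z <- Mod(Rp + Rd / complex(real = 1, imaginary = w * Rd * C))
  expect_lt(abs(amp - 20 * Z) / (20 * Z), 0.01)
})

test_that("cycle-mean flow is conserved at periodic convergence", {
  tree <- generate_tree(3, n_generations = 3, asymmetry = 0.3, seed = 2)
  leaf <- outlets(tree)
  rcr <- assemble_rcr(
    distribute_resistance(leaf$diameter_cm, 160),
    distribute_compliance(leaf$diameter_cm, 3e-3),
    outlet_ids = leaf$id, distal_pressure = 10
  )
  inflow <- make_inflow(5.2, 75)
  sol <- solve_hemodynamics(tree, rcr, inflow, periodicity_tol = 1e-4, max_cycles = 40)
  expect_true(sol$converged)
  q_in <- mean(sol$flow[tree$id[is.na(tree$parent_id)], ])
  q_out <- sum(rowMeans(sol$flow[leaf$id, ]))
  expect_lt(abs(q_out - q_in) / q_in, 0.005)
})

test_that("halving the time step barely changes the mean pressure", {
  tree <- generate_tree(2.5, n_generations = 2, seed = 4)
  leaf <- outlets(tree)
  rcr <- assemble_rcr(
    distribute_resistance(leaf$diameter_cm, 140),
    distribute_compliance(leaf$diameter_cm, 2.5e-3),
    outlet_ids = leaf$id, distal_pressure = 9
  )
  inflow <- make_inflow(5.2, 75)
  m1 <- summarize_pressures(solve_hemodynamics(tree, rcr, inflow, dt = 1e-3))$mPAP
  m2 <- summarize_pressures(solve_hemodynamics(tree, rcr, inflow, dt = 5e-4))$mPAP
  expect_lt(abs(m2 - m1) / m1, 0.002)
})

test_that("scaling all resistances scales the transpulmonary gradient", {
  tree <- generate_tree(2.5, n_generations = 2, seed = 6)
  leaf <- outlets(tree)
  inflow <- make_inflow(5.2, 75)
  pd <- 10
  grad <- sapply(c(1, 2.5), function(k) {
    # scale segment resistances via viscosity and outlet resistances directly
    blood <- blood_model(viscosity = 0.0035 * k)
    rcr <- assemble_rcr(
      distribute_resistance(leaf$diameter_cm, 160 * k),
      distribute_compliance(leaf$diameter_cm, 3e-3),
      outlet_ids = leaf$id, distal_pressure = pd
    )
    sol <- solve_hemodynamics(tree, rcr, inflow, blood = blood, periodicity_tol = 1e-5, max_cycles = 40)
    summarize_pressures(sol)$mPAP - pd
  })
  expect_equal(grad[2] / grad[1], 2.5, tolerance = 0.005)
})

test_that("pressure summary obeys dPAP <= mPAP <= sPAP and the trapezoid mean", {
  tree <- generate_tree(2.4, n_generations = 2, seed = 9)
  leaf <- outlets(tree)
  rcr <- assemble_rcr(
    distribute_resistance(leaf$diameter_cm, 150),
    distribute_compliance(leaf$diameter_cm, 2e-3),
    outlet_ids = leaf$id, distal_pressure = 9
  )
  sol <- solve_hemodynamics(tree, rcr, make_inflow(5, 70))
  s <- summarize_pressures(sol)
  expect_lte(s$dPAP, s$mPAP)
  expect_lte(s$mPAP, s$sPAP)
  root <- tree$id[is.na(tree$parent_id)]
  expect_equal(s$mPAP, mean(sol$pressure[root, ]) / 1333.22, tolerance = 1e-12)
  # distal pressure lower-bounds the capacitor pressures for positive inflow
  expect_true(all(sol$capacitor_pressure >= 9 * 1333.22 - 1e-6))
})

test_that("solution exports round-trip through the long-format table", {
  tree <- generate_tree(2.4, n_generations = 1, seed = 2)
  leaf <- outlets(tree)
  rcr <- assemble_rcr(
    distribute_resistance(leaf$diameter_cm, 150),
    distribute_compliance(leaf$diameter_cm, 2e-3),
    outlet_ids = leaf$id, distal_pressure = 9
  )
  sol <- solve_hemodynamics(tree, rcr, make_inflow(5, 75))
  long <- tidy(sol)
  expect_equal(nrow(long), length(sol$times) * length(sol$segment_ids))
  path <- withr::local_tempfile(fileext = ".csv")
  export_solution(sol, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# cycles_run", lines)))
  back <- readr::read_csv(I(lines[!grepl("^#", lines)]), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(long))
})
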