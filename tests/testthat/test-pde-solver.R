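test_that("null input stays null and closed systems conserve mass", {
  a <- assembly(list(layer_spec("B", 1, 1, 1, C0 = 0),
                     layer_spec("A", 0.5, 2, 0.5, C0 = 0)))
  sol <- solve_step(a, 10, times = c(1, 10))
  expect_true(all(sol$conc == 0))
  sc <- fixture("S1", substance = "sB")
  sol1 <- solve_step(sc$steps[[1]]$assembly, 100)   # Fo = 100 in layer 1
  expect_lt(mass_balance(sol1), 1e-6)
})

test_that("single-layer desorption matches the plane-sheet series within 1%", {
  sol <- solve_step(plane_sheet_assembly(), 1, times = c(0.01, 0.1, 1))
  got <- sol$kinetics$amounts[-1, "F"]
  expect_equal(unname(got), crank_fraction(c(0.01, 0.1, 1)), tolerance = 0.011)
})

test_that("doubling the mesh changes the fluid kinetics by less than 0.5%", {
  tt <- c(0.01, 0.1, 1)
  f1 <- solve_step(plane_sheet_assembly(), 1, grid_spec(nodes = 120),
                   times = tt)$kinetics$amounts[-1, "F"]
  f2 <- solve_step(plane_sheet_assembly(), 1, grid_spec(nodes = 240),
                   times = tt)$kinetics$amounts[-1, "F"]
  expect_lt(max(abs(f2 / f1 - 1)), 0.005)
})

test_that("early fluid uptake grows as the square root of time", {
  tt <- exp(seq(log(1e-4), log(1e-2), length.out = 15))
  sol <- solve_step(plane_sheet_assembly(), 1e-2, times = tt)
  slope <- coef(lm(log(sol$kinetics$amounts[-1, "F"]) ~ log(tt)))[[2]]
  expect_equal(slope, 0.5, tolerance = 0.04)  # 0.5 +/- 0.02 absolute
  expect_lt(abs(slope - 0.5), 0.02)
})

test_that("steady-state interface concentrations jump by the Henry ratio", {
  a <- assembly(list(layer_spec("B", 1, henry_k = 1, D = 1, C0 = 1),
                     layer_spec("A", 0.6, henry_k = 3.7, D = 0.4)))
  sol <- solve_step(a, 500, times = c(1, 500))
  prof <- profile_at(sol, 500)
  C1 <- prof$C[prof$layer == 1]; C2 <- prof$C[prof$layer == 2]
  expect_equal(tail(C1, 1) / head(C2, 1), 3.7 / 1, tolerance = 1e-6)
  ## transient activity is monotone across the interface
  mid <- profile_at(sol, 1)
  k <- ifelse(mid$layer == 1, 1, 3.7)
  expect_true(all(diff(mid$C * k) < 1e-12))
})

test_that("independently simulated sources superpose linearly", {
  g <- grid_spec(rtol = 1e-11, atol_rel = 1e-15)
  mk <- function(cB, cA) assembly(list(
    layer_spec("B", 1, henry_k = 1, D = 1, C0 = cB),
    layer_spec("A", 0.5, henry_k = 2, D = 0.5, C0 = cA)),
    fluid = fluid_compartment(10, henry_k = 2, Bi = 1000))
  tt <- c(0.1, 1, 10, 100)
  joint <- solve_step(mk(1, 0.7), 100, g, times = tt)$kinetics
  kB <- solve_step(mk(1, 0), 100, g, times = tt)$kinetics
  kA <- solve_step(mk(0, 0.7), 100, g, times = tt)$kinetics
  sup <- superpose(kB, kA)
  expect_lt(max(abs(sup$amounts - joint$amounts)), 1e-8)
  ## scaling the source scales the kinetics (homogeneity)
  k2 <- solve_step(mk(2, 0), 100, g, times = tt)$kinetics
  expect_equal(k2$amounts * k2$norm_base, 2 * kB$amounts * kB$norm_base,
               tolerance = 1e-9)
  ## mismatches are rejected
  expect_error(superpose(kB, solve_step(mk(1, 0), 100, g,
                                        times = c(1, 100))$kinetics),
               "time grids")
})

test_that("the set-off (periodic) condition doubles the early contact-face uptake", {
  ab <- list(layer_spec("A", 1, henry_k = 1, D = 1, C0 = 1),
             layer_spec("B", 1, henry_k = 1, D = 1, C0 = 0))
  p <- solve_step(assembly(ab, boundary = "periodic"), 0.5,
                  times = c(0.05, 0.5))
  i <- solve_step(assembly(ab, boundary = "impervious"), 0.5,
                  times = c(0.05, 0.5))
  expect_equal(unname(p$kinetics$amounts[2, "2"] /
                        i$kinetics$amounts[2, "2"]), 2, tolerance = 0.01)
  expect_lt(mass_balance(p), 1e-6)
})

test_that("the quasi-steady gas-gap rate matches the transient solver at short times", {
  sc <- fixture("S2", substance = "sB")
  a1 <- sc$steps[[1]]$assembly
  rate <- short_time_rate(a1$layers[[1]], a1$layers[[2]])
  tt <- c(3e-4, 1e-3)
  sol <- solve_step(a1, max(tt), times = tt)
  lost <- 1 - sol$kinetics$amounts[-1, "1"]
  expect_equal(unname(lost), rate$fraction_lost(tt), tolerance = 0.1)
  ## rate is linear in the source Henry coefficient and zero for p_sat = 0
  r2 <- short_time_rate(layer_spec("B", 1, henry_k = 2, D = 1),
                        a1$layers[[2]])
  expect_equal(r2$rate, 2 * rate$rate)
  k0 <- henry_coefficient(chi = 0.5, p_sat = 0, molar_volume = 1e-4)
  expect_equal(k0, 0)
})

test_that("a severe concentration undershoot aborts the run", {
  expect_error(kinetics_result(1:3, matrix(0, 2, 1), 1), "length")
  ## healthy runs stay non-negative
  sol <- solve_step(plane_sheet_assembly(), 1, times = c(0.01, 1))
  expect_true(all(sol$conc >= 0))
})

test_that("equilibration time is monotone in the target fraction", {
  a <- fixture("T1_caprolactam")$steps[[1]]$assembly
  tt <- exp(seq(log(1e3), log(1e9), length.out = 100))
  sol <- solve_step(a, 1e9, times = tt)
  t50 <- equilibration_time(sol, c("1", "2", "3"), theta = 0.5)
  t90 <- equilibration_time(sol, c("1", "2", "3"), theta = 0.9)
  t95 <- equilibration_time(sol, c("1", "2", "3"), theta = 0.95)
  expect_true(t50 < t90 && t90 < t95)
})
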