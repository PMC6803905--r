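test_that("Henry coefficients follow the linearised Flory isotherm", {
  ## chi = -1 cancels the exponent
  expect_equal(henry_coefficient(-1, 2.5, 1e-4), 2.5e-4)
  ## direct evaluations
  expect_equal(henry_coefficient(-0.19, 0.483, 1.06e-4),
               0.483 * 1.06e-4 * exp(0.81))
  expect_equal(henry_air(313.15), 8.31446261815324 * 313.15)
  expect_equal(henry_air(313.15), 2603.5, tolerance = 1e-4)
  expect_error(henry_coefficient(0, -1, 1), "p_sat")
})

test_that("polymer-polymer partition coefficients match the closed form", {
  expect_equal(round(polymer_partition(-1.19, 0.76), 2), 7.03)
  expect_equal(round(polymer_partition(-1.04, 0.76), 2), 6.05)
  expect_equal(polymer_partition(0.3, 0.3), 1)
  ## reciprocity
  for (i in 1:10) {
    ch <- runif(2, -2, 2)
    expect_equal(polymer_partition(ch[1], ch[2]) *
                   polymer_partition(ch[2], ch[1]), 1)
  }
})

test_that("uniform-activity equilibrium reproduces the two- and three-layer formulas", {
  set.seed(11)
  for (i in 1:20) {
    l <- runif(4, 0.1, 10)   # l1, l2, l3, l0
    k <- runif(4, 0.1, 10)   # k1, k2, k3, k0
    ## bilayer, closed
    a2 <- assembly(list(layer_spec("B", l[1], k[1], 1, C0 = runif(1)),
                        layer_spec("A", l[2], k[2], 1, C0 = runif(1))))
    eq <- equilibrium_distribution(a2)
    o <- eq_bilayer_step1(l[1], l[2], k[1], k[2])
    expect_equal(eq$table$fraction, unname(o[c("layer1", "layer2")]))
    ## bilayer + fluid
    a2f <- assembly(list(layer_spec("B", l[1], k[1], 1, C0 = 1),
                         layer_spec("A", l[2], k[2], 1, C0 = 0.3)),
                    fluid = fluid_compartment(l[4], k[4], Bi = 1000))
    eqf <- equilibrium_distribution(a2f)
    of <- eq_bilayer_fluid(l[1], l[2], l[4], k[1], k[2], k[4])
    expect_equal(eqf$table$fraction,
                 unname(of[c("fluid", "layer1", "layer2")]))
    ## trilayer, closed
    a3 <- assembly(list(layer_spec("B", l[1], k[1], 1, C0 = 1),
                        layer_spec("air", l[2], k[2], 1),
                        layer_spec("A", l[3], k[3], 1, C0 = 2)))
    eq3 <- equilibrium_distribution(a3)
    o3 <- eq_trilayer_step1(l[1], l[2], l[3], k[1], k[2], k[3])
    expect_equal(eq3$table$fraction[c(3, 1)],
                 unname(o3[c("layer3", "layer1")]))
    ## activity is uniform
    act <- eq3$table$henry_k * eq3$table$concentration
    expect_lt(diff(range(act)) / mean(act), 1e-12)
  }
})

test_that("the density-weighted general fluid equilibrium agrees with the capacity form", {
  ## the general expression in mass-fraction units with rho ratios reduces to
  ## the volumic capacity split used by equilibrium_distribution
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    l <- runif(n, 0.1, 5); k <- runif(n, 0.2, 5); Cv <- runif(n, 0, 3)
    rho <- runif(n, 500, 1500); l0 <- runif(1, 1, 20); k0 <- runif(1, 0.2, 5)
    rho0 <- runif(1, 700, 1100)
    layers <- lapply(seq_len(n), function(j)
      layer_spec(paste0("L", j), l[j], k[j], 1, C0 = Cv[j],
                 density = rho[j]))
    a <- assembly(layers, fluid = fluid_compartment(l0, k0, Bi = 1000,
                                                    density = rho0))
    C0_pkg <- equilibrium_distribution(a)$table$concentration[1]
    ## mass-fraction form: w = C/rho, mass-fraction Henry k' = k*rho
    w <- Cv / rho
    kp <- k * rho; kp0 <- k0 * rho0
    w0 <- sum((rho / rho0) * (l / l0) * w) /
      (1 + sum((kp0 / kp) * (rho / rho0) * (l / l0)))
    expect_equal(C0_pkg, w0 * rho0)
  }
})

test_that("apparent fluid/material partitioning equals k_eff / k_0", {
  a <- assembly(list(layer_spec("P", 1, henry_k = 0.5, D = 1, C0 = 1)),
                fluid = fluid_compartment(10, henry_k = 0.5, Bi = 1000))
  expect_equal(apparent_partition(equilibrium_distribution(a)), 1)
  l <- c(2, 1); k <- c(0.4, 1.7); k0 <- 0.9
  a2 <- assembly(list(layer_spec("P1", l[1], k[1], 1, C0 = 1),
                      layer_spec("P2", l[2], k[2], 1)),
                 fluid = fluid_compartment(5, k0, Bi = 1000))
  k_eff <- effective_henry(l / sum(l), k)
  expect_equal(apparent_partition(equilibrium_distribution(a2)), k_eff / k0)
})

test_that("effective Henry coefficient is the volume-weighted harmonic mean", {
  expect_equal(effective_henry(c(0.5, 0.5), c(1, 3)), 1.5)
  expect_equal(effective_henry(c(0.3, 0.7), c(2, 2)), 2)
  ## inverse mode round-trips the forward computation
  phi <- c(0.2, 0.5, 0.3); k <- c(0.4, 1.2, 3.3)
  ke <- effective_henry(phi, k)
  k_part <- k; k_part[2] <- NA
  expect_equal(effective_henry(phi, k_part, k_eff = ke), k)
  expect_error(effective_henry(phi, c(NA, NA, 1), k_eff = ke),
               "over-determined")
  expect_error(effective_henry(c(0.5, 0.6), c(1, 1)), "sum to 1")
})

test_that("Fuller gas diffusivity scales as T^1.75 / P and hits the caprolactam value", {
  sv <- fuller_diffusion_volume(c(C = 6, H = 11, N = 1, O = 1), rings = 1)
  D1 <- fuller_gas_diffusivity(113.16, sv, 313, 101325)
  expect_equal(fuller_gas_diffusivity(113.16, sv, 313, 2 * 101325), D1 / 2)
  expect_equal(fuller_gas_diffusivity(113.16, sv, 626, 101325) / D1, 2^1.75)
  expect_equal(D1, 8.12e-6, tolerance = 0.15)
  expect_error(fuller_diffusion_volume(c(Xx = 1)), "no Fuller increment")
})

test_that("layer resistances relative to a 0.1 mm air gap reproduce the printed integers", {
  rr1 <- resistance_ratios(fixture("T1_caprolactam")$steps[[1]]$assembly)
  expect_equal(rr1$rounded[rr1$material == "air"], 1)
  expect_equal(rr1$rounded[1:5], c(50, 46, 6, 1, 7))
  expect_equal(rr1$rounded[7], 4)
  rr2 <- resistance_ratios(fixture("T2_caprolactam")$steps[[1]]$assembly)
  expect_equal(rr2$rounded[1:5], c(47, 229, 22, 1, 7))
  ## no air layer: the reference must be supplied
  a <- assembly(list(layer_spec("P", 1e-4, 1, 1e-13)))
  expect_error(resistance_ratios(a), "supply ref_D")
  expect_equal(resistance_ratios(a, ref_D = 8.12e-6,
                                 ref_k = henry_air(313.15))$relative,
               (1e-4 * 1 / 1e-13) / (1e-4 * henry_air(313.15) / 8.12e-6))
})
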