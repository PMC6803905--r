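## Independent oracles used across the suite.

## Crank plane-sheet desorption series (impervious back, surface activity
## clamped by a large well-stirred bath): fraction released vs Fourier number
crank_fraction <- function(Fo, nterms = 50) {
  j <- 0:(nterms - 1)
  vapply(Fo, function(f)
    1 - sum(8 / ((2 * j + 1)^2 * pi^2) *
              exp(-(2 * j + 1)^2 * pi^2 * f / 4)), numeric(1))
}

## dimensionless plane sheet with a large fluid reservoir
plane_sheet_assembly <- function(Bi = 1000, fluid_capacity = 1e4) {
  assembly(list(layer_spec("P", 1, henry_k = 1, D = 1, C0 = 1)),
           fluid = fluid_compartment(fluid_capacity, henry_k = 1, Bi = Bi))
}

## classical closed-form equilibrium amounts (fractions of the total),
## written exactly as the two- and three-layer specializations
eq_bilayer_step1 <- function(l1, l2, k1, k2) {
  c(layer2 = 1 / (1 + l1 * k2 / (l2 * k1)),   # residual in the far layer
    layer1 = 1 / (1 + l2 * k1 / (l1 * k2)))   # complementary, contact layer
}
eq_bilayer_fluid <- function(l1, l2, l0, k1, k2, k0) {
  c(layer2 = 1 / (1 + l1 * k2 / (l2 * k1) + l0 * k2 / (l2 * k0)),
    layer1 = 1 / (1 + l2 * k1 / (l1 * k2) + l0 * k1 / (l1 * k0)),
    fluid  = 1 / (1 + l1 * k0 / (l0 * k1) + l2 * k0 / (l0 * k2)))
}
eq_trilayer_step1 <- function(l1, l2, l3, k1, k2, k3) {
  c(layer3 = 1 / (1 + l1 * k3 / (l3 * k1) + l2 * k3 / (l3 * k2)),
    layer1 = 1 / (1 + l3 * k1 / (l1 * k3) + l2 * k1 / (l1 * k2)))
}
eq_trilayer_then_fluid <- function(l1, l2, l3, l0, k1, k2, k3, k0) {
  inB <- 1 / (1 + (k1 / l1) * (l2 / k2 + l3 / k3))
  split <- 1 / (1 + l1 * k0 / (l0 * k1))
  c(layer1 = inB * (1 - split), fluid = inB * split)
}

## fitting template shared by the parameter-recovery tests: T2 wall geometry
## with a synthetic mid-volatility additive whose desorption and barrier
## regimes both fall inside a 120-day observation window
recovery_template <- function() {
  migration_template(thickness = 0.4e-3 * c(10.2, 1, 4.8) / 16,
                     D_contact = 1.25e-13, apparent_partition = 0.5,
                     mean_concentration = 0.3, fluid_thickness = 3.5e-3)
}
recovery_grid <- function() grid_spec(nodes = 60, min_nodes = 6)
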