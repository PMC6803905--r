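test_that("a one-step scenario is identical to solve_step", {
  a <- assembly(list(layer_spec("B", 1, 1, 1, C0 = 1),
                     layer_spec("A", 0.5, 2, 0.5)))
  tt <- c(0.1, 1, 10)
  res <- run_scenario(scenario(step_spec(10, a)), times = list(tt))
  ref <- solve_step(a, 10, times = tt)
  expect_equal(res$steps[[1]]$kinetics$amounts, ref$kinetics$amounts)
})

test_that("mass bookkeeping across layer removal is exact", {
  sc <- fixture("S2", substance = "sA", duration = 2e4)
  res <- run_scenario(sc)
  ## the transformation itself loses nothing: amount before = after + removed
  kin1 <- res$steps[[1]]$kinetics
  end1 <- sum(kin1$amounts[nrow(kin1$amounts), ])
  start2 <- sum(res$steps[[2]]$kinetics$amounts[1, ])
  expect_lt(abs(end1 - (start2 + res$removed[2])), 1e-10)
  ## removed amount equals the step-1 holdings of the discarded layers
  expect_equal(res$removed[2],
               unname(sum(kin1$amounts[nrow(kin1$amounts), c("2", "3")])),
               tolerance = 1e-9)
  ## whole-trajectory closure within integrator tolerances
  tot <- rowSums(res$steps[[2]]$kinetics$amounts) + res$removed[2]
  expect_lt(max(abs(tot - 1)), 1e-7)
})

test_that("two-step chains converge to the trilayer-then-fluid equilibria", {
  for (sub in c("sA", "sB")) {
    res <- run_scenario(fixture("S2", substance = sub, duration = 2e4))
    last <- res$steps[[2]]$kinetics$amounts
    last <- last[nrow(last), ]
    kair <- if (sub == "sB") 1e8 else 1e4
    kA <- if (sub == "sB") 2 else 0.5
    kF <- kA
    o <- eq_trilayer_then_fluid(1, 1, 0.5, 10, 1, kair, kA, kF)
    expect_equal(unname(last["1"]), unname(o["layer1"]), tolerance = 1e-3)
    expect_equal(unname(last["F"]), unname(o["fluid"]), tolerance = 1e-3)
  }
})

test_that("equilibrating a subset yields uniform activity and then a quiescent start", {
  a <- assembly(list(layer_spec("B", 1, 1, 1, C0 = 1),
                     layer_spec("A", 0.5, 2, 0.5, C0 = 0.2)))
  sc <- scenario(list(step_spec(5, a),
                      step_spec(100, a, transform = "equilibrate")))
  res <- run_scenario(sc)
  ## after the equilibrate transform the system starts at its equilibrium:
  ## subsequent kinetics are flat
  kin2 <- res$steps[[2]]$kinetics$amounts
  expect_lt(max(abs(sweep(kin2, 2, kin2[1, ]))), 1e-7)
  eqf <- equilibrium_distribution(a)$table$fraction
  expect_equal(unname(kin2[1, ]), eqf, tolerance = 1e-9)
})

test_that("equilibration-terminated steps commute when partition coefficients are constant", {
  a <- assembly(list(layer_spec("B", 1, 1, 1, C0 = 1),
                     layer_spec("A", 0.5, 2, 0.5)))
  ## two steps with different durations, each long enough to equilibrate
  ord1 <- run_scenario(scenario(list(step_spec(40, a), step_spec(70, a))))
  ord2 <- run_scenario(scenario(list(step_spec(70, a), step_spec(40, a))))
  f1 <- ord1$steps[[2]]$final_mesh$C
  f2 <- ord2$steps[[2]]$final_mesh$C
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("equilibrium seeding distributes the amount by chemical affinity", {
  ## PE/PA6/PE overpackaging with K_PA6/LDPE = 6.05: the two PE layers
  ## (3.6x the PA6 thickness in total) hold ~37% of the amount
  K <- polymer_partition(-1.04, 0.76)
  lay <- list(layer_spec("PE", 2.3, henry_k = K, D = 1),
              layer_spec("PA6", 1, henry_k = 1, D = 1),
              layer_spec("PE", 1.3, henry_k = K, D = 1))
  a <- distribute_equilibrium_initial(assembly(lay), total_amount = 1)
  df <- as.data.frame(a)
  amt <- df$thickness * df$C0
  expect_equal(sum(amt), 1, tolerance = 1e-12)
  expect_equal(sum(amt[c(1, 3)]), 3.6 / (3.6 + K), tolerance = 1e-9)
  ## activity uniform across the subset
  act <- df$henry_k * df$C0
  expect_lt(diff(range(act)) / mean(act), 1e-12)
  ## single-layer subset: everything in that layer
  b <- distribute_equilibrium_initial(assembly(lay), 2, layers = 2)
  expect_equal(as.data.frame(b)$C0, c(0, 2, 0))
})

test_that("air gaps delay loading without changing the equilibrium amounts", {
  eqf <- teq <- numeric(0)
  for (g in c(0, 1e-2, 5e-2)) {
    sc <- fixture("T1_caprolactam", air_gap = g)
    a <- sc$steps[[1]]$assembly
    eqt <- equilibrium_distribution(a)$table
    eqf <- c(eqf, sum(eqt$fraction[eqt$compartment %in% c("1", "2", "3")]))
    sol <- solve_step(a, 1e9,
                      times = exp(seq(log(1e3), log(1e9), length.out = 80)))
    teq <- c(teq, equilibration_time(sol, c("1", "2", "3"), theta = 0.5))
  }
  expect_lt(max(eqf) / min(eqf) - 1, 0.005)
  expect_true(all(diff(teq) > 0))
})

test_that("scenario results are reported against a preserved normalisation base", {
  sc <- loading_migration_scenario("T1", "caprolactam", air_gap = 1e-2,
                                   t1 = 86400, t2 = 86400)
  res <- run_scenario(sc)
  expect_equal(res$norm_base,
               total_initial_amount(sc$steps[[1]]$assembly))
  ## step-2 fractions + removed amount close the balance
  last <- res$steps[[2]]$kinetics$amounts
  expect_equal(unname(rowSums(last)[nrow(last)] + res$removed[2]), 1,
               tolerance = 1e-8)
})
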