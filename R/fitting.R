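#' Template of a barrier-laminate migration experiment
#'
#' Describes a three-layer wall (contact material / barrier / contact
#' material) desorbing into a well-mixed liquid, with the barrier's Henry
#' coefficient unknown.  For a candidate partition ratio
#' `r = K_barrier/contact = k_contact / k_barrier`, the two Henry
#' coefficients are reconstructed from the measured apparent partition
#' coefficient between liquid and whole wall via the effective-Henry
#' relation `1/k_eff = sum(phi_j / k_j)`, and the fixed total amount is
#' redistributed at uniform activity before simulation.
#'
#' @param thickness length-3 vector of layer thicknesses, m (contact,
#'   barrier, contact).
#' @param D_contact diffusivity of the contact material, m^2 s^-1.
#' @param D_barrier diffusivity of the barrier; defaults to
#'   `D_contact / 30`, the conventional dry-barrier estimate.
#' @param k_fluid Henry coefficient of the liquid (activity reference).
#' @param apparent_partition measured apparent partition coefficient
#'   `K_F/P` between liquid and whole wall.
#' @param mean_concentration initial wall-average concentration, kg m^-3.
#' @param fluid_thickness equivalent liquid thickness l0 = V/A, m.
#' @param Bi mass Biot number of the liquid contact.
#' @return object of class `migration_template`.
#' @export
migration_template <- function(thickness, D_contact,
                               D_barrier = D_contact / 30,
                               k_fluid = 1, apparent_partition,
                               mean_concentration, fluid_thickness,
                               Bi = 1000) {
  stopifnot(length(thickness) == 3L, all(thickness > 0), D_contact > 0,
            D_barrier > 0, k_fluid > 0, apparent_partition > 0,
            mean_concentration >= 0, fluid_thickness > 0, Bi > 0)
  structure(list(thickness = thickness, D_contact = D_contact,
                 D_barrier = D_barrier, k_fluid = k_fluid,
                 apparent_partition = apparent_partition,
                 mean_concentration = mean_concentration,
                 fluid_thickness = fluid_thickness, Bi = Bi),
            class = "migration_template")
}

#' Instantiate a template at a candidate partition ratio
#'
#' @param template a [migration_template()].
#' @param ratio candidate `K_barrier/contact = k_contact / k_barrier` (> 0).
#' @param duration migration duration, s.
#' @return a one-step [scenario()] whose initial amount equals
#'   `mean_concentration * sum(thickness)` for every ratio.
#' @export
template_scenario <- function(template, ratio, duration) {
  stopifnot(inherits(template, "migration_template"), ratio > 0)
  l <- template$thickness
  phi <- l / sum(l)
  k_eff <- template$apparent_partition * template$k_fluid
  k_c <- k_eff * ((phi[1] + phi[3]) + ratio * phi[2])
  k_b <- k_c / ratio
  layers <- list(
    layer_spec("contact", l[1], henry_k = k_c, D = template$D_contact),
    layer_spec("barrier", l[2], henry_k = k_b, D = template$D_barrier),
    layer_spec("contact", l[3], henry_k = k_c, D = template$D_contact))
  asm <- assembly(layers,
                  fluid = fluid_compartment(template$fluid_thickness,
                                            henry_k = template$k_fluid,
                                            Bi = template$Bi))
  asm <- distribute_equilibrium_initial(asm,
                                        template$mean_concentration * sum(l))
  scenario(step_spec(duration, asm), name = sprintf("template_r%.4g", ratio))
}

#' Synthetic desorption kinetics from a scenario
#'
#' Runs the scenario and samples the fraction released into the fluid at
#' the given times, optionally perturbed by multiplicative Gaussian noise
#' (a fixed seed makes the draw reproducible; the global RNG state is
#' restored).
#'
#' @param sc a [scenario()] ending in a fluid-contacted step.
#' @param times sampling times, s.
#' @param noise multiplicative noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @param grid a [grid_spec()].
#' @return data frame with columns `time` (s) and `fraction` released.
#' @export
generate_synthetic_kinetics <- function(sc, times, noise = 0, seed = NULL,
                                        grid = grid_spec()) {
  stopifnot(inherits(sc, "scenario"), all(times > 0), noise >= 0)
  res <- run_scenario(sc, grid,
                      times = c(rep(list(NULL), length(sc$steps) - 1L),
                                list(sort(times))))
  kin <- res$steps[[length(res$steps)]]$kinetics
  frac <- approx(kin$times, kin$amounts[, "F"], xout = times)$y
  if (noise > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
      }
      set.seed(seed)
    }
    frac <- frac * (1 + noise * rnorm(length(frac)))
  }
  data.frame(time = times, fraction = frac)
}

#' Identify an unknown barrier partition ratio from desorption kinetics
#'
#' For each candidate ratio the initial distribution in the wall is rebuilt
#' at uniform activity under that ratio (total amount and apparent
#' partitioning held fixed), the desorption is simulated and scored by the
#' sum of squared residuals on the fraction released.  The returned
#' objective-vs-ratio profile is typically non-monotone: too low a ratio
#' concentrates the migrant in the contact layers (too fast), too high a
#' ratio defers it behind the barrier (too slow).  A golden-section local
#' refinement (on the log-ratio scale) sharpens the best grid point.
#'
#' @param kinetics data frame with columns `time` (s) and `fraction`
#'   released; at least 4 points.
#' @param template a [migration_template()].
#' @param ratios candidate ratio grid (strictly positive).
#' @param refine logical: refine around the best grid point.
#' @param grid a [grid_spec()].
#' @return object of class `partition_fit`: list with the best `ratio`, the
#'   `objective` data frame (ratio, sse) and the refined optimum.
#' @export
identify_partition_ratio <- function(kinetics, template, ratios,
                                     refine = TRUE, grid = grid_spec()) {
  stopifnot(is.data.frame(kinetics),
            all(c("time", "fraction") %in% names(kinetics)))
  if (nrow(kinetics) < 4L)
    stop("at least 4 kinetic points are required")
  if (any(ratios <= 0)) stop("candidate ratios must be strictly positive")
  ratios <- sort(ratios)
  duration <- max(kinetics$time)
  sse <- function(r) {
    sc <- template_scenario(template, r, duration)
    pred <- generate_synthetic_kinetics(sc, kinetics$time, noise = 0,
                                        grid = grid)
    sum((pred$fraction - kinetics$fraction)^2)
  }
  obj <- vapply(ratios, sse, numeric(1))
  best <- which.min(obj)
  out <- list(objective = data.frame(ratio = ratios, sse = obj),
              grid_best = ratios[best])
  if (refine && length(ratios) >= 2L) {
    lo <- if (best > 1L) ratios[best - 1L] else ratios[1L] * 0.5
    hi <- if (best < length(ratios)) ratios[best + 1L] else
      ratios[length(ratios)] * 2
    opt <- optimize(function(lr) sse(exp(lr)), lower = log(lo),
                    upper = log(hi), tol = 1e-3)
    out$ratio <- exp(opt$minimum)
    out$sse <- opt$objective
  } else {
    out$ratio <- ratios[best]
    out$sse <- obj[best]
  }
  structure(out, class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("partition_fit: ratio = %.4g (grid best %.4g), SSE = %.4g\n",
              x$ratio, x$grid_best, x$sse))
  invisible(x)
}
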