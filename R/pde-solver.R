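#' Discretisation and solver settings
#'
#' Controls the cell-centred finite-volume mesh and the stiff time
#' integrator.  Nodes are shared between layers proportionally to
#' `l_j / sqrt(D_j)` (layers that equilibrate slowly get more cells) with a
#' per-layer minimum, and cell widths are graded geometrically towards both
#' faces of every layer so that early square-root-of-time boundary layers
#' are resolved.
#'
#' @param nodes target total number of cells over all layers.
#' @param min_nodes minimum number of cells per layer (>= 3).
#' @param grading geometric growth ratio of cell widths away from layer
#'   faces (1 = uniform).
#' @param n_times number of output times (geometric schedule) when none are
#'   requested explicitly.
#' @param rtol,atol_rel relative tolerance and relative floor of the absolute
#'   tolerance (scaled by the peak initial concentration) passed to the BDF
#'   integrator.
#' @param neg_tol largest tolerated concentration undershoot, as a fraction
#'   of the peak initial concentration; worse undershoot aborts the run.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(nodes = 120L, min_nodes = 8L, grading = 1.2,
                      n_times = 80L, rtol = 1e-8, atol_rel = 1e-13,
                      neg_tol = 1e-10) {
  stopifnot(nodes >= 3, min_nodes >= 3, grading >= 1, n_times >= 2,
            rtol > 0, atol_rel > 0, neg_tol > 0)
  structure(list(nodes = as.integer(nodes), min_nodes = as.integer(min_nodes),
                 grading = grading, n_times = as.integer(n_times),
                 rtol = rtol, atol_rel = atol_rel, neg_tol = neg_tol),
            class = "grid_spec")
}

## symmetric geometric grading: finest cells at both faces.  The growth is
## capped at a 64:1 width ratio so that refinement adds interior resolution
## instead of shrinking the face cells without bound (which would make the
## semi-discrete system needlessly stiff).
graded_widths <- function(l, n, r, cap = 64) {
  if (n == 1L) return(l)
  m1 <- ceiling(n / 2)
  m2 <- n - m1
  w <- c(pmin(r^(seq_len(m1) - 1), cap), rev(pmin(r^(seq_len(m2) - 1), cap)))
  w * l / sum(w)
}

allocate_nodes <- function(lengths, D, gs) {
  w <- lengths / sqrt(D)
  n <- pmax(gs$min_nodes, as.integer(round(gs$nodes * w / sum(w))))
  n
}

#' Build the finite-volume mesh of an assembly
#'
#' Internal workhorse, exported for inspection.  The mesh stores per-cell
#' widths, Henry coefficients, diffusivities and concentrations, plus the
#' series half-cell resistances used to couple cells across material
#' interfaces.
#'
#' @param x an [assembly()].
#' @param grid a [grid_spec()].
#' @return an object of class `migration_mesh`.
#' @keywords internal
#' @export
build_mesh <- function(x, grid = grid_spec()) {
  stopifnot(inherits(x, "assembly"), inherits(grid, "grid_spec"))
  lay <- as.data.frame(x)
  n_j <- allocate_nodes(lay$thickness, lay$D, grid)
  dx <- k <- D <- C <- xmid <- numeric(0)
  layer <- integer(0)
  material <- character(0)
  x0 <- 0
  for (j in seq_len(x$m)) {
    w <- graded_widths(lay$thickness[j], n_j[j], grid$grading)
    xm <- x0 + cumsum(w) - w / 2
    spec <- x$layers[[j]]
    C0 <- spec$C0
    if (is.numeric(C0)) {
      Cj <- rep(C0, n_j[j])
    } else if (is.function(C0)) {
      Cj <- C0(xm - x0)
    } else {
      Cj <- approx(C0$x, C0$C, xout = xm - x0, rule = 2)$y
    }
    if (any(!is.finite(Cj)) || any(Cj < 0))
      stop(sprintf("layer %d ('%s'): invalid initial profile", j,
                   spec$material))
    dx <- c(dx, w); xmid <- c(xmid, xm)
    k <- c(k, rep(spec$henry_k, n_j[j]))
    D <- c(D, rep(spec$D, n_j[j]))
    C <- c(C, Cj)
    layer <- c(layer, rep(j, n_j[j]))
    material <- c(material, rep(spec$material, n_j[j]))
    x0 <- x0 + lay$thickness[j]
  }
  mesh <- structure(list(
    dx = dx, k = k, D = D, C = C, x = xmid, layer = layer,
    material = material, boundary = x$boundary,
    fluid = x$fluid, t = 0, assembly = x), class = "migration_mesh")
  mesh
}

## half-cell resistances (activity form) and pair conductances; the fluid is
## a pseudo-cell in front of cell 1 whose half resistance is k0/h
mesh_conductances <- function(mesh) {
  hr <- mesh$dx * mesh$k / (2 * mesh$D)
  g <- 1 / (hr[-length(hr)] + hr[-1])
  g_fluid <- NULL
  if (!is.null(mesh$fluid))
    g_fluid <- 1 / (mesh$fluid$henry_k / mesh$fluid$h + hr[1])
  g_wrap <- NULL
  if (identical(mesh$boundary, "periodic"))
    g_wrap <- 1 / (hr[1] + hr[length(hr)])
  list(g = g, g_fluid = g_fluid, g_wrap = g_wrap)
}

## dense system matrix dC/dt = A C over [fluid?, cells...]
mesh_matrix <- function(mesh) {
  cond <- mesh_conductances(mesh)
  nf <- if (!is.null(mesh$fluid)) 1L else 0L
  dx <- c(if (nf) mesh$fluid$thickness, mesh$dx)
  k <- c(if (nf) mesh$fluid$henry_k, mesh$k)
  n <- length(dx)
  A <- matrix(0, n, n)
  g_all <- c(if (nf) cond$g_fluid, cond$g)
  for (i in seq_along(g_all)) {
    g <- g_all[i]
    A[i, i]         <- A[i, i]         - g * k[i]     / dx[i]
    A[i, i + 1]     <- A[i, i + 1]     + g * k[i + 1] / dx[i]
    A[i + 1, i + 1] <- A[i + 1, i + 1] - g * k[i + 1] / dx[i + 1]
    A[i + 1, i]     <- A[i + 1, i]     + g * k[i]     / dx[i + 1]
  }
  if (!is.null(cond$g_wrap)) {
    g <- cond$g_wrap
    A[1, 1] <- A[1, 1] - g * k[1] / dx[1]
    A[1, n] <- A[1, n] + g * k[n] / dx[1]
    A[n, n] <- A[n, n] - g * k[n] / dx[n]
    A[n, 1] <- A[n, 1] + g * k[1] / dx[n]
  }
  A
}

mesh_amounts <- function(mesh) {
  ids <- sort(unique(mesh$layer))
  amt <- vapply(ids, function(j) sum(mesh$dx[mesh$layer == j] *
                                       mesh$C[mesh$layer == j]), numeric(1))
  names(amt) <- as.character(ids)
  if (!is.null(mesh$fluid))
    amt <- c(F = mesh$fluid$thickness * mesh$fluid$C0, amt)
  amt
}

mesh_total <- function(mesh) sum(mesh_amounts(mesh))

#' Transient cross-mass transfer through a multilayer stack
#'
#' Solves the one-dimensional diffusion equation with discontinuous
#' diffusivities and Henry coefficients.  Interface fluxes are computed from
#' activity differences through series half-cell resistances, which enforces
#' local thermodynamic equilibrium (concentration jumps `C_j/C_{j+1} =
#' k_{j+1}/k_j`) at steady state; a fluid compartment evolves as a well-mixed
#' balance driven by the Biot-scaled surface flux; the far boundary is
#' zero-flux or periodic.  Time integration uses an adaptive implicit (BDF)
#' scheme, required by diffusivity contrasts of up to 1e8 between gas and
#' glassy polymer layers.
#'
#' @param x an [assembly()] (initial state taken from its `C0` fields) or a
#'   `migration_mesh` carried over from a previous step.
#' @param duration step duration in s.
#' @param grid a [grid_spec()].
#' @param times optional output times in s (strictly increasing, <=
#'   duration); defaults to a geometric schedule.
#' @param norm_base normalisation base in kg m^-2; defaults to the total
#'   initial amount of this step, per the convention that per-layer amounts
#'   are reported as fractions of the total initial amount.
#' @return an object of class `step_solution`: list with the output `times`,
#'   the concentration matrix `conc` (times x cells), the per-compartment
#'   normalised `kinetics` (a `kinetics_result`), the `mesh` (initial) and
#'   `final_mesh` (state at `duration`), and `norm_base`.
#' @export
solve_step <- function(x, duration, grid = grid_spec(), times = NULL,
                       norm_base = NULL) {
  if (inherits(x, "assembly")) {
    mesh <- build_mesh(x, grid)
  } else if (inherits(x, "migration_mesh")) {
    mesh <- x
  } else stop("'x' must be an assembly or a migration_mesh")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (is.null(times)) {
    times <- c(0, geom_seq(duration * 1e-5, duration, grid$n_times))
  } else {
    if (any(diff(times) <= 0)) stop("output times must be strictly increasing")
    if (max(times) > duration * (1 + 1e-12))
      stop("output times must not exceed the step duration")
    if (times[1] > 0) times <- c(0, times)
    if (max(times) < duration) times <- c(times, duration)
  }

  A <- mesh_matrix(mesh)
  has_fluid <- !is.null(mesh$fluid)
  y0 <- c(if (has_fluid) mesh$fluid$C0, mesh$C)
  scale <- max(abs(y0))
  if (scale == 0) {
    ## nothing to transport: the null state is stationary
    conc <- matrix(0, length(times), length(y0))
  } else {
    parms <- list(A = A)
    out <- deSolve::ode(y = y0, times = times,
                        func = function(t, y, p) list(as.vector(p$A %*% y)),
                        parms = parms,
                        jacfunc = function(t, y, p) p$A,
                        jactype = "fullusr", method = "lsoda",
                        rtol = grid$rtol, atol = grid$atol_rel * scale,
                        maxsteps = 100000)
    conc <- unname(out[, -1, drop = FALSE])
  }
  if (any(!is.finite(conc)))
    stop("solver produced non-finite concentrations (stiffness failure); ",
         "try tightening tolerances or refining the mesh")
  if (min(conc) < -grid$neg_tol * scale)
    stop(sprintf("concentration undershoot beyond tolerance: min = %.3e (scale %.3e)",
                 min(conc), scale))
  conc[conc < 0] <- 0

  if (is.null(norm_base)) norm_base <- mesh_total(mesh)
  ## per-compartment amounts
  labels <- as.character(sort(unique(mesh$layer)))
  amt <- matrix(0, nrow(conc), length(labels),
                dimnames = list(NULL, labels))
  off <- if (has_fluid) 1L else 0L
  for (jj in seq_along(labels)) {
    idx <- which(mesh$layer == as.integer(labels[jj]))
    amt[, jj] <- conc[, idx + off, drop = FALSE] %*% mesh$dx[idx]
  }
  if (has_fluid)
    amt <- cbind(F = mesh$fluid$thickness * conc[, 1], amt)
  kin <- kinetics_result(times, amt / norm_base, norm_base,
                         fluid_conc = if (has_fluid) conc[, 1] else NULL)

  final <- mesh
  final$C <- conc[nrow(conc), (1 + off):ncol(conc)]
  if (has_fluid) final$fluid$C0 <- conc[nrow(conc), 1]
  final$t <- mesh$t + duration

  structure(list(times = times, conc = conc, kinetics = kin, mesh = mesh,
                 final_mesh = final, norm_base = norm_base,
                 assembly = mesh$assembly, duration = duration),
            class = "step_solution")
}

#' @export
print.step_solution <- function(x, ...) {
  cat(sprintf("step_solution: %d cells, %d output times, duration %.4g s\n",
              length(x$mesh$dx), length(x$times), x$duration))
  cat(sprintf("mass-balance residual: %.3e\n", mass_balance(x)))
  invisible(x)
}

#' Normalised migration kinetics
#'
#' Time series of per-compartment amounts expressed as fractions of a
#' normalisation base (by default the total initial amount in the system),
#' following the convention that for closed systems the fractions sum to 1.
#'
#' @param times output times, s.
#' @param amounts matrix (times x compartments) of normalised amounts;
#'   column `"F"` is the fluid when present.
#' @param norm_base base amount, kg m^-2.
#' @param fluid_conc optional fluid concentration trace, kg m^-3.
#' @return object of class `kinetics_result`.
#' @export
kinetics_result <- function(times, amounts, norm_base, fluid_conc = NULL) {
  stopifnot(length(times) == nrow(amounts))
  structure(list(times = times, amounts = amounts, norm_base = norm_base,
                 fluid_conc = fluid_conc),
            class = "kinetics_result")
}

#' @export
as.data.frame.kinetics_result <- function(x, ...) {
  df <- data.frame(time = x$times)
  df <- cbind(df, as.data.frame(x$amounts))
  df$total <- rowSums(x$amounts)
  if (!is.null(x$fluid_conc)) df$C_fluid <- x$fluid_conc
  df
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("kinetics_result: %d times, compartments: %s, base %.4g kg/m^2\n",
              length(x$times), paste(colnames(x$amounts), collapse = ", "),
              x$norm_base))
  df <- as.data.frame(x)
  print(utils::head(df, 4)); cat("...\n"); print(utils::tail(df, 2))
  invisible(x)
}

#' Mass-balance residual of a closed-system trajectory
#'
#' Maximum over time of `|sum of compartment fractions - 1|`.  Used as a
#' runtime assertion: for closed systems the residual is bounded by the
#' integrator tolerances.
#'
#' @param x a `step_solution` or `kinetics_result`.
#' @return the residual (dimensionless).
#' @export
mass_balance <- function(x) {
  kin <- if (inherits(x, "step_solution")) x$kinetics else x
  stopifnot(inherits(kin, "kinetics_result"))
  max(abs(rowSums(kin$amounts) - 1))
}

#' Superpose kinetics of independently simulated sources
#'
#' The transport problem is linear in concentration, so the joint kinetics
#' of several sources in the same assembly is the sum of their individual
#' contributions.  Inputs must share geometry (compartment labels) and output
#' times; amounts are summed in absolute terms and renormalised by the summed
#' base.
#'
#' @param ... two or more `kinetics_result` objects.
#' @return a `kinetics_result`.
#' @export
superpose <- function(...) {
  ks <- list(...)
  if (length(ks) == 1L && is.list(ks[[1L]]) && !inherits(ks[[1L]], "kinetics_result"))
    ks <- ks[[1L]]
  stopifnot(length(ks) >= 2L,
            all(vapply(ks, inherits, logical(1), "kinetics_result")))
  t0 <- ks[[1L]]$times
  lab <- colnames(ks[[1L]]$amounts)
  for (k in ks[-1L]) {
    if (!isTRUE(all.equal(k$times, t0)))
      stop("mismatched time grids")
    if (!identical(colnames(k$amounts), lab))
      stop("mismatched compartments")
  }
  abs_amt <- Reduce(`+`, lapply(ks, function(k) k$amounts * k$norm_base))
  base <- sum(vapply(ks, `[[`, numeric(1), "norm_base"))
  fl <- lapply(ks, `[[`, "fluid_conc")
  fluid_conc <- if (all(!vapply(fl, is.null, logical(1))))
    Reduce(`+`, fl) else NULL
  kinetics_result(t0, abs_amt / base, base, fluid_conc)
}

#' Short-time screening rate of transfer across an air gap
#'
#' On short contact times the fractional loss from a source layer facing an
#' air gap is linear in time,
#' `(1 - C(t)/C(0)) * l_source ~ h_air * (k_source/RT) * t`,
#' with `h_air = D_air / l_air` the quasi-steady gas-gap conductance.  The
#' rate is proportional to the solute volatility through
#' `k = p_sat * Vbar * exp(1 + chi)`.
#'
#' @param source a [layer_spec()]: the emitting polymer layer.
#' @param air a [layer_spec()] with material `"air"`: the gap.
#' @return list with the gas conductance `h_air` (m s^-1), the fractional
#'   loss `rate` (s^-1) and a helper `fraction_lost(t)`.
#' @export
short_time_rate <- function(source, air) {
  stopifnot(inherits(source, "layer_spec"), inherits(air, "layer_spec"))
  if (!identical(air$material, "air"))
    stop("'air' must be an air layer")
  h_air <- air$D / air$thickness
  rate <- h_air * (source$henry_k / air$henry_k) / source$thickness
  list(h_air = h_air, rate = rate,
       fraction_lost = function(t) pmin(1, rate * t))
}

#' Time to reach a fraction of the equilibrium amount
#'
#' `t_eq(theta)` is the first time at which the receiving compartment(s)
#' reach the fraction `theta` of their analytic equilibrium amount.  The
#' crossing is located by monotone interpolation of the computed kinetics,
#' so the solution should extend well beyond the crossing.
#'
#' @param sol a `step_solution`.
#' @param compartments character vector of compartment labels (e.g. `"F"` or
#'   `c("1","2","3")`) whose amounts are summed.
#' @param theta target fraction of the equilibrium amount (default 0.95).
#' @param eq_fraction equilibrium amount of the compartments as a fraction of
#'   the solution's normalisation base; computed from the uniform-activity
#'   equilibrium of the step's own state when omitted.
#' @return time in s (NA with a warning if not reached).
#' @export
equilibration_time <- function(sol, compartments, theta = 0.95,
                               eq_fraction = NULL) {
  stopifnot(inherits(sol, "step_solution"), theta > 0, theta < 1)
  kin <- sol$kinetics
  miss <- setdiff(compartments, colnames(kin$amounts))
  if (length(miss)) stop("unknown compartment(s): ", paste(miss, collapse = ", "))
  series <- rowSums(kin$amounts[, compartments, drop = FALSE])
  if (is.null(eq_fraction)) {
    eq <- equilibrium_distribution(sol)
    tab <- eq$table
    eq_fraction <- sum(tab$fraction[tab$compartment %in% compartments]) *
      eq$total / sol$norm_base
  }
  target <- theta * eq_fraction
  idx <- which(series >= target)
  if (!length(idx)) {
    warning("target fraction not reached within the simulated window")
    return(NA_real_)
  }
  i <- idx[1L]
  if (i == 1L) return(kin$times[1L])
  t1 <- kin$times[i - 1L]; t2 <- kin$times[i]
  y1 <- series[i - 1L]; y2 <- series[i]
  t1 + (target - y1) / (y2 - y1) * (t2 - t1)
}

#' Concentration profile at an output time
#'
#' Cell-centre coordinates and concentrations at the stored output time
#' closest to `time`, together with the dimensionless concentration
#' `u = C * L_m / (total initial amount per area)` used by the
#' dimensionless formulation.
#'
#' @param sol a `step_solution`.
#' @param time requested time, s.
#' @return data frame with `x` (m), `layer`, `material`, `C` (kg m^-3) and
#'   `u` (dimensionless).
#' @export
profile_at <- function(sol, time) {
  stopifnot(inherits(sol, "step_solution"))
  i <- which.min(abs(sol$times - time))
  off <- if (!is.null(sol$mesh$fluid)) 1L else 0L
  C <- sol$conc[i, (1 + off):ncol(sol$conc)]
  L <- sum(sol$mesh$dx)
  data.frame(x = sol$mesh$x, layer = sol$mesh$layer,
             material = sol$mesh$material, C = C,
             u = C * L / sol$norm_base)
}

#' @export
equilibrium_distribution.step_solution <- function(x, ...) {
  mesh <- x$mesh
  lay <- as.data.frame(mesh$assembly)
  comp <- data.frame(compartment = as.character(lay$layer),
                     material = lay$material,
                     thickness = lay$thickness,
                     henry_k = lay$henry_k)
  if (!is.null(mesh$fluid))
    comp <- rbind(data.frame(compartment = "F", material = "fluid",
                             thickness = mesh$fluid$thickness,
                             henry_k = mesh$fluid$henry_k),
                  comp)
  .equilibrium_from_capacity(comp, mesh_total(mesh))
}
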