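#' One step of a multi-step storage-and-use scenario
#'
#' A step has a duration, a fully parameterised [assembly()] (per-step Henry
#' coefficients and diffusivities, so temperature changes between steps are
#' expressed through the parameters), and a transformation describing how
#' the previous step's final state maps onto this step's assembly:
#'
#' * `"keep"` - same layers, profiles carried unchanged;
#' * `list(remove = idx)` - layers `idx` of the previous assembly are
#'   discarded (their residual amount is logged, not silently dropped) and
#'   the remaining layers, in order, are this step's layers;
#' * `list(equilibrate = idx)` or `"equilibrate"` - the amount held by the
#'   subset (default: all layers) is redistributed at uniform activity
#'   within the subset before the step starts.
#'
#' Attaching or removing the fluid compartment is inferred from the step
#' assemblies themselves.
#'
#' @param duration step duration, s.
#' @param assembly the [assembly()] in force during the step.
#' @param transform transformation applied to the carried state (first step:
#'   must be `"keep"`).
#' @param temperature optional temperature label, K (documentation only).
#' @return an object of class `step_spec`.
#' @export
step_spec <- function(duration, assembly, transform = "keep",
                      temperature = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("step duration must be > 0")
  stopifnot(inherits(assembly, "assembly"))
  transform <- normalize_transform(transform)
  structure(list(duration = duration, assembly = assembly,
                 transform = transform, temperature = temperature),
            class = "step_spec")
}

normalize_transform <- function(tr) {
  if (identical(tr, "keep")) return(list(type = "keep"))
  if (identical(tr, "equilibrate"))
    return(list(type = "equilibrate", subset = NULL))
  if (is.list(tr)) {
    if (!is.null(tr$type)) return(tr)
    if (!is.null(tr$remove))
      return(list(type = "remove", layers = as.integer(tr$remove)))
    if (!is.null(tr$equilibrate)) {
      sub <- tr$equilibrate
      return(list(type = "equilibrate",
                  subset = if (identical(sub, "all")) NULL else as.integer(sub)))
    }
  }
  stop("unknown transform; use \"keep\", \"equilibrate\", list(remove=),",
       " or list(equilibrate=)")
}

#' A multi-step cross-mass transfer scenario
#'
#' @param steps list of [step_spec()] objects, executed in order.
#' @param solute optional [solute_spec()] (documentation/bookkeeping).
#' @param name scenario identifier, recorded in result headers.
#' @return object of class `scenario`.
#' @export
scenario <- function(steps, solute = NULL, name = "scenario") {
  if (inherits(steps, "step_spec")) steps <- list(steps)
  stopifnot(is.list(steps), length(steps) >= 1L,
            all(vapply(steps, inherits, logical(1), "step_spec")))
  if (steps[[1L]]$transform$type != "keep")
    stop("the first step cannot carry a transformation")
  if (!is.null(solute)) stopifnot(inherits(solute, "solute_spec"))
  structure(list(steps = steps, solute = solute, name = name),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d step(s)\n", x$name, length(x$steps)))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: %.4g s, %d layer(s)%s, transform %s\n",
                i, s$duration, s$assembly$m,
                if (!is.null(s$assembly$fluid)) " + fluid" else "",
                s$transform$type))
  }
  invisible(x)
}

## redistribute the amount held by a layer subset at uniform activity
equilibrate_mesh <- function(mesh, subset = NULL) {
  ids <- sort(unique(mesh$layer))
  if (is.null(subset)) subset <- ids
  if (!all(subset %in% ids)) stop("equilibrate: unknown layer index")
  sel <- mesh$layer %in% subset
  total <- sum(mesh$dx[sel] * mesh$C[sel])
  cap <- sum(mesh$dx[sel] / mesh$k[sel])
  if (cap <= 0) stop("equilibrate: zero-capacity subset")
  a <- total / cap
  mesh$C[sel] <- a / mesh$k[sel]
  mesh
}

remove_mesh_layers <- function(mesh, layers) {
  ids <- sort(unique(mesh$layer))
  if (!all(layers %in% ids))
    stop("remove: layer index out of range")
  sel <- mesh$layer %in% layers
  removed <- sum(mesh$dx[sel] * mesh$C[sel])
  keep <- !sel
  for (f in c("dx", "k", "D", "C", "x", "layer", "material"))
    mesh[[f]] <- mesh[[f]][keep]
  ## re-index contact-first and rebase coordinates
  old <- sort(unique(mesh$layer))
  mesh$layer <- match(mesh$layer, old)
  mesh$x <- cumsum(mesh$dx) - mesh$dx / 2
  list(mesh = mesh, removed = removed)
}

## align a carried mesh with the next step's assembly: update k, D, fluid
reconcile_mesh <- function(mesh, asm, step_index) {
  ids <- sort(unique(mesh$layer))
  if (length(ids) != asm$m)
    stop(sprintf("step %d: assembly has %d layer(s) but the carried state has %d",
                 step_index, asm$m, length(ids)))
  for (j in ids) {
    sel <- mesh$layer == j
    spec <- asm$layers[[j]]
    lsum <- sum(mesh$dx[sel])
    if (abs(lsum - spec$thickness) > 1e-9 * spec$thickness)
      stop(sprintf("step %d, layer %d: thickness mismatch (%.6g vs %.6g m)",
                   step_index, j, lsum, spec$thickness))
    mesh$k[sel] <- spec$henry_k
    mesh$D[sel] <- spec$D
    mesh$material[sel] <- spec$material
  }
  had_fluid <- !is.null(mesh$fluid)
  if (!is.null(asm$fluid)) {
    fl <- asm$fluid
    if (had_fluid && !is.null(mesh$fluid$C0)) fl$C0 <- mesh$fluid$C0
    mesh$fluid <- fl
  } else {
    mesh$fluid <- NULL
  }
  mesh$boundary <- asm$boundary
  mesh$assembly <- asm
  mesh
}

#' Run a multi-step scenario
#'
#' Executes the steps in order; each step starts from the previous step's
#' final concentration profiles after applying its transformation.  The
#' normalisation base (total initial amount of step 1) is preserved across
#' steps, and amounts removed with discarded layers are logged so that the
#' overall mass balance closes exactly.
#'
#' @param sc a [scenario()].
#' @param grid a [grid_spec()].
#' @param times optional list of per-step output-time vectors.
#' @return object of class `scenario_result`: per-step `step_solution`s, the
#'   log of removed amounts (`removed`, fractions of the base), the
#'   normalisation base and the scenario name.
#' @export
run_scenario <- function(sc, grid = grid_spec(), times = NULL) {
  stopifnot(inherits(sc, "scenario"))
  if (!is.null(times)) stopifnot(is.list(times),
                                 length(times) == length(sc$steps))
  results <- vector("list", length(sc$steps))
  removed <- numeric(length(sc$steps))
  mesh <- NULL
  base <- NULL
  for (i in seq_along(sc$steps)) {
    st <- sc$steps[[i]]
    if (i == 1L) {
      mesh <- build_mesh(st$assembly, grid)
      base <- mesh_total(mesh)
    } else {
      tr <- st$transform
      if (tr$type == "remove") {
        out <- remove_mesh_layers(mesh, tr$layers)
        mesh <- out$mesh
        removed[i] <- out$removed
      } else if (tr$type == "equilibrate") {
        mesh <- equilibrate_mesh(mesh, tr$subset)
      }
      mesh <- reconcile_mesh(mesh, st$assembly, i)
    }
    sol <- solve_step(mesh, st$duration, grid,
                      times = if (!is.null(times)) times[[i]],
                      norm_base = base)
    results[[i]] <- sol
    mesh <- sol$final_mesh
  }
  structure(list(steps = results,
                 removed = removed / base,
                 norm_base = base, name = sc$name, scenario = sc),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result '%s': %d step(s), base %.4g kg/m^2\n",
              x$name, length(x$steps), x$norm_base))
  for (i in seq_along(x$steps)) {
    kin <- x$steps[[i]]$kinetics
    last <- kin$amounts[nrow(kin$amounts), ]
    cat(sprintf("  step %d end: %s%s\n", i,
                paste(sprintf("%s=%.4f", colnames(kin$amounts), last),
                      collapse = " "),
                if (x$removed[i] > 0)
                  sprintf("  (removed %.4f)", x$removed[i]) else ""))
  }
  invisible(x)
}

#' Seed an assembly with an equilibrium initial distribution
#'
#' Distributes a given total amount (per unit area) over a subset of layers
#' at uniform activity - each layer of the subset receives an amount
#' proportional to its capacity `l_j / k_j` - and sets all other layers to
#' zero.  This is the standard way to encode "the residue is distributed in
#' the source according to its relative chemical affinity for each layer".
#'
#' @param x an [assembly()].
#' @param total_amount amount per unit area, kg m^-2.
#' @param layers indices of the subset carrying the amount (default: all).
#' @return the assembly with initial concentrations set.
#' @export
distribute_equilibrium_initial <- function(x, total_amount,
                                           layers = seq_len(x$m)) {
  stopifnot(inherits(x, "assembly"), total_amount >= 0)
  if (!length(layers)) stop("empty layer subset")
  if (!all(layers %in% seq_len(x$m))) stop("layer index out of range")
  l <- vapply(x$layers, `[[`, numeric(1), "thickness")[layers]
  k <- vapply(x$layers, `[[`, numeric(1), "henry_k")[layers]
  cap <- sum(l / k)
  if (cap <= 0) stop("zero-capacity subset")
  a <- total_amount / cap
  for (j in seq_len(x$m)) x$layers[[j]]$C0 <- 0
  for (i in seq_along(layers)) x$layers[[layers[i]]]$C0 <- a / k[i]
  x
}
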