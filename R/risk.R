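#' Weibull distribution of contact (loading) times
#'
#' Contact times are modelled as the product of a scale parameter (the
#' typical storage time) and a unit-scale Weibull variate; the quantile
#' function is `t(q) = scale * (-log(1 - q))^(1/shape)`.  `shape = Inf`
#' denotes the degenerate point mass at `scale`, used to recover the
#' deterministic case.
#'
#' @param scale scale parameter, s (> 0).
#' @param shape shape parameter (> 0; default 3).
#' @return object of class `contact_time_distribution`.
#' @export
contact_time_distribution <- function(scale, shape = 3) {
  stopifnot(is.numeric(scale), scale > 0, is.numeric(shape), shape > 0)
  structure(list(family = "weibull", scale = scale, shape = shape),
            class = "contact_time_distribution")
}

#' @export
print.contact_time_distribution <- function(x, ...) {
  cat(sprintf("Weibull contact times: scale %.4g s, shape %.4g\n",
              x$scale, x$shape))
  invisible(x)
}

#' Quantile of the contact-time distribution
#' @param dist a [contact_time_distribution()].
#' @param q probabilities in (0, 1).
#' @return times, s.
#' @export
quantile_contact_time <- function(dist, q) {
  stopifnot(inherits(dist, "contact_time_distribution"),
            all(q > 0), all(q < 1))
  if (is.infinite(dist$shape)) return(rep(dist$scale, length(q)))
  dist$scale * (-log(1 - q))^(1 / dist$shape)
}

#' CDF of the contact-time distribution
#' @param dist a [contact_time_distribution()].
#' @param t times, s.
#' @return probabilities.
#' @export
cdf_contact_time <- function(dist, t) {
  stopifnot(inherits(dist, "contact_time_distribution"))
  if (is.infinite(dist$shape)) return(as.numeric(t >= dist$scale))
  pweibull(t, shape = dist$shape, scale = dist$scale)
}

#' Reproducible contact-time draws
#'
#' Inverse-transform sampling from the stated quantile function.  When a
#' seed is given the global RNG state is saved and restored.
#'
#' @param dist a [contact_time_distribution()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return vector of times, s.
#' @export
sample_contact_times <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "contact_time_distribution"), n > 0)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  u <- runif(n)
  if (is.infinite(dist$shape)) return(rep(dist$scale, n))
  dist$scale * (-log(1 - u))^(1 / dist$shape)
}

#' Tabulated monotone loading model
#'
#' Simulates a one-step loading scenario once and tabulates the amount
#' transferred to the receiving compartments as a monotone function
#' `Omega(t1)` of the contact time, on a geometric grid spanning
#' `[1e-3, 1e2] * t_scale`.  The map and its inverse are monotone spline
#' interpolants (in `sqrt(t)` for a well-behaved early-time shape).
#'
#' @param sc a one-step [scenario()] (the loading configuration), or a
#'   multi-step scenario whose first step is the loading step.
#' @param receiving labels of the receiving compartments (e.g. `c("1","2","3")`
#'   for the bag wall layers).
#' @param t_scale time scale, s (typically the distribution's scale).
#' @param n_points number of tabulation points; the default resolves the
#'   inverse map even where the loading curve flattens near equilibrium.
#' @param grid a [grid_spec()].
#' @return object of class `loading_map` with fields `t`, `m`, interpolants
#'   `Omega` and `Omega_inv`, and `m_max`.
#' @export
loading_map <- function(sc, receiving, t_scale, n_points = 120,
                        grid = grid_spec()) {
  stopifnot(inherits(sc, "scenario"), t_scale > 0)
  st <- sc$steps[[1L]]
  tgrid <- geom_seq(1e-3 * t_scale, 1e2 * t_scale, n_points)
  sol <- solve_step(st$assembly, duration = max(tgrid), grid = grid,
                    times = tgrid)
  kin <- sol$kinetics
  miss <- setdiff(receiving, colnames(kin$amounts))
  if (length(miss)) stop("unknown receiving compartment(s): ",
                         paste(miss, collapse = ", "))
  m <- rowSums(kin$amounts[, receiving, drop = FALSE])
  t <- kin$times
  if (t[1] > 0) { t <- c(0, t); m <- c(0, m) }
  m[1] <- 0
  m <- cummax(m)  # guard against integrator-level non-monotonicity
  if (any(diff(m) < 0)) stop("loading map is not monotone")
  keep <- !duplicated(m)
  Omega <- splinefun(sqrt(t), m, method = "hyman")
  Omega_inv <- splinefun(m[keep], sqrt(t)[keep], method = "hyman")
  structure(list(t = t, m = m, m_max = max(m),
                 Omega = function(tt) pmax(0, Omega(sqrt(tt))),
                 Omega_inv = function(mm) Omega_inv(mm)^2,
                 receiving = receiving, scenario_name = sc$name),
            class = "loading_map")
}

#' @export
print.loading_map <- function(x, ...) {
  cat(sprintf("loading_map: Omega tabulated at %d times in [%.3g, %.3g] s, sup = %.4g\n",
              length(x$t), min(x$t[x$t > 0]), max(x$t), x$m_max))
  invisible(x)
}

#' Probability that the transferred amount exceeds a value
#'
#' For a monotone loading model `Omega`,
#' `Pr(m(t1) >= m) = 1 - F_t1(Omega^{-1}(m))`:
#' the exceedance probability of the amount transferred during a random
#' contact time `t1`.
#'
#' @param m amount threshold(s), on the same (normalised) scale as the map.
#' @param map a [loading_map()].
#' @param dist a [contact_time_distribution()].
#' @return exceedance probabilities in `[0, 1]`, non-increasing in `m`.
#' @export
exceedance_probability <- function(m, map, dist) {
  stopifnot(inherits(map, "loading_map"),
            inherits(dist, "contact_time_distribution"))
  if (any(m < 0)) stop("m must be >= 0")
  p <- numeric(length(m))
  for (i in seq_along(m)) {
    if (m[i] <= 0) { p[i] <- 1; next }
    if (m[i] >= map$m_max) { p[i] <- 0; next }
    p[i] <- 1 - cdf_contact_time(dist, map$Omega_inv(m[i]))
  }
  p
}

#' Migration kinetics at a given percentile of the loading-time distribution
#'
#' Because the loading model is monotone in the contact time, the q-th
#' percentile of the transferred amount is reached exactly at the q-th
#' percentile of the contact time.  The loading step is therefore run to
#' `t1(q)` and its final concentration profile seeds the migration step,
#' giving the migration kinetics of the q-th percentile scenario without
#' Monte-Carlo sampling.
#'
#' @param sc a two-step [scenario()] (loading then migration).
#' @param dist a [contact_time_distribution()].
#' @param q percentile in (0, 1).
#' @param grid a [grid_spec()].
#' @param times optional output times for the migration step.
#' @return the migration-step `step_solution`, with attributes `t1` (the
#'   loading time used) and `q`.
#' @export
percentile_kinetics <- function(sc, dist, q, grid = grid_spec(),
                                times = NULL) {
  stopifnot(inherits(sc, "scenario"), length(sc$steps) >= 2L,
            length(q) == 1L, q > 0, q < 1)
  t1 <- quantile_contact_time(dist, q)
  sc$steps[[1L]]$duration <- t1
  res <- run_scenario(sc, grid,
                      times = if (!is.null(times))
                        c(list(NULL), rep(list(times), length(sc$steps) - 1L)))
  out <- res$steps[[length(res$steps)]]
  attr(out, "t1") <- t1
  attr(out, "q") <- q
  out
}

#' Tabular risk report
#'
#' Runs [percentile_kinetics()] for the median, an upper percentile and the
#' deterministic case (contact time fixed at the distribution scale) and
#' returns the fluid uptake curves side by side.
#'
#' @param sc a two-step [scenario()].
#' @param dist a [contact_time_distribution()].
#' @param percentiles percentiles to report.
#' @param grid a [grid_spec()].
#' @param times migration-step output times (s).
#' @return data frame: time, one column per percentile, and `deterministic`.
#' @export
risk_report <- function(sc, dist, percentiles = c(0.5, 0.95),
                        grid = grid_spec(), times = NULL) {
  if (is.null(times)) {
    d2 <- sc$steps[[length(sc$steps)]]$duration
    times <- geom_seq(d2 * 1e-4, d2, 40)
  }
  cols <- lapply(percentiles, function(q) {
    sol <- percentile_kinetics(sc, dist, q, grid, times)
    approx(sol$kinetics$times, sol$kinetics$amounts[, "F"], xout = times)$y
  })
  det <- contact_time_distribution(dist$scale, Inf)
  sol <- percentile_kinetics(sc, det, 0.5, grid, times)
  out <- data.frame(time = times)
  for (i in seq_along(percentiles))
    out[[sprintf("q%02d", round(100 * percentiles[i]))]] <- cols[[i]]
  out$deterministic <- approx(sol$kinetics$times,
                              sol$kinetics$amounts[, "F"], xout = times)$y
  out
}
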