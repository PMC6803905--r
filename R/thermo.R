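#' Henry coefficient from the Flory-Huggins interaction parameter
#'
#' At low solute concentration a Flory sorption isotherm linearises into a
#' Henry law `p = k * C` with
#' `k = p_sat * Vbar * exp(1 + chi)`,
#' where `p_sat` is the saturation pressure of the solute, `Vbar` its molar
#' volume and `chi` the polymer-solute Flory-Huggins coefficient.
#'
#' @param chi Flory-Huggins interaction parameter (dimensionless).
#' @param p_sat saturation pressure, Pa.
#' @param molar_volume molar volume, m^3 mol^-1.
#' @return Henry coefficient k, Pa m^3 mol^-1.
#' @seealso [henry_air()] for gas layers.
#' @export
#' @examples
#' henry_coefficient(chi = -0.19, p_sat = 0.483, molar_volume = 1.06e-4)
henry_coefficient <- function(chi, p_sat, molar_volume) {
  if (any(p_sat < 0)) stop("p_sat must be >= 0")
  if (any(molar_volume <= 0)) stop("molar_volume must be > 0")
  p_sat * molar_volume * exp(1 + chi)
}

#' Polymer-polymer partition coefficient from Flory-Huggins parameters
#'
#' Equilibrium concentration ratio `K = C_target / C_source` of a solute
#' between two polymers at equal activity:
#' `ln K_target/source = chi_source - chi_target`.
#' A solute partitions preferentially into the polymer with the lower `chi`.
#'
#' @param chi_target Flory-Huggins parameter in the target (numerator) phase.
#' @param chi_source Flory-Huggins parameter in the source (denominator) phase.
#' @return dimensionless partition coefficient.
#' @export
#' @examples
#' ## caprolactam between PA6 and LDPE
#' polymer_partition(chi_target = -1.19, chi_source = 0.76)  # ~7.03
polymer_partition <- function(chi_target, chi_source) {
  if (any(!is.finite(chi_target)) || any(!is.finite(chi_source)))
    stop("chi values must be finite")
  exp(chi_source - chi_target)
}

#' Analytic uniform-activity equilibrium of a closed stack
#'
#' At thermodynamic equilibrium the activity `k_j * C_j` is uniform over all
#' layers and the fluid, so each compartment holds an amount proportional to
#' its capacity `l_j / k_j`.  This is the long-time limit of the transient
#' solver for any closed (impervious or fluid-terminated) assembly and
#' generalises the classical two- and three-layer equilibrium formulas.
#'
#' @param x an [assembly()] with scalar initial concentrations, or an object
#'   with a solver mesh (a `step_solution`), in which case the current total
#'   amount is redistributed.
#' @param ... unused.
#' @return an object of class `equilibrium_result`: a list with a data frame
#'   `table` (compartment, capacity, fraction of the total amount,
#'   equilibrium concentration), the uniform `activity` (Pa) and the total
#'   amount per area (kg m^-2).
#' @export
equilibrium_distribution <- function(x, ...) UseMethod("equilibrium_distribution")

#' @export
equilibrium_distribution.assembly <- function(x, ...) {
  lay <- as.data.frame(x)
  total <- total_initial_amount(x)
  comp <- data.frame(compartment = as.character(lay$layer),
                     material = lay$material,
                     thickness = lay$thickness,
                     henry_k = lay$henry_k)
  if (!is.null(x$fluid))
    comp <- rbind(data.frame(compartment = "F", material = "fluid",
                             thickness = x$fluid$thickness,
                             henry_k = x$fluid$henry_k),
                  comp)
  .equilibrium_from_capacity(comp, total)
}

.equilibrium_from_capacity <- function(comp, total) {
  comp$capacity <- comp$thickness / comp$henry_k
  cap <- sum(comp$capacity)
  if (cap <= 0) stop("zero total capacity")
  activity <- total / cap
  comp$fraction <- comp$capacity / cap
  comp$concentration <- activity / comp$henry_k
  structure(list(table = comp, activity = activity, total = total),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Uniform-activity equilibrium: activity = %.6g Pa, total = %.6g kg/m^2\n",
              x$activity, x$total))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Apparent partition coefficient between the fluid and the whole material
#'
#' Ratio of the equilibrium fluid concentration to the thickness-averaged
#' concentration of the solid stack, `K_F/P = C_F / Cbar_P`.  At uniform
#' activity this equals `k_eff / k_0` with `k_eff` the effective Henry
#' coefficient of the stack (see [effective_henry()]).
#'
#' @param eq an `equilibrium_result` from [equilibrium_distribution()]; must
#'   contain a fluid compartment.
#' @return dimensionless apparent partition coefficient.
#' @export
apparent_partition <- function(eq) {
  stopifnot(inherits(eq, "equilibrium_result"))
  tab <- eq$table
  f <- tab$compartment == "F"
  if (!any(f)) stop("equilibrium has no fluid compartment")
  mat <- tab[!f, , drop = FALSE]
  cbar <- sum(mat$thickness * mat$concentration) / sum(mat$thickness)
  if (cbar <= 0) stop("zero average material concentration")
  tab$concentration[f] / cbar
}

#' Effective Henry coefficient of a composite material
#'
#' Volume-fraction harmonic mean, `1/k_eff = sum(phi_j / k_j)`.  When exactly
#' one `k` is `NA` and `k_eff` is supplied, the missing coefficient is solved
#' for instead (inverse mode).
#'
#' @param phi volume fractions, non-negative, summing to 1.
#' @param k Henry coefficients, same length as `phi`; in inverse mode exactly
#'   one entry is `NA`.
#' @param k_eff known effective coefficient (inverse mode only).
#' @return `k_eff` (forward mode) or the completed `k` vector (inverse mode).
#' @export
#' @examples
#' effective_henry(c(0.5, 0.5), c(1, 3))         # 1.5
#' effective_henry(c(0.5, 0.5), c(1, NA), k_eff = 1.5)
effective_henry <- function(phi, k, k_eff = NULL) {
  if (length(phi) != length(k)) stop("phi and k must have the same length")
  if (any(phi < 0)) stop("volume fractions must be >= 0")
  if (abs(sum(phi) - 1) > 1e-8) stop("volume fractions must sum to 1")
  miss <- is.na(k)
  if (!any(miss)) {
    if (any(k == 0)) stop("Henry coefficients must be non-zero")
    return(1 / sum(phi / k))
  }
  if (sum(miss) > 1L)
    stop("inverse mode is over-determined: more than one missing k")
  if (is.null(k_eff)) stop("k_eff is required to solve for a missing k")
  if (any(k[!miss] == 0)) stop("Henry coefficients must be non-zero")
  rest <- 1 / k_eff - sum(phi[!miss] / k[!miss])
  if (rest <= 0)
    stop("no positive solution for the missing Henry coefficient")
  k[miss] <- phi[miss] / rest
  k
}

## Fuller-Schettler-Giddings atomic diffusion-volume increments (cm^3/mol)
.fuller_increments <- c(C = 15.9, H = 2.31, O = 6.11, N = 4.54, S = 22.9,
                        F = 14.7, Cl = 21.0, Br = 21.9, I = 29.8)
.fuller_ring <- -18.3
.fuller_air_M <- 29
.fuller_air_v <- 19.7

#' Fuller diffusion volume from an atomic composition
#'
#' Sums published atomic increments with a correction of -18.3 per aromatic
#' or heterocyclic ring.
#'
#' @param counts named numeric vector of atom counts, e.g.
#'   `c(C = 6, H = 11, N = 1, O = 1)`.
#' @param rings number of aromatic/heterocyclic rings.
#' @return diffusion volume (dimensionless Fuller units).
#' @export
#' @examples
#' fuller_diffusion_volume(c(C = 6, H = 11, N = 1, O = 1), rings = 1)
fuller_diffusion_volume <- function(counts, rings = 0) {
  if (is.null(names(counts))) stop("'counts' must be a named vector")
  unknown <- setdiff(names(counts), names(.fuller_increments))
  if (length(unknown))
    stop("no Fuller increment for element(s): ",
         paste(unknown, collapse = ", "))
  sum(counts * .fuller_increments[names(counts)]) + rings * .fuller_ring
}

#' Gas-phase diffusivity from Fuller's law
#'
#' Fuller-Schettler-Giddings correlation for the binary diffusivity of a
#' solute in air (`M_air = 29` g/mol, diffusion volume 19.7):
#' `D ~ T^1.75 / P`.
#'
#' @param molar_mass solute molar mass, g mol^-1.
#' @param diffusion_volume solute Fuller diffusion volume, e.g. from
#'   [fuller_diffusion_volume()].
#' @param temperature absolute temperature, K.
#' @param pressure total pressure, Pa.
#' @return diffusivity in m^2 s^-1.
#' @export
#' @examples
#' fuller_gas_diffusivity(113.16,
#'   fuller_diffusion_volume(c(C = 6, H = 11, N = 1, O = 1), rings = 1),
#'   temperature = 313.15)
fuller_gas_diffusivity <- function(molar_mass, diffusion_volume,
                                   temperature = 298.15, pressure = 101325) {
  stopifnot(molar_mass > 0, diffusion_volume > 0, temperature > 0,
            pressure > 0)
  p_atm <- pressure / 101325
  ## 1e-7: Fuller's 1e-3 (cm^2/s) converted to m^2/s
  1e-7 * temperature^1.75 * sqrt(1 / molar_mass + 1 / .fuller_air_M) /
    (p_atm * (diffusion_volume^(1 / 3) + .fuller_air_v^(1 / 3))^2)
}

#' Per-layer mass-transfer resistances relative to a reference air gap
#'
#' The steady-state resistance of a layer to permeation is `l * k / D`; the
#' conventional diagnostic normalises it by the resistance of a 0.1 mm air
#' layer, giving a dimensionless ranking of barrier strengths.  The reference
#' air properties default to those of the air layer present in the assembly.
#'
#' @param x an [assembly()].
#' @param ref_thickness reference air-gap thickness, m (default 0.1 mm).
#' @param ref_D reference gas diffusivity, m^2 s^-1; defaults to the
#'   diffusivity of the assembly's air layer.
#' @param ref_k reference Henry coefficient; defaults to that of the
#'   assembly's air layer (`R * T`).
#' @return data frame with the layer resistances, their ratio to the air
#'   reference and the ratio rounded to the nearest integer (the usual
#'   reporting convention).
#' @export
resistance_ratios <- function(x, ref_thickness = 1e-4, ref_D = NULL,
                              ref_k = NULL) {
  stopifnot(inherits(x, "assembly"))
  lay <- as.data.frame(x)
  air <- which(lay$material == "air")
  if (is.null(ref_D)) {
    if (!length(air))
      stop("no air layer in the assembly: supply ref_D")
    ref_D <- lay$D[air[1L]]
  }
  if (is.null(ref_k)) {
    if (!length(air))
      stop("no air layer in the assembly: supply ref_k (typically R*T)")
    ref_k <- lay$henry_k[air[1L]]
  }
  if (any(lay$D <= 0) || ref_D <= 0) stop("zero diffusivity")
  R <- lay$thickness * lay$henry_k / lay$D
  R_ref <- ref_thickness * ref_k / ref_D
  data.frame(layer = lay$layer, material = lay$material,
             thickness = lay$thickness, resistance = R,
             relative = R / R_ref, rounded = round(R / R_ref))
}
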