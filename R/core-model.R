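#' Physical description of a migrating solute
#'
#' Bundles the physical constants of a migrant (molar mass, saturation
#' pressure, molar volume) with its per-material sorption and transport
#' parameters.  A material entry may specify the Flory-Huggins interaction
#' parameter `chi` (from which the Henry coefficient is derived, see
#' [henry_coefficient()]), or a Henry coefficient `henry_k` directly, plus a
#' diffusivity `D`.
#'
#' @param name solute name.
#' @param molar_mass molar mass in g mol^-1.
#' @param p_sat saturation (vapour) pressure in Pa at the working temperature.
#' @param molar_volume molar volume in m^3 mol^-1.
#' @param materials named list; each element a list with fields among
#'   `chi` (dimensionless), `henry_k` (Pa m^3 mol^-1) and `D` (m^2 s^-1).
#' @return an object of class `solute_spec`.
#' @export
#' @examples
#' caprolactam <- solute_spec("caprolactam", 113.16, p_sat = 0.483,
#'   molar_volume = 1.06e-4,
#'   materials = list(LDPE = list(chi = 0.76, D = 1e-13),
#'                    PA6  = list(chi = -1.19, D = 1.9e-16)))
solute_spec <- function(name, molar_mass, p_sat, molar_volume,
                        materials = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0)
    stop("'molar_mass' must be a positive scalar (g/mol)")
  if (!is.numeric(p_sat) || length(p_sat) != 1L || p_sat < 0)
    stop("'p_sat' must be a non-negative scalar (Pa)")
  if (!is.numeric(molar_volume) || length(molar_volume) != 1L || molar_volume <= 0)
    stop("'molar_volume' must be a positive scalar (m^3/mol)")
  if (length(materials) && is.null(names(materials)))
    stop("'materials' must be a named list")
  for (m in names(materials)) {
    entry <- materials[[m]]
    if (!is.list(entry))
      stop(sprintf("materials$%s must be a list", m))
    bad <- setdiff(names(entry), c("chi", "henry_k", "D"))
    if (length(bad))
      stop(sprintf("materials$%s: unknown field(s) %s", m,
                   paste(bad, collapse = ", ")))
  }
  structure(list(name = name, molar_mass = molar_mass, p_sat = p_sat,
                 molar_volume = molar_volume, materials = materials),
            class = "solute_spec")
}

#' Resolve the Henry coefficient of a solute in a named material
#'
#' Uses the stored `henry_k` if present, otherwise computes it from the
#' Flory-Huggins `chi` via [henry_coefficient()].  The material name `"air"`
#' always resolves to `R * T`.
#'
#' @param solute a [solute_spec()].
#' @param material material name.
#' @param temperature absolute temperature (K), used for air layers.
#' @return Henry coefficient in Pa m^3 mol^-1.
#' @export
material_henry <- function(solute, material, temperature = 298.15) {
  stopifnot(inherits(solute, "solute_spec"))
  if (identical(material, "air")) return(henry_air(temperature))
  entry <- solute$materials[[material]]
  if (is.null(entry))
    stop(sprintf("solute '%s' has no parameters for material '%s'",
                 solute$name, material))
  if (!is.null(entry$henry_k)) return(entry$henry_k)
  if (!is.null(entry$chi))
    return(henry_coefficient(entry$chi, solute$p_sat, solute$molar_volume))
  stop(sprintf("material '%s' of solute '%s' has neither 'henry_k' nor 'chi'",
               material, solute$name))
}

#' Resolve the diffusivity of a solute in a named material
#'
#' @inheritParams material_henry
#' @return diffusion coefficient in m^2 s^-1.
#' @export
material_diffusivity <- function(solute, material) {
  stopifnot(inherits(solute, "solute_spec"))
  entry <- solute$materials[[material]]
  if (is.null(entry) || is.null(entry$D))
    stop(sprintf("solute '%s' has no diffusivity for material '%s'",
                 solute$name, material))
  entry$D
}

#' Specification of one layer of a multilayer stack
#'
#' @param material material name (free text; `"air"` marks a gas layer).
#' @param thickness layer thickness in m.
#' @param henry_k Henry coefficient k (Pa m^3 mol^-1) in the activity
#'   convention `p = k * C`; for air layers use `henry_air(T)`.
#' @param D diffusion coefficient in m^2 s^-1.
#' @param C0 initial concentration, kg m^-3.  Either a scalar (uniform), a
#'   function of the local coordinate (m, measured from the contact-side face
#'   of the layer), or a two-column data frame with columns `x` and `C`.
#' @param density material density in kg m^-3; only used for
#'   mg/kg <-> kg/m^3 conversions.
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(material, thickness, henry_k, D, C0 = 0,
                       density = 1000) {
  stopifnot(is.character(material), length(material) == 1L)
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop(sprintf("layer '%s': thickness must be > 0", material))
  if (!is.numeric(henry_k) || length(henry_k) != 1L || henry_k <= 0)
    stop(sprintf("layer '%s': henry_k must be > 0", material))
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop(sprintf("layer '%s': D must be > 0", material))
  if (is.numeric(C0)) {
    if (length(C0) != 1L || C0 < 0)
      stop(sprintf("layer '%s': scalar C0 must be >= 0", material))
  } else if (!is.function(C0) && !(is.data.frame(C0) &&
             all(c("x", "C") %in% names(C0)))) {
    stop(sprintf("layer '%s': C0 must be a scalar, a function, or a data frame with columns x, C",
                 material))
  }
  if (!is.numeric(density) || density <= 0)
    stop(sprintf("layer '%s': density must be > 0", material))
  structure(list(material = material, thickness = thickness,
                 henry_k = henry_k, D = D, C0 = C0, density = density),
            class = "layer_spec")
}

#' Air layer shortcut
#'
#' @param thickness gap thickness in m.
#' @param temperature absolute temperature in K; sets `henry_k = R * T`.
#' @param D gas-phase diffusivity in m^2 s^-1 (e.g. from
#'   [fuller_gas_diffusivity()]).
#' @return a [layer_spec()] with material `"air"`.
#' @export
air_layer <- function(thickness, temperature = 298.15, D) {
  layer_spec("air", thickness, henry_k = henry_air(temperature), D = D,
             C0 = 0, density = 1.2)
}

#' Well-mixed fluid compartment in contact with the stack
#'
#' The fluid (food simulant, culture medium, ...) is represented by its
#' equivalent thickness (volume per unit contact area), Henry coefficient and
#' a surface mass-transfer resistance expressed either as a mass Biot number
#' `Bi = h * l1 / D1` (relative to the contact layer) or a mass-transfer
#' coefficient `h` (m s^-1).  Exactly one of `Bi` and `h` must be given; the
#' other is derived when the compartment is attached to an [assembly()].
#'
#' @param thickness equivalent fluid thickness l0 = V/A in m.
#' @param henry_k Henry coefficient of the solute in the fluid.
#' @param Bi mass Biot number (dimensionless); `Bi = 1000` is used as the
#'   conventional "negligible external resistance" value.
#' @param h surface mass-transfer coefficient in m s^-1.
#' @param C0 initial fluid concentration, kg m^-3.
#' @param density fluid density, kg m^-3.
#' @return an object of class `fluid_compartment`.
#' @export
fluid_compartment <- function(thickness, henry_k, Bi = NULL, h = NULL,
                              C0 = 0, density = 1000) {
  if (!is.numeric(thickness) || thickness <= 0)
    stop("fluid: thickness must be > 0")
  if (!is.numeric(henry_k) || henry_k <= 0)
    stop("fluid: henry_k must be > 0")
  if (is.null(Bi) == is.null(h))
    stop("fluid: exactly one of 'Bi' and 'h' must be given")
  if (!is.null(Bi) && (!is.numeric(Bi) || Bi <= 0))
    stop("fluid: Bi must be > 0")
  if (!is.null(h) && (!is.numeric(h) || h <= 0))
    stop("fluid: h must be > 0")
  if (!is.numeric(C0) || C0 < 0) stop("fluid: C0 must be >= 0")
  structure(list(thickness = thickness, henry_k = henry_k, Bi = Bi, h = h,
                 C0 = C0, density = density),
            class = "fluid_compartment")
}

#' Assemble layers (and an optional fluid) into a one-dimensional stack
#'
#' Layers are ordered contact-side first: layer 1 touches the fluid (or the
#' free contact face), layer m is the far side.  The far boundary is either
#' impervious (zero flux, the stacked/symmetric storage configuration) or
#' periodic (set-off: the far face exchanges with the contact face, as in
#' reel storage).  A periodic assembly cannot carry a fluid compartment.
#'
#' @param layers list of [layer_spec()] objects, contact side first.
#' @param fluid optional [fluid_compartment()] on the contact side.
#' @param boundary far-side boundary condition, `"impervious"` or
#'   `"periodic"`.
#' @return an object of class `assembly` with cumulated thicknesses `L` and,
#'   when a fluid is present, both `Bi` and `h` resolved.
#' @export
#' @examples
#' a <- assembly(list(
#'   layer_spec("B", 1e-4, henry_k = 1, D = 1e-13, C0 = 1),
#'   layer_spec("A", 5e-5, henry_k = 2, D = 5e-14)))
assembly <- function(layers, fluid = NULL,
                     boundary = c("impervious", "periodic")) {
  boundary <- match.arg(boundary)
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a non-empty list of layer_spec objects")
  if (!all(vapply(layers, inherits, logical(1), "layer_spec")))
    stop("every element of 'layers' must be a layer_spec")
  if (!is.null(fluid)) {
    if (!inherits(fluid, "fluid_compartment"))
      stop("'fluid' must be a fluid_compartment")
    if (boundary == "periodic")
      stop("a periodic assembly cannot carry a fluid compartment")
    l1 <- layers[[1L]]
    if (is.null(fluid$h)) fluid$h <- fluid$Bi * l1$D / l1$thickness
    if (is.null(fluid$Bi)) fluid$Bi <- fluid$h * l1$thickness / l1$D
  }
  l <- vapply(layers, `[[`, numeric(1), "thickness")
  structure(list(layers = layers, fluid = fluid, boundary = boundary,
                 m = length(layers), L = cumsum(l)),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("Multilayer assembly: %d layer(s), far boundary %s%s\n",
              x$m, x$boundary,
              if (!is.null(x$fluid)) ", fluid-contacted" else ""))
  print(as.data.frame(x))
  if (!is.null(x$fluid))
    cat(sprintf("fluid: l0 = %.4g m, k0 = %.4g, Bi = %.4g, C0 = %.4g kg/m^3\n",
                x$fluid$thickness, x$fluid$henry_k, x$fluid$Bi, x$fluid$C0))
  invisible(x)
}

#' @export
as.data.frame.assembly <- function(x, ...) {
  data.frame(
    layer = seq_len(x$m),
    material = vapply(x$layers, `[[`, character(1), "material"),
    thickness = vapply(x$layers, `[[`, numeric(1), "thickness"),
    henry_k = vapply(x$layers, `[[`, numeric(1), "henry_k"),
    D = vapply(x$layers, `[[`, numeric(1), "D"),
    C0 = vapply(x$layers, function(l)
      if (is.numeric(l$C0)) l$C0 else NA_real_, numeric(1)),
    density = vapply(x$layers, `[[`, numeric(1), "density"))
}

#' Total initial amount per unit area in an assembly
#'
#' Sum over layers (and the fluid) of thickness times initial concentration,
#' in kg m^-2.  Requires scalar initial concentrations; assemblies with
#' stored profiles are integrated on the solver mesh instead.
#'
#' @param x an [assembly()].
#' @return amount per unit area, kg m^-2.
#' @export
total_initial_amount <- function(x) {
  stopifnot(inherits(x, "assembly"))
  C0 <- vapply(x$layers, function(l) {
    if (!is.numeric(l$C0))
      stop("total_initial_amount needs scalar initial concentrations; ",
           "profiles are integrated on the solver mesh")
    l$C0
  }, numeric(1))
  l <- vapply(x$layers, `[[`, numeric(1), "thickness")
  tot <- sum(l * C0)
  if (!is.null(x$fluid)) tot <- tot + x$fluid$thickness * x$fluid$C0
  tot
}

#' Convert a mass-fraction concentration to a volumic one
#'
#' @param x concentration in mg per kg of material.
#' @param density material density in kg m^-3.
#' @return concentration in kg m^-3.
#' @export
mgkg_to_kgm3 <- function(x, density = 1000) x * 1e-6 * density

#' @rdname mgkg_to_kgm3
#' @param y concentration in kg m^-3.
#' @export
kgm3_to_mgkg <- function(y, density = 1000) y * 1e6 / density
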