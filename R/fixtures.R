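## Built-in case studies: dimensionless didactic scenarios (S1, S2), the
## overpackaging -> bag loading systems (T1/T2, caprolactam and BHT) and the
## bag -> ethanol migration systems for ten surrogate solutes.

## surrogate solute constants: molar mass (g/mol), saturation pressure at
## 25 C (Pa), mean concentration after spiking/equilibration in bag walls
## (mg/kg; T1 and T2)
.surrogates <- data.frame(
  solute = c("acetic_acid", "hexanol", "caprolactam", "decane", "prodox146",
             "BHT", "hexadecane", "irganox1076", "irgafos168", "irganox1010"),
  molar_mass = c(60.05, 102.17, 113.16, 142.29, 206.33,
                 220.35, 286.8, 530.87, 646.92, 1177.65),
  p_sat = c(2.14e3, 105, 0.483, 211, 0.356,
            0.236, 0.929, 4.51e-11, 6.32e-12, 9.84e-29),
  C_T1 = c(754, 533, 854, 2227, 1258, 1159, 4299, 2562, 1907, 635),
  C_T2 = c(540, 213, 630, 1189, 324, 299, 2989, 666, 172, 48),
  stringsAsFactors = FALSE)

## migration-step partition coefficients K_F/layer (= k_layer/k_F) and
## diffusivities (1e-14 m^2/s) for the bag walls in absolute ethanol at 25 C
.migration_params <- data.frame(
  solute = .surrogates$solute,
  T1_K_contact = c(0.16, 0.35, 0.25, 0.30, 0.55, 0.57, 0.20, 0.29, 0.20, 0.45),
  T1_K_barrier = c(0.23, 0.59, 0.31, 0.57, 1.37, 0.97, 0.26, 0.57, 0.38, 0.94),
  T1_D_contact = c(147, 187, 3.71, 97.5, 3.12, 2.52, 10.1, 7.70, 4.11, 1.21),
  T1_D_barrier = c(6.97, 4.07, 0.27, 3.90, 0.23, 0.18, 0.44, 0.22, 0.06, 0.24),
  T2_K_contact = c(0.09, 0.82, 0.14, 0.28, 0.97, 1.12, 0.07, 0.60, 0.52, 0.50),
  T2_K_barrier = c(0.23, 0.59, 0.31, 0.57, 1.37, 0.97, 0.26, 0.57, 0.38, 0.94),
  T2_D_contact = c(209, 122, 8.2, 117, 6.9, 5.39, 13.3, 6.73, 5.78, 2.13),
  T2_D_barrier = c(6.97, 4.07, 0.27, 3.90, 0.23, 0.18, 0.44, 0.22, 0.06, 0.24),
  stringsAsFactors = FALSE)

## bag wall geometries: total thickness (m) and relative layer thicknesses,
## contact side first; step-2 contact areas (m^2, one-sided)
.bag_geometry <- list(
  T1 = list(materials = c("EVA", "EVOH", "EVA"), total = 0.3e-3,
            ratio = c(53, 1, 6), area_step2 = 0.155 * 0.09),
  T2 = list(materials = c("PE", "EVOH", "PE"), total = 0.4e-3,
            ratio = c(10.2, 1, 4.8), area_step2 = 0.13 * 0.11))

## overpackaging: PE/PA6/PE laminate, 0.08 mm, relative thickness 2.3:1:1.3
.overpack_geometry <- list(materials = c("PE", "PA6", "PE"), total = 0.08e-3,
                           ratio = c(2.3, 1, 1.3))

## loading-step parameters at 40 C: k/RT and D (m^2/s) per material, plus
## initial concentrations (kg/m^3) in the overpackaging layers
.loading_params <- list(
  caprolactam = list(
    k_over_RT = c(EVA = 1.83e-7, EVOH_T1 = 3.83e-7, PE = 2.47e-7,
                  EVOH_T2 = 3.83e-7, PA6 = 3.96e-8),
    D = c(EVA = 7.94e-14, EVOH_T1 = 0.34e-14, PE = 10.8e-14,
          EVOH_T2 = 0.34e-14, PA6 = 1.92e-16),
    D_air = c(T1 = 8.12e-6, T2 = 8.12e-6),
    C0_overpack = c(0.58, 3.62, 0.58)),
  BHT = list(
    k_over_RT = c(EVA = 2.37e-6, EVOH_T1 = 2.90e-6, PE = 1.63e-6,
                  EVOH_T2 = 2.90e-6, PA6 = 3.20e-6),
    D = c(EVA = 3.52e-14, EVOH_T1 = 0.24e-14, PE = 9.97e-14,
          EVOH_T2 = 0.33e-14, PA6 = 4.50e-17),
    ## the two printed air diffusivities are stored verbatim
    D_air = c(T1 = 5.29e-6, T2 = 8.12e-6),
    C0_overpack = c(4.0, 2.1, 4.0)))

.loading_temperature <- 313.15   # 40 C
.migration_temperature <- 298.15 # 25 C
.fluid_volume_step2 <- 50e-6     # 50 mL of simulant

#' Built-in scenarios
#'
#' Fully parameterised scenarios for the shipped case studies:
#'
#' * `"S1"`, `"S2"`: dimensionless two-substance didactic cases (direct
#'   contact and air-gap contact followed by a liquid-contact step).  Choose
#'   the substance with `substance = "sB"` (endogenous to the contact-side
#'   material B) or `"sA"` (endogenous to the far material A).
#' * `"T1_caprolactam"`, `"T2_caprolactam"`, `"T1_BHT"`, `"T2_BHT"`:
#'   loading of a multilayer bag by a migrant of the PE/PA6/PE
#'   overpackaging across an air gap, at 40 C.  The gap thickness is
#'   parameterizable from 0 (perfect contact; the air layer is dropped) to
#'   50 mm; the default 0.1 mm matches the conventional air reference of
#'   the resistance tables, placing air at layer index 4 and PA6 at 6.
#' * `"T1_migration_<solute>"`, `"T2_migration_<solute>"`: desorption of a
#'   spiked surrogate from the bag wall into absolute ethanol at 25 C, with
#'   the initial amount distributed at uniform activity across the wall
#'   layers.  See `migration_solutes()` for the solute names.
#'
#' @param name fixture name (case-insensitive).
#' @param air_gap air-gap thickness in m for the loading fixtures
#'   (0 to 0.05).
#' @param duration optional step duration override, s (loading and migration
#'   fixtures: the duration of the single step; S1/S2: the contact step).
#' @return a [scenario()].
#' @export
#' @examples
#' fixture("T1_caprolactam")
#' fixture("S2", substance = "sA")
fixture <- function(name, air_gap = 1e-4, duration = NULL,
                    substance = c("sB", "sA")) {
  substance <- match.arg(substance)
  key <- tolower(name)
  if (key %in% c("s1", "s2"))
    return(fixture_dimensionless(toupper(key), substance, duration))
  m <- regmatches(key, regexec("^(t[12])_(caprolactam|bht)$", key))[[1]]
  if (length(m))
    return(fixture_loading(toupper(m[2]),
                           if (m[3] == "bht") "BHT" else "caprolactam",
                           air_gap, duration))
  m <- regmatches(key, regexec("^(t[12])_migration_(.+)$", key))[[1]]
  if (length(m)) {
    sol <- match_solute(m[3])
    return(fixture_migration(toupper(m[2]), sol, duration))
  }
  stop(sprintf("unknown fixture '%s'", name))
}

#' @rdname fixture
#' @param substance for S1/S2: which substance to simulate.
#' @export
migration_solutes <- function() .surrogates$solute

match_solute <- function(x) {
  key <- gsub("[_ ]", "", tolower(x))
  tab <- gsub("[_ ]", "", tolower(.surrogates$solute))
  i <- match(key, tab)
  if (is.na(i))
    stop(sprintf("unknown solute '%s'; see migration_solutes()", x))
  .surrogates$solute[i]
}

fixture_dimensionless <- function(which, substance, duration) {
  ## dimensionless parameters relative to the contact layer B (j = 1):
  ## l, k, D all 1 in B; the solver is fed the numbers as SI values
  kA  <- if (substance == "sB") 2 else 0.5
  kF  <- if (substance == "sB") 2 else 0.5
  kair <- if (substance == "sB") 1e8 else 1e4
  B <- layer_spec("B", 1, henry_k = 1, D = 1,
                  C0 = if (substance == "sB") 1 else 0)
  A <- layer_spec("A", 0.5, henry_k = kA, D = 0.5,
                  C0 = if (substance == "sA") 1 else 0)
  FL <- fluid_compartment(10, henry_k = kF, Bi = 1000, C0 = 0)
  t2 <- if (is.null(duration)) 400 else duration
  if (which == "S1") {
    steps <- list(
      step_spec(100, assembly(list(B, A))),
      step_spec(t2, assembly(list(B, A), fluid = FL)))
  } else {
    air <- layer_spec("air", 1, henry_k = kair, D = 1e8)
    steps <- list(
      step_spec(100, assembly(list(B, air, A))),
      step_spec(t2, assembly(list(B), fluid = FL),
                transform = list(remove = c(2, 3))))
  }
  scenario(steps, name = sprintf("%s_%s", which, substance))
}

fixture_loading <- function(bag, solute, air_gap, duration) {
  if (air_gap < 0 || air_gap > 0.05)
    stop("air_gap must be between 0 and 0.05 m")
  RT <- henry_air(.loading_temperature)
  p <- .loading_params[[solute]]
  geo <- .bag_geometry[[bag]]
  l_bag <- geo$total * geo$ratio / sum(geo$ratio)
  mat <- geo$materials
  evoh_key <- paste0("EVOH_", bag)
  kname <- function(m) if (m == "EVOH") evoh_key else m
  bag_layers <- lapply(seq_along(mat), function(j) {
    layer_spec(mat[j], l_bag[j],
               henry_k = p$k_over_RT[[kname(mat[j])]] * RT,
               D = p$D[[kname(mat[j])]], C0 = 0)
  })
  op <- .overpack_geometry
  l_op <- op$total * op$ratio / sum(op$ratio)
  op_layers <- lapply(seq_along(op$materials), function(j) {
    layer_spec(op$materials[j], l_op[j],
               henry_k = p$k_over_RT[[op$materials[j]]] * RT,
               D = p$D[[op$materials[j]]], C0 = p$C0_overpack[j])
  })
  layers <- bag_layers
  if (air_gap > 0)
    layers <- c(layers, list(air_layer(air_gap, .loading_temperature,
                                       D = p$D_air[[bag]])))
  layers <- c(layers, op_layers)
  dur <- if (is.null(duration)) 100 * 86400 else duration
  scenario(step_spec(dur, assembly(layers), temperature = .loading_temperature),
           name = sprintf("%s_%s_gap%gmm", bag, solute, air_gap * 1e3))
}

#' Two-step loading-then-migration scenario
#'
#' Chains the loading of a bag by an overpackaging migrant (step 1, 40 C)
#' with the subsequent desorption into the liquid simulant (step 2, 25 C):
#' the overpackaging and the air gap are discarded between the steps, the
#' bag-wall profiles are carried over, and the step-2 sorption/transport
#' parameters of the wall apply from the moment of filling.  This is the
#' configuration used for percentile-based risk evaluation.
#'
#' @param bag `"T1"` or `"T2"`.
#' @param solute a loading migrant with step-2 parameters
#'   (`"caprolactam"` or `"BHT"`).
#' @param air_gap loading air gap, m.
#' @param t1,t2 durations of the loading and migration steps, s.
#' @return a two-step [scenario()].
#' @export
loading_migration_scenario <- function(bag = "T1", solute = "caprolactam",
                                       air_gap = 1e-2, t1 = 7 * 86400,
                                       t2 = 30 * 86400) {
  stopifnot(bag %in% c("T1", "T2"), solute %in% c("caprolactam", "BHT"))
  load_sc <- fixture_loading(bag, solute, air_gap, duration = t1)
  mig_sc <- fixture_migration(bag, solute, duration = t2)
  n_load <- load_sc$steps[[1]]$assembly$m
  scenario(list(load_sc$steps[[1]],
                step_spec(t2, mig_sc$steps[[1]]$assembly,
                          transform = list(remove = 4:n_load),
                          temperature = .migration_temperature)),
           name = sprintf("%s_%s_loading_migration", bag, solute))
}

fixture_migration <- function(bag, solute, duration) {
  geo <- .bag_geometry[[bag]]
  i <- match(solute, .surrogates$solute)
  mp <- .migration_params[i, ]
  Kc <- mp[[paste0(bag, "_K_contact")]]
  Kb <- mp[[paste0(bag, "_K_barrier")]]
  Dc <- mp[[paste0(bag, "_D_contact")]] * 1e-14
  Db <- mp[[paste0(bag, "_D_barrier")]] * 1e-14
  l <- geo$total * geo$ratio / sum(geo$ratio)
  ## activity reference: k_F = 1, so k_layer = K_F/layer
  layers <- list(
    layer_spec(geo$materials[1], l[1], henry_k = Kc, D = Dc),
    layer_spec(geo$materials[2], l[2], henry_k = Kb, D = Db),
    layer_spec(geo$materials[3], l[3], henry_k = Kc, D = Dc))
  l0 <- .fluid_volume_step2 / geo$area_step2
  asm <- assembly(layers,
                  fluid = fluid_compartment(l0, henry_k = 1, Bi = 1000))
  C_avg <- mgkg_to_kgm3(.surrogates[[paste0("C_", bag)]][i])
  asm <- distribute_equilibrium_initial(asm, C_avg * sum(l))
  dur <- if (is.null(duration)) 120 * 86400 else duration
  sol <- solute_spec(solute, .surrogates$molar_mass[i], .surrogates$p_sat[i],
                     molar_volume = 1e-4)
  scenario(step_spec(dur, asm, temperature = .migration_temperature),
           solute = sol, name = sprintf("%s_migration_%s", bag, solute))
}
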