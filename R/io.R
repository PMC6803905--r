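## Configuration I/O: scenarios as YAML (canonical) or JSON, kinetics as
## delimiter-separated text with a provenance header.

.length_units <- c(m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6, nm = 1e-9)
.time_units <- c(s = 1, min = 60, h = 3600, hr = 3600, d = 86400,
                 day = 86400, days = 86400)

parse_quantity <- function(x, type = c("length", "time"), where = "") {
  type <- match.arg(type)
  if (is.numeric(x)) return(x)  # bare numbers are SI
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("%s: expected a number or a \"value unit\" string", where))
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([A-Za-z]+)\\s*$", x))[[1]]
  if (!length(m))
    stop(sprintf("%s: cannot parse quantity '%s'", where, x))
  val <- as.numeric(m[2])
  if (is.na(val)) stop(sprintf("%s: cannot parse number in '%s'", where, x))
  units <- if (type == "length") .length_units else .time_units
  fac <- units[m[3]]
  if (is.na(fac))
    stop(sprintf("%s: unknown %s unit '%s'", where, type, m[3]))
  val * unname(fac)
}

field <- function(lst, name, where, required = TRUE, default = NULL) {
  if (is.null(lst[[name]])) {
    if (required) stop(sprintf("%s: missing required field '%s'", where, name))
    return(default)
  }
  lst[[name]]
}

#' Read a scenario from a YAML or JSON configuration file
#'
#' The canonical configuration format lists the steps with their layers,
#' optional fluid compartment, boundary flag and transformation.  Lengths
#' and durations accept convenience units (`"0.3 mm"`, `"100 d"`); bare
#' numbers are SI (m, s).  Validation errors name the offending field.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return a [scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yml = , yaml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                          simplifyMatrix = FALSE),
                stop(sprintf("unsupported extension '.%s' (use .yaml or .json)",
                             ext)))
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  name <- field(cfg, "name", "scenario", required = FALSE,
                default = "scenario")
  steps_cfg <- field(cfg, "steps", "scenario")
  if (!is.list(steps_cfg) || !length(steps_cfg))
    stop("scenario: 'steps' must be a non-empty list")
  steps <- lapply(seq_along(steps_cfg), function(i) {
    sc <- steps_cfg[[i]]
    w <- sprintf("steps[%d]", i)
    duration <- parse_quantity(field(sc, "duration", w), "time",
                               paste0(w, ".duration"))
    layers_cfg <- field(sc, "layers", w)
    layers <- lapply(seq_along(layers_cfg), function(j) {
      lc <- layers_cfg[[j]]
      wl <- sprintf("%s.layers[%d]", w, j)
      mat <- field(lc, "material", wl)
      layer_spec(
        material = mat,
        thickness = parse_quantity(field(lc, "thickness", wl), "length",
                                   paste0(wl, ".thickness")),
        henry_k = field(lc, "henry_k", paste0(wl, " ('", mat, "')")),
        D = field(lc, "D", paste0(wl, " ('", mat, "')")),
        C0 = field(lc, "C0", wl, required = FALSE, default = 0),
        density = field(lc, "density", wl, required = FALSE, default = 1000))
    })
    fluid <- NULL
    if (!is.null(sc$fluid)) {
      fc <- sc$fluid
      wf <- paste0(w, ".fluid")
      fluid <- fluid_compartment(
        thickness = parse_quantity(field(fc, "thickness", wf), "length",
                                   paste0(wf, ".thickness")),
        henry_k = field(fc, "henry_k", wf),
        Bi = fc[["Bi"]], h = fc[["h"]],
        C0 = field(fc, "C0", wf, required = FALSE, default = 0),
        density = field(fc, "density", wf, required = FALSE, default = 1000))
    }
    boundary <- field(sc, "boundary", w, required = FALSE,
                      default = "impervious")
    transform <- field(sc, "transform", w, required = FALSE,
                       default = "keep")
    step_spec(duration, assembly(layers, fluid = fluid, boundary = boundary),
              transform = transform,
              temperature = sc$temperature)
  })
  solute <- NULL
  if (!is.null(cfg$solute)) {
    so <- cfg$solute
    solute <- solute_spec(field(so, "name", "solute"),
                          field(so, "molar_mass", "solute"),
                          field(so, "p_sat", "solute"),
                          field(so, "molar_volume", "solute"),
                          materials = if (is.null(so$materials)) list()
                          else so$materials)
  }
  scenario(steps, solute = solute, name = name)
}

#' Write a scenario to a YAML or JSON configuration file
#'
#' Canonical units on output are SI (m, s); the file round-trips through
#' [read_scenario()] to an identical scenario.
#'
#' @param sc a [scenario()].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  cfg <- scenario_to_config(sc)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yml = , yaml = yaml::write_yaml(cfg, path, precision = 15),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop(sprintf("unsupported extension '.%s'", ext)))
  invisible(path)
}

scenario_to_config <- function(sc) {
  steps <- lapply(sc$steps, function(st) {
    a <- st$assembly
    out <- list(duration = st$duration)
    tr <- st$transform
    out$transform <- switch(tr$type,
                            keep = "keep",
                            remove = list(remove = tr$layers),
                            equilibrate = if (is.null(tr$subset)) "equilibrate"
                            else list(equilibrate = tr$subset))
    out$boundary <- a$boundary
    if (!is.null(st$temperature)) out$temperature <- st$temperature
    out$layers <- lapply(a$layers, function(l) {
      ll <- list(material = l$material, thickness = l$thickness,
                 henry_k = l$henry_k, D = l$D, C0 = l$C0,
                 density = l$density)
      if (!is.numeric(ll$C0))
        stop("only scalar initial concentrations can be serialised")
      ll
    })
    ## Bi is the canonical serialised form (h is re-derived on assembly)
    if (!is.null(a$fluid))
      out$fluid <- list(thickness = a$fluid$thickness,
                        henry_k = a$fluid$henry_k, Bi = a$fluid$Bi,
                        C0 = a$fluid$C0, density = a$fluid$density)
    out
    out
  })
  cfg <- list(name = sc$name, steps = steps)
  if (!is.null(sc$solute))
    cfg$solute <- list(name = sc$solute$name,
                       molar_mass = sc$solute$molar_mass,
                       p_sat = sc$solute$p_sat,
                       molar_volume = sc$solute$molar_volume,
                       materials = sc$solute$materials)
  cfg
}

#' Write kinetics to delimiter-separated text
#'
#' Columns: time in seconds (and in a convenience unit), per-compartment
#' normalised amounts, total, and the fluid concentration when present.
#' Header comment lines record the scenario identifier, solver tolerances
#' and the seed of the run for provenance.
#'
#' @param x a `kinetics_result` or `step_solution`.
#' @param path output path.
#' @param scenario_name identifier recorded in the header.
#' @param seed seed recorded in the header (NA if none).
#' @param grid the [grid_spec()] used (for tolerance provenance).
#' @param time_unit convenience unit for the second time column.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(x, path, scenario_name = "unknown", seed = NA,
                           grid = grid_spec(), time_unit = "d") {
  kin <- if (inherits(x, "step_solution")) x$kinetics else x
  stopifnot(inherits(kin, "kinetics_result"))
  df <- as.data.frame(kin)
  fac <- .time_units[time_unit]
  if (is.na(fac)) stop(sprintf("unknown time unit '%s'", time_unit))
  df <- cbind(time_s = df$time,
              setNames(data.frame(df$time / fac),
                       paste0("time_", time_unit)),
              df[-1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# crossmigrate kinetics",
               sprintf("# scenario: %s", scenario_name),
               sprintf("# norm_base_kg_m2: %.15g", kin$norm_base),
               sprintf("# rtol: %g  atol_rel: %g", grid$rtol, grid$atol_rel),
               sprintf("# seed: %s", as.character(seed))), con)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = TRUE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read kinetics written by [write_kinetics()] or any time/fraction table
#'
#' Comment lines starting with `#` are collected into the `header`
#' attribute.
#'
#' @param path input path.
#' @return data frame of the table, with attribute `header`.
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  df <- read.csv(text = paste(lines[!hdr], collapse = "\n"))
  attr(df, "header") <- lines[hdr]
  df
}
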