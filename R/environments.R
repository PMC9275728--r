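#' Ocean environment parameter set
#'
#' Bundles the water-side parameters that drive all bubble computations for
#' one ocean environment. All values are strict SI (Pa, kg/m^3, Pa s, N/m,
#' m/s); unit conversion from tabulated conventions (MPa, mPa s, mN/m)
#' happens only at I/O boundaries such as [load_fixture_environments()].
#'
#' @param name Label for the environment (e.g. `"cold_surface"`).
#' @param depth Depth below the surface (m, >= 0).
#' @param temperature Water temperature (degrees C).
#' @param salinity Salinity (g/kg).
#' @param pressure Ambient (hydrostatic + atmospheric) pressure in the
#'   liquid, `P_liq` (Pa).
#' @param density Water density, `rho_liq` (kg/m^3).
#' @param viscosity Dynamic (shear) viscosity of the water, `eta_s` (Pa s).
#' @param surface_tension Water surface tension, `tau` (N/m).
#' @param sound_speed Speed of sound in the water, `c` (m/s).
#'
#' @return An object of class `"ocean_environment"` (a named list of the
#'   arguments).
#' @seealso [gas_properties()], [bubble_spec()], [load_fixture_environments()]
#' @export
#' @examples
#' warm <- ocean_environment("warm_surface", depth = 0, temperature = 20,
#'                           salinity = 35, pressure = 101325, density = 1028,
#'                           viscosity = 1.077e-3, surface_tension = 73.52e-3,
#'                           sound_speed = 1522)
ocean_environment <- function(name, depth, temperature, salinity, pressure,
                              density, viscosity, surface_tension,
                              sound_speed) {
  stopifnot(is.character(name), length(name) == 1L)
  num <- c(depth = depth, temperature = temperature, salinity = salinity,
           pressure = pressure, density = density, viscosity = viscosity,
           surface_tension = surface_tension, sound_speed = sound_speed)
  if (!all(is.finite(num)))
    stop("all environment parameters must be finite numbers")
  if (depth < 0) stop("depth must be >= 0")
  pos <- c("pressure", "density", "viscosity", "surface_tension",
           "sound_speed")
  bad <- pos[num[pos] <= 0]
  if (length(bad))
    stop("environment parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  num <- as.numeric(num)   # integer columns from CSVs become doubles
  structure(list(name = name, depth = num[1], temperature = num[2],
                 salinity = num[3], pressure = num[4], density = num[5],
                 viscosity = num[6], surface_tension = num[7],
                 sound_speed = num[8]),
            class = "ocean_environment")
}

#' @export
print.ocean_environment <- function(x, ...) {
  cat(sprintf("<ocean_environment> %s (depth %g m, %g degC)\n", x$name,
              x$depth, x$temperature))
  cat(sprintf("  P_liq = %g Pa, rho = %g kg/m^3, eta_s = %g Pa s\n",
              x$pressure, x$density, x$viscosity))
  cat(sprintf("  tau = %g N/m, c = %g m/s, S = %g g/kg\n",
              x$surface_tension, x$sound_speed, x$salinity))
  invisible(x)
}

#' Thermodynamic properties of a bubble gas
#'
#' @param gas Gas label, `"N2"` or `"O2"` (other labels are allowed for
#'   synthetic test gases).
#' @param gamma Ratio of specific heats (> 1, dimensionless). Controls the
#'   adiabatic stiffness of the gas and the span of the complex polytropic
#'   index between its isothermal (1) and adiabatic (`gamma`) limits.
#' @param thermal_diffusivity Equilibrium thermal diffusivity `D_p` of the
#'   gas at ambient conditions (m^2/s, > 0). Sets the thermal diffusion
#'   length and thereby the thermal damping.
#'
#' @return An object of class `"gas_properties"`.
#' @export
gas_properties <- function(gas, gamma, thermal_diffusivity) {
  stopifnot(is.character(gas), length(gas) == 1L)
  if (!is.finite(gamma) || gamma <= 1)
    stop("gamma must be a finite number > 1")
  if (!is.finite(thermal_diffusivity) || thermal_diffusivity <= 0)
    stop("thermal_diffusivity must be a finite number > 0")
  structure(list(gas = gas, gamma = as.numeric(gamma),
                 thermal_diffusivity = as.numeric(thermal_diffusivity)),
            class = "gas_properties")
}

#' @export
print.gas_properties <- function(x, ...) {
  cat(sprintf("<gas_properties> %s: gamma = %g, D_p = %g m^2/s\n",
              x$gas, x$gamma, x$thermal_diffusivity))
  invisible(x)
}

# Expected column layout of the shipped environment fixture table.
.fixture_columns <- c("name", "depth_m", "temperature_C", "salinity_g_kg",
                      "pressure_MPa", "density_kg_m3", "viscosity_mPa_s",
                      "surface_tension_mN_m", "sound_speed_m_s",
                      "gamma_N2", "gamma_O2",
                      "thermal_diffusivity_N2_1e9_m2_s",
                      "thermal_diffusivity_O2_1e9_m2_s")

#' Load the five shipped ocean environments
#'
#' Reads the package's environment fixture table (five ocean environments:
#' warm surface, cold surface, and cold water at 1000 m, 2000 m and 3500 m
#' depth; tabulated in the conventional units MPa, mPa s, mN/m and
#' 1e-9 m^2/s) and returns every environment paired with each of the two
#' swim-bladder gases, nitrogen and oxygen, converted to SI.
#'
#' @param path Path to a fixture CSV. Defaults to the table shipped with the
#'   package.
#' @return A named list of 10 pairs, each a list with elements `environment`
#'   (an [ocean_environment()]) and `gas` (a [gas_properties()]). Names are
#'   `"<environment>.<gas>"`, e.g. `"cold_surface.N2"`.
#' @export
#' @examples
#' fx <- load_fixture_environments()
#' fx[["warm_surface.N2"]]$environment$pressure  # 101325 Pa
load_fixture_environments <- function(path = system.file(
    "extdata", "table1_environments.csv", package = "bubbleacoustics")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.fixture_columns, names(tab))
  if (length(missing))
    stop("fixture table is missing columns: ", paste(missing, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    env <- ocean_environment(
      name = row$name, depth = row$depth_m,
      temperature = row$temperature_C, salinity = row$salinity_g_kg,
      pressure = row$pressure_MPa * 1e6,          # MPa -> Pa
      density = row$density_kg_m3,
      viscosity = row$viscosity_mPa_s * 1e-3,     # mPa s -> Pa s
      surface_tension = row$surface_tension_mN_m * 1e-3,  # mN/m -> N/m
      sound_speed = row$sound_speed_m_s)
    for (gas in c("N2", "O2")) {
      gp <- gas_properties(
        gas, gamma = row[[paste0("gamma_", gas)]],
        thermal_diffusivity =
          row[[paste0("thermal_diffusivity_", gas, "_1e9_m2_s")]] * 1e-9)
      out[[paste(row$name, gas, sep = ".")]] <-
        list(environment = env, gas = gp)
    }
  }
  out
}

#' Equilibrium gas pressure inside a bubble
#'
#' The gas pressure of a bubble of radius `R0` in mechanical equilibrium,
#' including the Laplace surface-tension overpressure:
#' `P_gas = P_liq + 2 tau / R0`. At swim-bladder radii (centimetres) the
#' Laplace term is below 0.02% of the ambient pressure even at the surface,
#' so results are insensitive to `laplace`.
#'
#' @param env An [ocean_environment()].
#' @param R0 Equilibrium bubble radius (m, > 0).
#' @param laplace Include the `2 tau / R0` Laplace term? Default `TRUE`.
#' @return Gas pressure (Pa).
#' @export
laplace_gas_pressure <- function(env, R0, laplace = TRUE) {
  stopifnot(inherits(env, "ocean_environment"))
  if (!is.numeric(R0) || any(!is.finite(R0)) || any(R0 <= 0))
    stop("R0 must be > 0")
  if (laplace) env$pressure + 2 * env$surface_tension / R0 else env$pressure
}

# -- depth profiles ----------------------------------------------------------

# SI column layout for user-supplied property-vs-depth tables; the gamma_*
# and thermal_diffusivity_* columns may appear for one or both gases.
.profile_fixed_columns <- c("depth_m", "temperature_C", "salinity_g_kg",
                            "pressure_Pa", "density_kg_m3", "viscosity_Pa_s",
                            "surface_tension_N_m", "sound_speed_m_s")

#' Read a property-vs-depth table
#'
#' Parses a CSV of water and gas properties on a strictly increasing depth
#' grid into a `property_profile`. Columns are in SI:
#' `depth_m, temperature_C, salinity_g_kg, pressure_Pa, density_kg_m3,
#' viscosity_Pa_s, surface_tension_N_m, sound_speed_m_s`, plus
#' `gamma_<gas>` and `thermal_diffusivity_<gas>_m2_s` for each gas present
#' (`<gas>` in `N2`, `O2`). Intermediate depths are later obtained by cubic
#' spline interpolation via [interpolate_profile()].
#'
#' @param path Path to the CSV file.
#' @return An object of class `"property_profile"`: the validated data frame
#'   plus the vector of gases it covers.
#' @export
read_property_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_property_profile(tab)
}

#' Build a property profile from a data frame
#'
#' Validates a data frame in the layout of [read_property_table()] and
#' returns a `property_profile`. Useful for profiles constructed in code,
#' e.g. from the shipped fixtures (see [fixture_profile()]).
#'
#' @param tab A data frame with the columns documented in
#'   [read_property_table()].
#' @return A `"property_profile"` object.
#' @export
as_property_profile <- function(tab) {
  missing <- setdiff(.profile_fixed_columns, names(tab))
  if (length(missing))
    stop("property table is missing columns: ",
         paste(missing, collapse = ", "))
  gases <- character()
  for (gas in c("N2", "O2")) {
    gcol <- paste0("gamma_", gas)
    dcol <- paste0("thermal_diffusivity_", gas, "_m2_s")
    if (gcol %in% names(tab) && dcol %in% names(tab)) gases <- c(gases, gas)
  }
  if (!length(gases))
    stop("property table must contain gamma_<gas> and ",
         "thermal_diffusivity_<gas>_m2_s for at least one of N2, O2")
  d <- tab$depth_m
  if (nrow(tab) < 2L) stop("property table needs at least two depth rows")
  if (any(diff(d) <= 0))
    stop("depth_m must be strictly increasing (duplicate or decreasing ",
         "depth at row ", which(diff(d) <= 0)[1] + 1L, ")")
  phys <- c("pressure_Pa", "density_kg_m3", "viscosity_Pa_s",
            "surface_tension_N_m", "sound_speed_m_s",
            paste0("gamma_", gases),
            paste0("thermal_diffusivity_", gases, "_m2_s"))
  for (col in phys) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] <= 0)
    if (length(bad))
      stop("non-positive or missing value in column '", col, "' at row ",
           bad[1])
  }
  structure(list(table = tab[order(d), , drop = FALSE], gases = gases),
            class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  d <- x$table$depth_m
  cat(sprintf("<property_profile> %d depths, %g-%g m, gases: %s\n",
              length(d), min(d), max(d), paste(x$gases, collapse = ", ")))
  invisible(x)
}

#' Interpolate a property profile at a depth
#'
#' Cubic-spline interpolation (via [stats::splinefun()], method `"fmm"`) of
#' every property column at the requested depth. At a grid node the node's
#' values are returned unchanged; extrapolation outside the grid is refused.
#' Thermal diffusivity falls by two orders of magnitude over the first
#' kilometre, so that column alone is splined on the log scale
#' (`exp(spline(log(D_p)))`), which keeps the interpolant positive and is
#' still exact at the nodes; all other columns are splined linearly.
#'
#' @param profile A `"property_profile"` from [read_property_table()].
#' @param depth Query depth (m), within the profile's depth range.
#' @param gas Which gas columns to use; defaults to the first gas in the
#'   profile.
#' @return A list with elements `environment` ([ocean_environment()]) and
#'   `gas` ([gas_properties()]) at the query depth.
#' @export
interpolate_profile <- function(profile, depth, gas = profile$gases[1]) {
  stopifnot(inherits(profile, "property_profile"), length(depth) == 1L)
  gas <- match.arg(gas, profile$gases)
  tab <- profile$table
  d <- tab$depth_m
  if (depth < d[1] || depth > d[length(d)])
    stop(sprintf("depth %g m outside profile range [%g, %g] m: refusing to extrapolate",
                 depth, d[1], d[length(d)]))
  dcol <- paste0("thermal_diffusivity_", gas, "_m2_s")
  cols <- c(.profile_fixed_columns[-1], paste0("gamma_", gas), dcol)
  at <- vapply(cols, function(col) {
    y <- tab[[col]]
    if (col == dcol)
      exp(stats::splinefun(d, log(y), method = "fmm")(depth))
    else
      stats::splinefun(d, y, method = "fmm")(depth)
  }, numeric(1))
  env <- ocean_environment(
    name = sprintf("profile_%gm", depth), depth = depth,
    temperature = at[["temperature_C"]], salinity = at[["salinity_g_kg"]],
    pressure = at[["pressure_Pa"]], density = at[["density_kg_m3"]],
    viscosity = at[["viscosity_Pa_s"]],
    surface_tension = at[["surface_tension_N_m"]],
    sound_speed = at[["sound_speed_m_s"]])
  gp <- gas_properties(gas, gamma = at[[paste0("gamma_", gas)]],
                       thermal_diffusivity =
                         at[[paste0("thermal_diffusivity_", gas, "_m2_s")]])
  list(environment = env, gas = gp)
}

#' Constant-temperature depth profile from the shipped fixtures
#'
#' Builds a `property_profile` from the four cold (1.5 degC, 35 g/kg)
#' fixture environments (0, 1000, 2000 and 3500 m), for both gases. This is
#' the profile used by the depth-resolved analyses when no user table is
#' supplied; it isolates the effect of depth (pressure) at constant
#' temperature and salinity.
#'
#' @return A `"property_profile"` covering 0-3500 m.
#' @export
fixture_profile <- function() {
  fx <- load_fixture_environments()
  envs <- c("cold_surface", "depth_1000m", "depth_2000m", "depth_3500m")
  rows <- lapply(envs, function(e) {
    env <- fx[[paste0(e, ".N2")]]$environment
    data.frame(
      depth_m = env$depth, temperature_C = env$temperature,
      salinity_g_kg = env$salinity, pressure_Pa = env$pressure,
      density_kg_m3 = env$density, viscosity_Pa_s = env$viscosity,
      surface_tension_N_m = env$surface_tension,
      sound_speed_m_s = env$sound_speed,
      gamma_N2 = fx[[paste0(e, ".N2")]]$gas$gamma,
      thermal_diffusivity_N2_m2_s =
        fx[[paste0(e, ".N2")]]$gas$thermal_diffusivity,
      gamma_O2 = fx[[paste0(e, ".O2")]]$gas$gamma,
      thermal_diffusivity_O2_m2_s =
        fx[[paste0(e, ".O2")]]$gas$thermal_diffusivity)
  })
  as_property_profile(do.call(rbind, rows))
}
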