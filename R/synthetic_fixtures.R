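#' The ten shipped environment/gas fixtures
#'
#' Alias of [load_fixture_environments()]: the five ocean environments
#' paired with nitrogen and oxygen, in SI units. These pairs are the study
#' conditions every resonance and depth analysis in the package is run
#' against.
#'
#' @return A named list of 10 `list(environment, gas)` pairs.
#' @export
table1_fixtures <- function() load_fixture_environments()

#' Seeded perturbations of the fixture parameter sets
#'
#' Deterministic generator of randomised bubble specifications for
#' property-based testing: each draw picks one of the ten fixtures,
#' log-uniform radius `R0` in [0.005, 0.25] m, and applies independent
#' multiplicative perturbations uniform in [0.8, 1.2] to every physical
#' water and gas property (keeping `gamma > 1` by perturbing `gamma - 1`).
#' The same seed always yields the identical list.
#'
#' @param seed Integer seed for the generator.
#' @param n Number of specs to generate (> 0).
#' @return A list of `n` [bubble_spec()] objects.
#' @export
perturbed_specs <- function(seed, n) {
  stopifnot(n > 0)
  fx <- table1_fixtures()
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  lapply(seq_len(n), function(i) {
      base <- fx[[sample.int(length(fx), 1)]]
      R0 <- exp(stats::runif(1, log(0.005), log(0.25)))
      p <- function(x) x * stats::runif(1, 0.8, 1.2)
      env <- base$environment
      env2 <- ocean_environment(
        name = paste0(env$name, "_perturbed"), depth = env$depth,
        temperature = env$temperature, salinity = env$salinity,
        pressure = p(env$pressure), density = p(env$density),
        viscosity = p(env$viscosity),
        surface_tension = p(env$surface_tension),
        sound_speed = p(env$sound_speed))
      gas2 <- gas_properties(
        base$gas$gas, gamma = 1 + p(base$gas$gamma - 1),
        thermal_diffusivity = p(base$gas$thermal_diffusivity))
      bubble_spec(R0, env2, gas2)
  })
}

#' Limit-case bubble specifications
#'
#' Hand-built specs that push the model into its closed-form corners, for
#' limit tests: `minnaert` (zero surface tension, huge thermal diffusivity
#' forcing the adiabatic limit, tiny radius-to-wavelength ratio so that
#' radiation terms vanish and the far-field resonance collapses onto the
#' Minnaert frequency), `isothermal` (tiny diffusivity, `X -> 0`,
#' `Re Gamma -> 1`), and `no_radiation` (enormous sound speed, `eps -> 0`,
#' `beta_ac -> 0`).
#'
#' @return A named list of [bubble_spec()] objects with elements
#'   `minnaert`, `isothermal`, `no_radiation`.
#' @export
limit_cases <- function() {
  base <- ocean_environment("limit_base", depth = 0, temperature = 10,
                            salinity = 35, pressure = 101325,
                            density = 1025, viscosity = 1e-3,
                            surface_tension = 0.075, sound_speed = 1500)
  no_tension <- base
  no_tension$surface_tension <- 1e-300   # tau -> 0 (type requires > 0)
  huge_c <- base
  huge_c$sound_speed <- 1e12
  list(
    minnaert = {
      env <- no_tension
      env$sound_speed <- 1e12
      # tiny thermal diffusivity -> X -> Inf -> adiabatic Gamma -> gamma
      bubble_spec(1e-3, env,
                  gas_properties("synthetic", gamma = 1.4,
                                 thermal_diffusivity = 1e-18),
                  laplace = FALSE)
    },
    isothermal = bubble_spec(
      0.05, base,
      gas_properties("synthetic", gamma = 1.4,
                     thermal_diffusivity = 1e3)),
    no_radiation = bubble_spec(
      0.05, huge_c,
      gas_properties("synthetic", gamma = 1.4,
                     thermal_diffusivity = 1.9e-8)))
}
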