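#' Bubble specification
#'
#' Binds an equilibrium radius to an ocean environment and a bubble gas and
#' derives, once, the equilibrium gas pressure (see
#' [laplace_gas_pressure()]). All frequency-dependent quantities of the
#' driven-bubble model are evaluated against such a spec.
#'
#' @param R0 Equilibrium bubble radius (m, > 0). Swim-bladder scale is
#'   roughly 0.01-0.20 m.
#' @param environment An [ocean_environment()].
#' @param gas A [gas_properties()].
#' @param laplace Include the Laplace surface-tension overpressure in the
#'   equilibrium gas pressure? Default `TRUE`; negligible at the radii
#'   studied.
#' @return An object of class `"bubble_spec"` with fields `R0`,
#'   `environment`, `gas` and the derived `P_gas` (Pa).
#' @export
#' @examples
#' fx <- load_fixture_environments()
#' spec <- bubble_spec(0.05, fx[["cold_surface.N2"]]$environment,
#'                     fx[["cold_surface.N2"]]$gas)
#' minnaert_frequency(spec)
bubble_spec <- function(R0, environment, gas, laplace = TRUE) {
  stopifnot(inherits(environment, "ocean_environment"),
            inherits(gas, "gas_properties"))
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("R0 must be a single finite number > 0")
  structure(list(R0 = R0, environment = environment, gas = gas,
                 P_gas = laplace_gas_pressure(environment, R0, laplace)),
            class = "bubble_spec")
}

#' @export
print.bubble_spec <- function(x, ...) {
  cat(sprintf("<bubble_spec> R0 = %g m, %s bubble in %s (P_gas = %g Pa)\n",
              x$R0, x$gas$gas, x$environment$name, x$P_gas))
  invisible(x)
}

#' Minnaert frequency of a bubble
#'
#' Closed-form natural frequency of a bubble that is large on the thermal
#' and Laplace scales, `omega_M = (1/R0) sqrt(3 gamma P_liq / rho_liq)`.
#' It is the classic zeroth-order estimate against which the numerically
#' solved resonances are compared.
#'
#' @param spec A [bubble_spec()].
#' @return `minnaert_omega()` returns the angular frequency (rad/s);
#'   `minnaert_frequency()` returns `omega_M / (2 pi)` in Hz.
#' @export
minnaert_omega <- function(spec) {
  stopifnot(inherits(spec, "bubble_spec"))
  env <- spec$environment
  sqrt(3 * spec$gas$gamma * env$pressure / env$density) / spec$R0
}

#' @rdname minnaert_omega
#' @export
minnaert_frequency <- function(spec) minnaert_omega(spec) / (2 * pi)

# Complex polytropic index as a function of gamma and the thermal diffusion
# ratio X = R0 / l_th, with z = (1 + i) X / 2:
#
#   Gamma = gamma / (1 - (z / tanh(z) - 1) * 6i (gamma - 1) / X^2)
#
# Numerics: for X/2 > 40, tanh(z) is 1 to double precision, so z/tanh(z)-1
# is replaced by z - 1 (complex tanh overflows near Re z ~ 350); for
# X < 1e-3 the subtraction z/tanh(z) - 1 loses all digits and the series
# z^2/3 - z^4/45 is used instead. Both branches preserve the isothermal
# (Gamma -> 1 as X -> 0) and adiabatic (Gamma -> gamma as X -> Inf) limits.
polytropic_index <- function(gamma, X) {
  z <- complex(real = X / 2, imaginary = X / 2)
  f <- complex(length(X))
  hi <- X > 80
  lo <- X < 1e-3
  mid <- !hi & !lo
  f[hi] <- z[hi] - 1
  f[lo] <- z[lo]^2 / 3 - z[lo]^4 / 45
  f[mid] <- z[mid] / tanh(z[mid]) - 1
  gamma / (1 - f * 6i * (gamma - 1) / X^2)
}

#' Thermal state of a driven bubble
#'
#' Evaluates, at driving angular frequency `omega`, the thermal diffusion
#' length `l_th = sqrt(D_p / (2 omega))`, the thermal diffusion ratio
#' `X = R0 / l_th`, and the complex polytropic index `Gamma(omega)`.
#' `Re(Gamma)` interpolates between the isothermal value 1 (small `X`) and
#' the adiabatic value `gamma` (large `X`); `Im(Gamma) >= 0` generates the
#' thermal damping.
#'
#' @param spec A [bubble_spec()].
#' @param omega Driving angular frequency (rad/s, > 0). Vectorised.
#' @return A data frame with columns `omega`, `l_th`, `X`, and the complex
#'   column `Gamma`.
#' @export
thermal_state <- function(spec, omega) {
  stopifnot(inherits(spec, "bubble_spec"))
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be > 0")
  l_th <- sqrt(spec$gas$thermal_diffusivity / (2 * omega))
  X <- spec$R0 / l_th
  data.frame(omega = omega, l_th = l_th, X = X,
             Gamma = polytropic_index(spec$gas$gamma, X))
}

#' Frequency-dependent resonance parameter omega_0^2
#'
#' The square of the frequency-dependent parameter `omega_0` entering the
#' stiffness and the scattering cross-section:
#' `omega_0^2 = 3 Re(Gamma(omega)) P_gas / (rho_liq R0^2)
#'              - 2 tau / (rho_liq R0^3)`.
#' In the adiabatic limit with zero surface tension and `P_gas = P_liq`
#' this reduces to the square of the Minnaert angular frequency.
#'
#' @inheritParams thermal_state
#' @return `omega_0^2` (rad^2/s^2). Vectorised over `omega`.
#' @export
omega0_squared <- function(spec, omega) {
  ts <- thermal_state(spec, omega)
  env <- spec$environment
  w0sq <- 3 * Re(ts$Gamma) * spec$P_gas / (env$density * spec$R0^2) -
    2 * env$surface_tension / (env$density * spec$R0^3)
  if (any(w0sq <= 0))
    stop("omega_0^2 <= 0: parameters outside the model's validity range")
  w0sq
}

#' Bubble stiffness
#'
#' The frequency-dependent stiffness of the driven bubble,
#' `K(omega) = omega_0^2(omega) + omega^2 epsilon^2 / (1 + epsilon^2)`,
#' with the dimensionless frequency `epsilon = omega R0 / c`. `K` plays the
#' role of the squared undamped frequency of a mass-spring oscillator; its
#' own frequency dependence is why the resonance frequencies below are
#' solutions of implicit equations.
#'
#' @inheritParams thermal_state
#' @return Stiffness `K` (rad^2/s^2). Vectorised over `omega`.
#' @export
stiffness_K <- function(spec, omega) {
  eps <- omega * spec$R0 / spec$environment$sound_speed
  omega0_squared(spec, omega) + eps^2 / (1 + eps^2) * omega^2
}

#' Damping decomposition of a driven bubble
#'
#' The damping factor `beta` (rad/s) decomposed into its three mechanisms:
#' thermal conduction `beta_th = 3 P_gas Im(Gamma) / (2 rho_liq R0^2 omega)`,
#' viscosity `beta_vis = 2 eta_s / (rho_liq R0^2)`, and acoustic radiation
#' `beta_ac = (omega / 2) epsilon / (1 + epsilon^2)`. The non-acoustic part
#' is `beta_0 = beta_th + beta_vis` and the total is
#' `beta = beta_0 + beta_ac`. All parts are non-negative; thermal damping
#' dominates at low frequency and radiation at high frequency.
#'
#' @inheritParams thermal_state
#' @return A data frame with columns `omega`, `beta_th`, `beta_vis`,
#'   `beta_ac`, `beta0`, `beta`.
#' @export
damping <- function(spec, omega) {
  ts <- thermal_state(spec, omega)
  env <- spec$environment
  eps <- omega * spec$R0 / env$sound_speed
  beta_th <- 3 * spec$P_gas * Im(ts$Gamma) /
    (2 * env$density * spec$R0^2 * omega)
  beta_vis <- rep_len(2 * env$viscosity / (env$density * spec$R0^2),
                      length(omega))
  beta_ac <- (omega / 2) * eps / (1 + eps^2)
  beta0 <- beta_th + beta_vis
  data.frame(omega = omega, beta_th = beta_th, beta_vis = beta_vis,
             beta_ac = beta_ac, beta0 = beta0, beta = beta0 + beta_ac)
}

#' Scattering cross-section of a driven bubble
#'
#' The scattering cross-section (ratio of scattered to incident power for
#' an incident plane wave; a proxy for how efficiently a driven bladder
#' radiates to the far field):
#' \deqn{\sigma_s = \frac{4 \pi R_0^2}{(\omega_0^2/\omega^2 - 1 -
#'   2\beta_0\epsilon/\omega)^2 + (2\beta_0/\omega +
#'   (\omega_0^2/\omega^2)\epsilon)^2}}
#' Only the non-acoustic damping `beta_0` appears explicitly; radiation
#' loss enters through the `epsilon` terms. The normalised cross-section is
#' `sigma_s_norm = sigma_s / (4 pi R0^2)`, which makes bubbles of different
#' radii comparable.
#'
#' @inheritParams thermal_state
#' @return A data frame (one row per `omega`) with columns `omega`, `eps`,
#'   `omega0_sq`, `K`, `sigma_s` (m^2) and `sigma_s_norm` (dimensionless).
#' @export
scattering_cross_section <- function(spec, omega) {
  env <- spec$environment
  eps <- omega * spec$R0 / env$sound_speed
  w0sq <- omega0_squared(spec, omega)
  K <- w0sq + eps^2 / (1 + eps^2) * omega^2
  b0 <- damping(spec, omega)$beta0
  r <- w0sq / omega^2
  denom <- (r - 1 - 2 * b0 * eps / omega)^2 + (2 * b0 / omega + r * eps)^2
  sigma_norm <- 1 / denom
  data.frame(omega = omega, eps = eps, omega0_sq = w0sq, K = K,
             sigma_s = 4 * pi * spec$R0^2 * sigma_norm,
             sigma_s_norm = sigma_norm)
}

#' Sampled frequency-response curve
#'
#' Convenience wrapper sampling the full response of a bubble over a
#' frequency grid: stiffness, damping decomposition and scattering
#' cross-section, plus the frequency axis in Hz and normalised to the
#' undamped resonance (`fprime = f / f_und`).
#'
#' @param spec A [bubble_spec()].
#' @param fprime Normalised frequency grid (dimensionless, > 0). Default
#'   samples 0.8-1.2 around the resonance.
#' @return A data frame with columns `f`, `fprime`, `omega`, `K`,
#'   `beta_th`, `beta_vis`, `beta_ac`, `beta0`, `beta`, `sigma_s`,
#'   `sigma_s_norm`.
#' @export
response_curve <- function(spec, fprime = seq(0.8, 1.2, length.out = 401)) {
  w_und <- solve_undamped(spec)$omega
  omega <- fprime * w_und
  dmp <- damping(spec, omega)
  sc <- scattering_cross_section(spec, omega)
  data.frame(f = omega / (2 * pi), fprime = fprime, omega = omega,
             K = sc$K, beta_th = dmp$beta_th, beta_vis = dmp$beta_vis,
             beta_ac = dmp$beta_ac, beta0 = dmp$beta0, beta = dmp$beta,
             sigma_s = sc$sigma_s, sigma_s_norm = sc$sigma_s_norm)
}
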