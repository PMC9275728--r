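test_that("complex polytropic index hits its isothermal and adiabatic limits", {
  for (gamma in seq(1.3, 2.0, by = 0.1)) {
    expect_lt(Mod(bubbleacoustics:::polytropic_index(gamma, 1e-6) - 1), 1e-6)
    expect_lt(Mod(bubbleacoustics:::polytropic_index(gamma, 1e9) - gamma),
              1e-6)
  }
})

test_that("polytropic index matches 50-digit arbitrary-precision values", {
  # reference values evaluated with mpmath at 50 significant digits
  cases <- list(
    list(gamma = 1.4, X = 10,
         ref = complex(real = 1.24088965759736034,
                       imaginary = 0.106345579870577171)),
    list(gamma = 1.95, X = 0.5,
         ref = complex(real = 1.00003184658167431,
                       imaginary = 0.00405955045994640241)),
    list(gamma = 1.76, X = 1000,
         ref = complex(real = 1.75598727784129719,
                       imaginary = 0.00398655434757872179)))
  for (cs in cases) {
    got <- bubbleacoustics:::polytropic_index(cs$gamma, cs$X)
    expect_lt(Mod(got - cs$ref) / Mod(cs$ref), 1e-12)
  }
})

test_that("thermal state reports near-adiabatic gas at the surface", {
  # surface thermal diffusivities (~2e-5 m^2/s) put X in the 10-1000 range
  # at audio frequencies for a 0.01 m bubble, so Re Gamma sits close to gamma
  spec <- fixture_spec("cold_surface", "N2", 0.01)
  ts <- thermal_state(spec, 2 * pi * c(100, 300, 1000))
  expect_true(all(ts$X > 10 & ts$X < 1e3))
  expect_true(all(Re(ts$Gamma) > 0.9 * spec$gas$gamma))
  expect_true(all(Im(ts$Gamma) >= 0))
  expect_true(all(Re(ts$Gamma) <= spec$gas$gamma + 1e-9))
  expect_error(thermal_state(spec, -5), "omega")
})

test_that("Minnaert frequency has the closed form and its scalings", {
  spec <- fixture_spec("warm_surface", "N2", 0.01)
  expect_equal(minnaert_frequency(spec), 323.937760569, tolerance = 1e-9)
  expect_equal(minnaert_omega(fixture_spec("warm_surface", "N2", 0.02)),
               minnaert_omega(spec) / 2)
  env4 <- spec$environment
  env4$pressure <- 4 * env4$pressure
  spec4 <- bubble_spec(0.01, env4, spec$gas)
  expect_equal(minnaert_omega(spec4), 2 * minnaert_omega(spec))
})

test_that("omega_0^2 reduces to the Minnaert form in the adiabatic limit", {
  lc <- limit_cases()
  spec <- lc$minnaert   # tau ~ 0, adiabatic, P_gas = P_liq
  w <- minnaert_omega(spec)
  expect_equal(omega0_squared(spec, w), w^2, tolerance = 1e-6)

  # the surface-tension term is ~143 s^-2, minuscule next to omega_M^2
  warm <- fixture_spec("warm_surface", "N2", 0.01)
  tension_term <- 2 * warm$environment$surface_tension /
    (warm$environment$density * warm$R0^3)
  expect_equal(tension_term, 2 * 0.07352 / (1028 * 1e-6), tolerance = 1e-12)
  expect_lt(tension_term / minnaert_omega(warm)^2, 1e-3)

  # monotone in P_gas at fixed frequency
  w <- minnaert_omega(warm)
  hi <- warm; hi$P_gas <- warm$P_gas * 1.3
  expect_gt(omega0_squared(hi, w), omega0_squared(warm, w))
})

test_that("stiffness interpolates between omega_0^2 and its radiation limit", {
  spec <- fixture_spec("cold_surface", "N2", 0.05)
  w_small <- 1e-3   # eps ~ 3e-8: K -> omega_0^2
  expect_equal(stiffness_K(spec, w_small), omega0_squared(spec, w_small),
               tolerance = 1e-10)
  # large eps: K - omega_0^2 -> omega^2
  w_big <- 1e9
  expect_equal((stiffness_K(spec, w_big) - omega0_squared(spec, w_big)) /
                 w_big^2, 1, tolerance = 1e-4)
})

test_that("full pipeline matches frozen arbitrary-precision evaluation", {
  # N2 bubble, 3500 m environment, R0 = 0.05 m, omega = 8000 rad/s;
  # reference computed with mpmath at 50 digits through the same formulae
  spec <- fixture_spec("depth_3500m", "N2", 0.05)
  w <- 8000
  expect_equal(stiffness_K(spec, w), 76285467.9988086161, tolerance = 1e-12)
  d <- damping(spec, w)
  expect_equal(d$beta_th, 0.50173912046775737, tolerance = 1e-12)
  expect_equal(d$beta_vis, 0.00138983700862895494, tolerance = 1e-12)
  expect_equal(d$beta_ac, 986.715785499964202, tolerance = 1e-12)
  expect_equal(scattering_cross_section(spec, w)$sigma_s_norm,
               9.56321578214008808, tolerance = 1e-12)
})

test_that("damping decomposition is exact, non-negative, with a crossover", {
  for (name in fixture_names) {
    for (gas in c("N2", "O2")) {
      spec <- fixture_spec(name, gas, 0.05)
      wu <- solve_undamped(spec)$omega
      w <- exp(seq(log(1e-2 * wu), log(1e2 * wu), length.out = 60))
      d <- damping(spec, w)
      expect_true(all(d$beta_th >= 0))
      expect_true(all(d$beta_vis >= 0))
      expect_true(all(d$beta_ac >= 0))
      expect_identical(d$beta, d$beta0 + d$beta_ac)
      expect_identical(d$beta0, d$beta_th + d$beta_vis)
      # thermal dominates at the low end, radiation at the high end
      expect_gt(d$beta_th[1], d$beta_ac[1])
      expect_gt(d$beta_ac[60], d$beta_th[60])
    }
  }
})

test_that("viscous damping is negligible at swim-bladder scale", {
  spec <- fixture_spec("cold_surface", "N2", 0.10)
  d <- damping(spec, solve_undamped(spec)$omega)
  expect_equal(d$beta_vis, 2 * 1.812e-3 / (1027 * 0.01), tolerance = 1e-12)
  expect_lt(d$beta_vis / d$beta, 1e-2)
})

test_that("radiation damping approaches omega * eps / 2 for small eps", {
  spec <- fixture_spec("cold_surface", "N2", 0.05)
  w <- 1e-2 * solve_undamped(spec)$omega
  eps <- w * spec$R0 / spec$environment$sound_speed
  expect_equal(damping(spec, w)$beta_ac, w * eps / 2, tolerance = 1e-4)
})

test_that("normalisation identity sigma_s = 4 pi R0^2 sigma_s' holds exactly", {
  for (spec in perturbed_specs(seed = 11, n = 12)) {
    w <- minnaert_omega(spec) * c(0.3, 1, 3)
    sc <- scattering_cross_section(spec, w)
    expect_identical(sc$sigma_s, 4 * pi * spec$R0^2 * sc$sigma_s_norm)
  }
})

test_that("scattering cross-section has the correct high-frequency limit", {
  spec <- fixture_spec("cold_surface", "N2", 0.05)
  w <- 1e5 * solve_undamped(spec)$omega
  b0 <- damping(spec, w)$beta0
  limit <- 1 / (1 + (2 * b0 * spec$R0 / spec$environment$sound_speed)^2)
  expect_equal(scattering_cross_section(spec, w)$sigma_s_norm, limit,
               tolerance = 1e-3)
})

test_that("normalised response peaks are radius-invariant in deep water", {
  # In the deep environments damping at resonance is thermal-dominated and
  # the peak height of sigma_s'(f') is the same for every radius; at the
  # surface the sharp peak height retains a radius dependence (the same
  # effect that makes the surface quality factor grow with radius).
  for (name in c("depth_1000m", "depth_2000m", "depth_3500m")) {
    peaks <- vapply(c(0.01, 0.05, 0.10), function(R0) {
      solve_far_field(fixture_spec(name, "N2", R0))$peak$sigma_s_norm
    }, numeric(1))
    expect_lt(diff(range(peaks)) / mean(peaks), 0.01)
  }
})

test_that("response_curve returns a consistent sampled response", {
  spec <- fixture_spec("depth_1000m", "N2", 0.05)
  rc <- response_curve(spec, fprime = seq(0.9, 1.1, length.out = 21))
  expect_identical(nrow(rc), 21L)
  expect_identical(rc$beta, rc$beta0 + rc$beta_ac)
  expect_equal(rc$sigma_s, 4 * pi * spec$R0^2 * rc$sigma_s_norm)
  expect_equal(rc$f, rc$omega / (2 * pi))
})
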