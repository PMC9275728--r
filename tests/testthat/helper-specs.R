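# Shared helpers: fixture access and independent brute-force solvers used
# as oracles against the package's root-finders and maximiser.

.fx <- load_fixture_environments()

fixture_spec <- function(env_name, gas, R0) {
  pair <- .fx[[paste(env_name, gas, sep = ".")]]
  bubble_spec(R0, pair$environment, pair$gas)
}

fixture_names <- c("warm_surface", "cold_surface", "depth_1000m",
                   "depth_2000m", "depth_3500m")

# Independent root scan: dense grid over [lo, hi] x omega_M, locate the
# sign change of fn, then bisect it down to a relative width of 1e-10.
# Deliberately avoids uniroot/optimize, which the solvers use.
oracle_root <- function(fn, omega_ref, lo = 0.5, hi = 2, n = 4000L) {
  w <- seq(lo * omega_ref, hi * omega_ref, length.out = n)
  s <- sign(vapply(w, fn, numeric(1)))
  k <- which(diff(s) != 0)[1]
  stopifnot(!is.na(k))
  a <- w[k]; b <- w[k + 1]
  fa <- fn(a)
  while ((b - a) / omega_ref > 1e-12) {
    m <- (a + b) / 2
    fm <- fn(m)
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
  }
  (a + b) / 2
}

oracle_omega_und <- function(spec) {
  wM <- minnaert_omega(spec)
  oracle_root(function(w) stiffness_K(spec, w) - w^2, wM)
}

# Independent maximiser: three stages of grid refinement around the
# running argmax, final relative grid step ~1e-9.
oracle_omega_sigma <- function(spec) {
  wM <- minnaert_omega(spec)
  lo <- 0.5 * wM; hi <- 2 * wM
  for (stage in 1:4) {
    w <- seq(lo, hi, length.out = 2001L)
    y <- scattering_cross_section(spec, w)$sigma_s_norm
    k <- which.max(y)
    stopifnot(k > 1L, k < length(w))
    lo <- w[k - 1L]; hi <- w[k + 1L]
  }
  w[k]
}
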