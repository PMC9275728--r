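# Bracket helper: start from [0.5, 2] x omega_M and widen geometrically up
# to [1e-2, 1e2] x omega_M until fun changes sign over the bracket. Every
# resonance of the studied parameter ranges lies within a few percent of
# the Minnaert frequency, so the initial bracket almost always suffices.
.bracket_root <- function(fun, omega_ref, lo = 0.5, hi = 2,
                          lo_min = 1e-2, hi_max = 1e2) {
  repeat {
    flo <- fun(lo * omega_ref)
    fhi <- fun(hi * omega_ref)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0)
      return(c(lo, hi) * omega_ref)
    if (lo <= lo_min && hi >= hi_max) return(NULL)
    lo <- max(lo / 2, lo_min)
    hi <- min(hi * 2, hi_max)
  }
}

# Check fun changes sign exactly once on a log-spaced grid over the bracket.
.single_sign_change <- function(fun, bracket, n = 64L) {
  x <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n))
  s <- sign(vapply(x, fun, numeric(1)))
  sum(diff(s[s != 0]) != 0) == 1L
}

#' Undamped resonance frequency
#'
#' Solves the implicit equation `omega^2 = K(omega)` for the frequency of
#' undamped oscillation `omega_und` (the stiffness `K` is itself
#' frequency-dependent, so there is no closed form). The root is bracketed
#' around the Minnaert frequency and solved with [stats::uniroot()] to a
#' relative tolerance of 1e-12; the bracket is checked to contain exactly
#' one sign change.
#'
#' @param spec A [bubble_spec()].
#' @return A list with elements `omega` (rad/s) and `frequency` (Hz).
#' @export
solve_undamped <- function(spec) {
  stopifnot(inherits(spec, "bubble_spec"))
  wM <- minnaert_omega(spec)
  g <- function(w) stiffness_K(spec, w) - w^2
  br <- .bracket_root(g, wM)
  if (is.null(br))
    stop("solve_undamped: no sign change of K(omega) - omega^2 in ",
         "[1e-2, 1e2] x omega_M; check spec parameters")
  if (!.single_sign_change(g, br))
    warning("solve_undamped: multiple sign changes in bracket; ",
            "returning the root found by uniroot")
  w <- stats::uniroot(g, br, tol = 1e-12 * wM)$root
  list(omega = w, frequency = w / (2 * pi))
}

#' Natural (free-oscillation) frequency
#'
#' Solves `omega^2 = K(omega) - beta(omega)^2` for the natural angular
#' frequency of unforced, damped oscillation. Because `beta^2 <= K` at the
#' solution, `omega_nat <= omega_und`. If the system is overdamped at all
#' candidate frequencies the outcome is reported rather than thrown.
#'
#' @param spec A [bubble_spec()].
#' @return A list with `oscillatory` (logical), and when `TRUE` also
#'   `omega` (rad/s) and `frequency` (Hz).
#' @export
solve_natural <- function(spec) {
  stopifnot(inherits(spec, "bubble_spec"))
  wM <- minnaert_omega(spec)
  g <- function(w) w^2 - stiffness_K(spec, w) + damping(spec, w)$beta^2
  br <- .bracket_root(g, wM)
  if (is.null(br))
    return(list(oscillatory = FALSE,
                reason = "overdamped: no root of omega^2 = K - beta^2"))
  w <- stats::uniroot(g, br, tol = 1e-12 * wM)$root
  list(oscillatory = TRUE, omega = w, frequency = w / (2 * pi))
}

#' Far-field (peak-scattering) resonance
#'
#' The far-field pressure resonance `omega_sigma` is the driving frequency
#' that maximises the scattering cross-section; it is the frequency at
#' which a driven bladder radiates most efficiently to distant receivers.
#' The maximum is found with Brent's method ([stats::optimize()]) on the
#' log of the cross-section, bracketed around `omega_und`, to a relative
#' tolerance of 1e-10. A maximiser pinned at the bracket boundary triggers
#' one bracket widening, then an error.
#'
#' @param spec A [bubble_spec()].
#' @return A list with `omega` (rad/s), `frequency` (Hz), `fprime`
#'   (`omega / omega_und`), and `peak`, the one-row response data frame
#'   from [scattering_cross_section()] at the maximum.
#' @export
solve_far_field <- function(spec) {
  stopifnot(inherits(spec, "bubble_spec"))
  w_und <- solve_undamped(spec)$omega
  obj <- function(w) -log(scattering_cross_section(spec, w)$sigma_s_norm)
  span <- c(0.5, 2)
  for (attempt in 1:2) {
    br <- span * w_und
    opt <- stats::optimize(obj, interval = br, tol = 1e-10 * w_und)
    edge <- min(opt$minimum - br[1], br[2] - opt$minimum)
    if (edge > 1e-6 * w_und) {
      w <- opt$minimum
      return(list(omega = w, frequency = w / (2 * pi), fprime = w / w_und,
                  peak = scattering_cross_section(spec, w)))
    }
    span <- c(0.1, 10)
  }
  stop("solve_far_field: maximiser at bracket boundary even after ",
       "widening to [0.1, 10] x omega_und")
}

#' Quality factor of the far-field resonance
#'
#' `Q_f = omega_sigma / (2 beta(omega_sigma))` with `beta` the total
#' damping factor. High `Q_f` means a sharp resonance peak; `Q_f` falls
#' steeply with depth, which broadens and flattens the response of deep
#' swim bladders.
#'
#' @param spec A [bubble_spec()].
#' @return The dimensionless quality factor.
#' @export
quality_factor <- function(spec) {
  w_sigma <- solve_far_field(spec)$omega
  w_sigma / (2 * damping(spec, w_sigma)$beta)
}

#' Classify the damping regime
#'
#' Compares the total damping factor at a driving frequency with the
#' undamped resonance frequency: underdamped for `beta / omega_und < 1`,
#' overdamped for `> 1`, critical within a 1e-9 band of 1.
#'
#' @param spec A [bubble_spec()].
#' @param omega Driving angular frequency (rad/s, > 0).
#' @return One of `"underdamped"`, `"critical"`, `"overdamped"`.
#' @export
damping_regime <- function(spec, omega) {
  stopifnot(length(omega) == 1L, is.finite(omega), omega > 0)
  ratio <- damping(spec, omega)$beta / solve_undamped(spec)$omega
  if (abs(ratio - 1) <= 1e-9) "critical"
  else if (ratio < 1) "underdamped"
  else "overdamped"
}

#' Resonance summary for one bubble
#'
#' Aggregates the resonance picture of a single bubble: the Minnaert,
#' undamped, natural and far-field resonance frequencies, the total
#' damping at resonance, the quality factor, and the frequency ratios used
#' to compare environments (`omega_sigma / omega_und`, which is nearly
#' radius-invariant, and `f_sigma / f_M`, the departure from the Minnaert
#' estimate).
#'
#' @param spec A [bubble_spec()].
#' @return An object of class `"resonance_summary"`: a one-row data frame
#'   with columns `gas`, `environment`, `R0`, `f_M`, `f_und`, `f_nat`,
#'   `f_sigma`, `beta_at_resonance`, `Q_f`, `ratio_sigma_und`,
#'   `ratio_sigma_minnaert`.
#' @export
resonance_summary <- function(spec) {
  und <- solve_undamped(spec)
  nat <- solve_natural(spec)
  ff <- solve_far_field(spec)
  beta_res <- damping(spec, ff$omega)$beta
  f_M <- minnaert_frequency(spec)
  # ratios are recomputed from the stored frequency fields so that each
  # ratio column is exactly the quotient of its stored numerator and
  # denominator
  out <- data.frame(
    gas = spec$gas$gas, environment = spec$environment$name, R0 = spec$R0,
    f_M = f_M, f_und = und$frequency,
    f_nat = if (nat$oscillatory) nat$frequency else NA_real_,
    f_sigma = ff$frequency, beta_at_resonance = beta_res,
    Q_f = ff$omega / (2 * beta_res),
    ratio_sigma_und = ff$frequency / und$frequency,
    ratio_sigma_minnaert = ff$frequency / f_M)
  class(out) <- c("resonance_summary", class(out))
  out
}

#' @export
summary.bubble_spec <- function(object, ...) resonance_summary(object)
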