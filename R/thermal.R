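# Bounded stochastic temperature process.
#
# tau_t = (tau0 + m * sin(omega * t)) / (1 + exp(-sigma_eps * X_t)),
# with X_t iid standard normal. The numerator is the predictable
# (sinusoidal) component; the sigmoid-transformed noise keeps every
# realised temperature strictly inside (0, 1) provided tau0 - m > 0 and
# tau0 + m < 1.

#' Thermal regime of a stochastically fluctuating environment
#'
#' Describes the dimensionless temperature process
#' \deqn{\tau_t = \frac{\tau_0 + m \sin(\omega t)}{1 + e^{-\sigma_\epsilon X_t}},}
#' where \eqn{X_t \sim N(0,1)} are independent draws from the stream
#' identified by `seed`. Temperatures are dimensionless on (0, 1); no
#' mapping to physical units is defined. With `sigma_eps = 0` the process
#' reduces exactly to the deterministic sinusoid
#' \eqn{(\tau_0 + m\sin(\omega t))/2}, and over the long run the expected
#' temperature is approximately \eqn{\tau_0/2} (exactly so when `m = 0`, or
#' when `omega` is an integer multiple of \eqn{\pi} so the sine vanishes at
#' integer steps).
#'
#' @param tau0 Vertical shift of the sinusoidal component (dimensionless
#'   temperature). Together with `m` it must satisfy `tau0 - m > 0` and
#'   `tau0 + m < 1` so that all temperatures stay strictly inside (0, 1).
#' @param m Magnitude of the sinusoidal component, `m >= 0`.
#' @param omega Frequency in radians per time step, in `[0, 2*pi]`. May be
#'   given as a number or as a string multiple of pi such as `"13pi/20"`,
#'   `"pi"`, or `"2pi"`; stored canonically as a float.
#' @param sigma_eps Environmental noise magnitude, `sigma_eps >= 0`.
#' @param seed Integer noise-stream identifier. Every comparative
#'   evaluation (resident vs mutant, finite-difference stencils) reuses the
#'   frozen noise sequence identified by this seed (common random numbers).
#'
#' @return An object of class `"thermal_regime"`.
#' @seealso [generate_temperature()], [deterministic_component()]
#' @examples
#' reg <- thermal_regime(tau0 = 0.5, m = 0.25, omega = "13pi/20",
#'                       sigma_eps = 0.5, seed = 1)
#' reg
#' @export
thermal_regime <- function(tau0 = 0.5, m = 0.25, omega = 13 * pi / 20,
                           sigma_eps = 0.5, seed = 1L) {
  omega <- parse_omega(omega)
  stopifnot(is.numeric(tau0), length(tau0) == 1L, is.finite(tau0),
            is.numeric(m), length(m) == 1L, is.finite(m),
            is.numeric(sigma_eps), length(sigma_eps) == 1L,
            is.finite(sigma_eps))
  if (m < 0)
    stop("'m' must be nonnegative", call. = FALSE)
  if (!(tau0 - m > 0 && tau0 + m < 1))
    stop("boundedness requires tau0 - m > 0 and tau0 + m < 1 (got tau0 = ",
         tau0, ", m = ", m, ")", call. = FALSE)
  if (sigma_eps < 0)
    stop("'sigma_eps' must be nonnegative", call. = FALSE)
  if (omega < 0 || omega > 2 * pi)
    stop("'omega' must lie in [0, 2*pi]", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(list(tau0 = tau0, m = m, omega = omega,
                 sigma_eps = sigma_eps, seed = seed),
            class = "thermal_regime")
}

#' Parse a frequency given as a multiple of pi
#'
#' Accepts a plain number, or strings of the form `"pi"`, `"2pi"`,
#' `"pi/20"`, `"13pi/20"`.
#'
#' @param omega Numeric or string frequency.
#' @return Frequency as a double, in radians per step.
#' @export
parse_omega <- function(omega) {
  if (is.numeric(omega)) {
    stopifnot(length(omega) == 1L, is.finite(omega))
    return(as.numeric(omega))
  }
  if (!is.character(omega) || length(omega) != 1L)
    stop("'omega' must be a number or a string like \"13pi/20\"",
         call. = FALSE)
  txt <- gsub("\\s", "", tolower(omega))
  m <- regmatches(txt, regexec("^([0-9]*\\.?[0-9]*)\\*?pi(?:/([0-9]+\\.?[0-9]*))?$", txt))[[1]]
  if (length(m) == 0) {
    val <- suppressWarnings(as.numeric(txt))
    if (is.na(val))
      stop("cannot parse omega string: '", omega, "'", call. = FALSE)
    return(val)
  }
  num <- if (m[2] == "") 1 else as.numeric(m[2])
  den <- if (is.na(m[3]) || m[3] == "") 1 else as.numeric(m[3])
  num * pi / den
}

#' @export
print.thermal_regime <- function(x, ...) {
  cat("Thermal regime: tau_t = (", x$tau0, " + ", x$m,
      " sin(", format(x$omega, digits = 6), " t)) / (1 + exp(-",
      x$sigma_eps, " X_t))\n", sep = "")
  cat("  noise seed:", x$seed,
      if (x$sigma_eps == 0) " (deterministic limit)" else "", "\n")
  invisible(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a bounded stochastic temperature series
#'
#' Draws the frozen standard-normal noise sequence identified by
#' `regime$seed` and returns the temperatures for steps
#' `t = 0, 1, ..., horizon - 1`. The same `(regime, horizon)` pair always
#' yields bit-identical output, and the caller's RNG state is left
#' untouched.
#'
#' @param regime A [thermal_regime()].
#' @param horizon Number of time steps (positive integer).
#' @return An object of class `"temperature_series"`: a list with `values`
#'   (temperatures, strictly inside (0, 1)), `noise_draws` (the standard
#'   normal `X_t` used), and `regime`.
#' @examples
#' ts <- generate_temperature(thermal_regime(sigma_eps = 1.5), 100)
#' range(ts$values)
#' @export
generate_temperature <- function(regime, horizon) {
  stopifnot(inherits(regime, "thermal_regime"))
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) ||
      horizon < 1 || horizon != floor(horizon))
    stop("'horizon' must be a positive integer", call. = FALSE)
  horizon <- as.integer(horizon)
  x <- with_seed(regime$seed, stats::rnorm(horizon))
  t <- seq_len(horizon) - 1
  values <- (regime$tau0 + regime$m * sin(regime$omega * t)) /
    (1 + exp(-regime$sigma_eps * x))
  structure(list(values = values, noise_draws = x, regime = regime),
            class = "temperature_series")
}

#' Deterministic component of the temperature process
#'
#' The `sigma_eps = 0` limit, \eqn{(\tau_0 + m\sin(\omega t))/2}.
#'
#' @param regime A [thermal_regime()].
#' @param t Integer time step(s).
#' @return Temperature value(s).
#' @export
deterministic_component <- function(regime, t) {
  stopifnot(inherits(regime, "thermal_regime"), is.numeric(t))
  (regime$tau0 + regime$m * sin(regime$omega * t)) / 2
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(t = seq_along(x$values) - 1L, tau = x$values,
             x_noise = x$noise_draws)
}

#' @export
print.temperature_series <- function(x, ...) {
  cat("Temperature series:", length(x$values), "steps, range [",
      format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "], mean",
      format(mean(x$values), digits = 4), "\n")
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$values)
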