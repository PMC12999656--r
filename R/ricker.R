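# Stochastic Ricker dynamics driven by a temperature series. The resident
# update is N[t+1] = N[t] * exp(r(tau_t) * (1 - N[t]/k(tau_t))); the
# resident-mutant pair adds temperature-dependent competition coefficients
# from the two TPCs. Trajectories are deterministic given the temperature
# series: all stochasticity enters through the frozen noise stream.

MAX_EXPONENT <- 700  # beyond this exp() overflows double precision

#' Simulate a single resident population
#'
#' Applies the temperature-driven Ricker map stepwise along a frozen
#' temperature series: `N[t+1] = N[t] * exp(r(tau[t]) * (1 - N[t]/k(tau[t])))`.
#' The trajectory is positive for positive `N0` and, because the map is
#' deterministic given the series, bit-reproducible. If the update exponent
#' exceeds 700 (an exploding trajectory) the simulation aborts with the
#' offending step index rather than propagating infinities.
#'
#' @param N0 Initial population size (> 0).
#' @param tau A `"temperature_series"` from [generate_temperature()].
#' @param params A [demography_params()].
#' @return An object of class `"ricker_trajectory"`: list with `times`
#'   (`0:(H-1)`), `tau` (the driving temperatures), `N`, and `params`.
#' @examples
#' reg <- thermal_regime(sigma_eps = 0.5, seed = 1)
#' traj <- simulate_resident(0.1, generate_temperature(reg, 500),
#'                           demography_params())
#' attractor_summary(traj, burn_in = 200)
#' @export
simulate_resident <- function(N0, tau, params) {
  stopifnot(inherits(tau, "temperature_series"),
            inherits(params, "demography_params"))
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 <= 0)
    stop("'N0' must be a positive number", call. = FALSE)
  tv <- tau$values
  H <- length(tv)
  r <- growth_rate(tv, params)
  k <- carrying_capacity(tv, params)
  N <- numeric(H)
  N[1] <- N0
  if (H > 1) {
    for (t in 1:(H - 1)) {
      expo <- r[t] * (1 - N[t] / k[t])
      if (expo > MAX_EXPONENT)
        stop("divergent resident trajectory at step ", t,
             " (update exponent ", format(expo, digits = 3), " > 700)",
             call. = FALSE)
      N[t + 1] <- N[t] * exp(expo)
    }
  }
  structure(list(times = seq_len(H) - 1L, tau = tv, N = N, M = NULL,
                 params = params, shapes = NULL),
            class = "ricker_trajectory")
}

#' Simulate coupled resident-mutant dynamics
#'
#' The two types share the demographic TPCs `r(tau)` and `k(tau)` but
#' compete through their competition TPCs: at each step the resident
#' experiences crowding `N + alpha_NM * M` and the mutant
#' `alpha_MN * N + M`, with the coefficients recomputed from the current
#' temperature. With identical shapes the coefficients are 1 and the summed
#' population obeys the single-type map; with `M0 = 0` the mutant stays at
#' zero and the resident path is identical (bit-for-bit) to
#' [simulate_resident()]. Mutant sizes underflowing below 1e-300 are
#' clamped to exact zero (the map never reaches zero analytically); the
#' number of clamped steps is recorded in the `"extinction_events"`
#' attribute.
#'
#' @param N0 Initial resident size (> 0).
#' @param M0 Initial mutant size (>= 0).
#' @param tau A `"temperature_series"`.
#' @param params A [demography_params()].
#' @param resident,mutant [tpc_shape()] objects for the two types.
#' @return A `"ricker_trajectory"` with both `N` and `M` filled in, plus an
#'   `alpha_MN` component holding the per-step coefficient.
#' @export
simulate_pair <- function(N0, M0, tau, params, resident, mutant) {
  stopifnot(inherits(tau, "temperature_series"),
            inherits(params, "demography_params"))
  resident <- as_tpc_shape(resident); mutant <- as_tpc_shape(mutant)
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 <= 0)
    stop("'N0' must be a positive number", call. = FALSE)
  if (!is.numeric(M0) || length(M0) != 1L || !is.finite(M0) || M0 < 0)
    stop("'M0' must be a nonnegative number", call. = FALSE)
  tv <- tau$values
  H <- length(tv)
  r <- growth_rate(tv, params)
  k <- carrying_capacity(tv, params)
  ac <- competition_coefficients(tv, resident, mutant)
  aMN <- ac$alpha_MN; aNM <- ac$alpha_NM
  N <- numeric(H); M <- numeric(H)
  N[1] <- N0; M[1] <- M0
  clamped <- 0L
  if (H > 1) {
    for (t in 1:(H - 1)) {
      eN <- r[t] * (1 - (N[t] + aNM[t] * M[t]) / k[t])
      eM <- r[t] * (1 - (aMN[t] * N[t] + M[t]) / k[t])
      if (eN > MAX_EXPONENT || eM > MAX_EXPONENT)
        stop("divergent resident-mutant trajectory at step ", t,
             call. = FALSE)
      N[t + 1] <- N[t] * exp(eN)
      Mn <- M[t] * exp(eM)
      if (Mn != 0 && Mn < 1e-300) {
        Mn <- 0
        clamped <- clamped + 1L
      }
      M[t + 1] <- Mn
    }
  }
  structure(list(times = seq_len(H) - 1L, tau = tv, N = N, M = M,
                 params = params,
                 shapes = list(resident = resident, mutant = mutant),
                 alpha_MN = aMN),
            class = "ricker_trajectory",
            extinction_events = clamped)
}

#' @export
as.data.frame.ricker_trajectory <- function(x, ...) {
  out <- data.frame(t = x$times, tau = x$tau, N = x$N)
  if (!is.null(x$M)) {
    out$M <- x$M
    out$alpha_MN <- x$alpha_MN
  }
  out
}

#' @export
print.ricker_trajectory <- function(x, ...) {
  cat("Ricker trajectory:", length(x$N), "steps",
      if (!is.null(x$M)) "(resident + mutant)" else "(resident only)", "\n")
  cat("  final N =", format(x$N[length(x$N)], digits = 6))
  if (!is.null(x$M)) cat(", final M =", format(x$M[length(x$M)], digits = 6))
  cat("\n")
  invisible(x)
}

#' Summarise the attractor of a trajectory
#'
#' Mean and standard deviation of the resident sizes after discarding a
#' burn-in; the mean is the long-term average effective population size
#' used by the canonical equations. Transients die out within about 100
#' steps under the reference regimes, so the default burn-in of 1000 leaves
#' a wide margin.
#'
#' @param traj A `"ricker_trajectory"`.
#' @param burn_in Number of initial steps to discard (time indices
#'   `< burn_in` are dropped).
#' @return An object of class `"attractor_summary"`: list with `mean_N`,
#'   `sd_N`, `burn_in`, `window` (number of steps retained).
#' @export
attractor_summary <- function(traj, burn_in = 1000) {
  stopifnot(inherits(traj, "ricker_trajectory"))
  H <- length(traj$N)
  if (!is.numeric(burn_in) || length(burn_in) != 1L || burn_in < 0 ||
      burn_in >= H)
    stop("'burn_in' must satisfy 0 <= burn_in < length(trajectory)",
         call. = FALSE)
  keep <- traj$times >= burn_in
  n <- traj$N[keep]
  structure(list(mean_N = mean(n),
                 sd_N = if (length(n) > 1) stats::sd(n) else 0,
                 burn_in = as.integer(burn_in), window = length(n)),
            class = "attractor_summary")
}

#' @export
print.attractor_summary <- function(x, ...) {
  cat("Attractor summary over", x$window, "steps (burn-in", x$burn_in,
      "): mean_N =", format(x$mean_N, digits = 6),
      ", sd_N =", format(x$sd_N, digits = 6), "\n")
  invisible(x)
}
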