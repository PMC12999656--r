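# High-level model interface in the classic R fitting idiom: tpc_ess()
# runs the whole pipeline (frozen noise -> resident attractor -> selection
# gradients -> singularity -> classification) and returns a fitted-model
# object with the usual accessor methods.

#' Fit the evolutionarily singular competition TPC for a thermal regime
#'
#' Locates and classifies the evolutionary endpoint of competition-TPC
#' adaptation under a given stochastic thermal regime: the resident
#' population is simulated to its fluctuating attractor along a frozen
#' noise sequence, invasion fitness of rare mutants is computed by long-run
#' time averaging, and the joint root of the two selection gradients is
#' found and classified (CSS/ESS/branching candidate/repeller, or boundary
#' convergence when selection drives a trait against its admissible
#' limit).
#'
#' @param regime A [thermal_regime()] (or a preset name such as `"fig2a"`,
#'   see [preset()]).
#' @param params A [demography_params()].
#' @param init Initial `(mu, s)` guess for the singularity search.
#' @param invasion An [invasion_config()].
#' @param canonical A [canonical_config()].
#' @return An object of class `c("tpc_ess", "singularity_report")`; see
#'   [find_singularity()] for the fields. Supports `print()`, `summary()`,
#'   `coef()` (the singular traits plus derived optimum and breadth),
#'   `predict()` (the singular TPC density at new temperatures),
#'   `residuals()` (the selection gradient at the fitted point -- the
#'   estimating-equation residual), `simulate()` (population trajectories
#'   under the fitted regime) and `plot()`.
#' @examples
#' \donttest{
#' fit <- tpc_ess(thermal_regime(sigma_eps = 0.5, seed = 1),
#'                invasion = invasion_config(horizon_L = 2e4))
#' coef(fit)
#' summary(fit)
#' }
#' @export
tpc_ess <- function(regime = thermal_regime(),
                    params = demography_params(),
                    init = c(mu = 0.2, s = 0.08),
                    invasion = invasion_config(),
                    canonical = canonical_config()) {
  if (is.character(regime)) regime <- preset(regime)$thermal
  rep <- find_singularity(init, regime, params, invasion, canonical)
  rep$call <- match.call()
  rep$init <- c(mu = as_tpc_shape(init)$mu, s = as_tpc_shape(init)$s)
  class(rep) <- c("tpc_ess", "singularity_report")
  rep
}

#' @export
print.tpc_ess <- function(x, ...) {
  cat("Evolutionarily singular competition TPC\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  print.singularity_report(x)
  invisible(x)
}

#' @export
coef.tpc_ess <- function(object, ...) {
  c(mu = object$mu_star, s = object$s_star,
    tau_opt = object$tau_opt_star, breadth = object$breadth_star)
}

#' @export
residuals.tpc_ess <- function(object, ...) {
  object$gradient
}

#' @export
summary.tpc_ess <- function(object, ...) {
  structure(list(fit = object), class = "summary.tpc_ess")
}

#' @export
print.summary.tpc_ess <- function(x, ...) {
  f <- x$fit
  print.tpc_ess(f)
  cat("\nConvergence stability (canonical Jacobian eigenvalues):\n  ")
  cat(paste(format(f$jacobian_eigs, digits = 5), collapse = ", "), "\n")
  cat("Evolutionary stability (fitness Hessian eigenvalues):\n  ")
  cat(paste(format(f$hessian_eigs, digits = 5), collapse = ", "), "\n")
  cat("Thermal regime: tau0 =", f$regime$tau0, " m =", f$regime$m,
      " omega =", format(f$regime$omega, digits = 5),
      " sigma_eps =", f$regime$sigma_eps, "\n")
  cat("Averaging: L =", f$inv_cfg$horizon_L, " burn-in =",
      f$inv_cfg$burn_in, " seed =", f$seed, "\n")
  invisible(x)
}

#' Singular-TPC density at new temperatures
#'
#' @param object A fitted [tpc_ess()] object.
#' @param newdata Temperatures at which to evaluate the singular TPC:
#'   a numeric vector or a data frame with a `tau` column. Defaults to a
#'   fine grid over (0, 1).
#' @param ... Unused.
#' @return A data frame with columns `tau` and `performance`.
#' @export
predict.tpc_ess <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) seq(0.002, 0.998, length.out = 500)
    else if (is.data.frame(newdata)) newdata$tau
    else as.numeric(newdata)
  data.frame(tau = tau,
             performance = beta_density(tau,
                                        tpc_shape(object$mu_star,
                                                  object$s_star)))
}

#' Simulate population dynamics under the fitted regime
#'
#' Resident-only trajectories driven by fresh noise sequences from the
#' fitted thermal regime (the singular strategy is selectively neutral
#' against itself, so the resident dynamics are the relevant ecology).
#'
#' @param object A fitted [tpc_ess()] object.
#' @param nsim Number of trajectories.
#' @param seed Base seed for the noise streams; defaults to the fitted
#'   seed.
#' @param horizon Number of time steps.
#' @param N0 Initial population size.
#' @param ... Unused.
#' @return A list of `"ricker_trajectory"` objects (a single trajectory if
#'   `nsim = 1`).
#' @export
simulate.tpc_ess <- function(object, nsim = 1, seed = NULL,
                             horizon = 1000, N0 = 0.1, ...) {
  base <- if (is.null(seed)) object$seed else as.integer(seed)
  sims <- lapply(seq_len(nsim), function(i) {
    reg <- object$regime
    reg$seed <- as.integer((base + (i - 1L)) %% .Machine$integer.max)
    simulate_resident(N0, generate_temperature(reg, horizon),
                      object$params)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Plot a fitted singular TPC against the temperature distribution
#'
#' Draws the normalised histogram of a long temperature series from the
#' fitted regime with the singular TPC density overlaid, marking the
#' singular thermal optimum and the long-run mean temperature.
#'
#' @param x A fitted [tpc_ess()] object.
#' @param horizon Length of the temperature series for the histogram.
#' @param bins Number of histogram bins over (0, 1).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tpc_ess <- function(x, horizon = 1e5, bins = 50, ...) {
  tab <- temperature_histogram_with_tpc(x$regime, x$params, x$inv_cfg,
                                        bins = bins, singularity = x,
                                        horizon = horizon)
  ylim <- range(0, tab$frequency, tab$tpc_density, finite = TRUE)
  graphics::plot(tab$bin_center, tab$frequency, type = "h", lwd = 3,
                 col = "grey70", xlab = "temperature (dimensionless)",
                 ylab = "density", ylim = ylim, ...)
  graphics::lines(tab$bin_center, tab$tpc_density, col = "blue", lwd = 2)
  graphics::abline(v = x$tau_opt_star, col = "blue", lty = 2)
  graphics::abline(v = x$regime$tau0 / 2, col = "red", lty = 3)
  graphics::legend("topright", bty = "n",
                   legend = c("temperature", "singular TPC",
                              expression(tau[opt]^"*"),
                              expression(tau[0] / 2)),
                   col = c("grey70", "blue", "blue", "red"),
                   lty = c(1, 1, 2, 3), lwd = c(3, 2, 1, 1))
  invisible(x)
}
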