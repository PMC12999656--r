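# Invasion fitness and its derivatives. A rare mutant never feeds back on
# the resident, so its long-run average per-capita growth rate on the
# resident's attractor is
#   lambda(x_N, x_M) = mean_t [ r(tau_t) (1 - alpha_MN(tau_t) N_t / k(tau_t)) ]
# over the post-burn-in window of one frozen noise realisation. Because the
# resident's own dynamics do not involve its competition TPC (identical
# individuals compete with coefficient 1), the resident trajectory -- and
# hence the weights r_t N_t / k_t -- depend only on the thermal regime and
# the demographic parameters. All fitness, gradient and Hessian evaluations
# at a given regime therefore share a single cached resident context, which
# is what makes the finite-difference stencils common-random-number exact.

#' Numerical controls for invasion-fitness evaluation
#'
#' @param horizon_L Averaging length `L` of the long-run fitness average
#'   (positive integer).
#' @param burn_in Steps discarded before averaging (must be `< horizon_L`).
#' @param fd_step Central finite-difference step used for selection
#'   gradients, in trait units.
#' @param noise_seed Seed of the frozen noise sequence; overrides the seed
#'   carried by the thermal regime so that one experiment record pins down
#'   the randomness completely. `NULL` keeps the regime's own seed.
#' @param ensemble_reps Number of independent noise realisations averaged
#'   (default 1: a single frozen sequence, which keeps nullclines smooth).
#' @param N0 Initial resident size for the attractor simulation.
#' @return An object of class `"invasion_config"`.
#' @export
invasion_config <- function(horizon_L = 1e5, burn_in = 1e3, fd_step = 1e-4,
                            noise_seed = NULL, ensemble_reps = 1, N0 = 0.1) {
  stopifnot(horizon_L >= 1, burn_in >= 1, burn_in < horizon_L,
            fd_step > 0, ensemble_reps >= 1, N0 > 0)
  structure(list(horizon_L = as.integer(horizon_L),
                 burn_in = as.integer(burn_in),
                 fd_step = fd_step,
                 noise_seed = if (is.null(noise_seed)) NULL
                              else as.integer(noise_seed),
                 ensemble_reps = as.integer(ensemble_reps),
                 N0 = N0),
            class = "invasion_config")
}

# Build the cached resident context: frozen temperatures, growth rates,
# attractor weights w_t = r_t N_t / k_t over the averaging window, and the
# long-term average effective population size Ne. One context per noise
# realisation.
resident_context <- function(regime, params, cfg) {
  stopifnot(inherits(regime, "thermal_regime"),
            inherits(params, "demography_params"),
            inherits(cfg, "invasion_config"))
  base_seed <- if (is.null(cfg$noise_seed)) regime$seed else cfg$noise_seed
  reps <- lapply(seq_len(cfg$ensemble_reps), function(i) {
    reg <- regime
    reg$seed <- as.integer((base_seed + (i - 1L)) %% .Machine$integer.max)
    ts <- generate_temperature(reg, cfg$horizon_L)
    traj <- simulate_resident(cfg$N0, ts, params)
    idx <- (cfg$burn_in + 1L):cfg$horizon_L
    tau <- ts$values[idx]
    r <- growth_rate(tau, params)
    k <- carrying_capacity(tau, params)
    N <- traj$N[idx]
    list(tau = tau, r = r, mean_r = mean(r), w = r * N / k, Ne = mean(N),
         log_tau = log(tau), log_1mtau = log1p(-tau))
  })
  structure(list(reps = reps, regime = regime, params = params, cfg = cfg,
                 seed = base_seed,
                 Ne = mean(vapply(reps, `[[`, numeric(1), "Ne"))),
            class = "resident_context")
}

# lambda for one realisation; shapes as plain (mu, s) pairs.
lambda_rep <- function(rep, res, mut) {
  d <- stats::dbeta(rep$tau, res[1] / res[2], (1 - res[1]) / res[2],
                    log = TRUE) -
       stats::dbeta(rep$tau, mut[1] / mut[2], (1 - mut[1]) / mut[2],
                    log = TRUE)
  if (any(!is.finite(d)) || max(abs(d)) > MAX_EXPONENT)
    stop("TPC density ratio out of numerical range during fitness ",
         "averaging (resident mu = ", res[1], ", s = ", res[2],
         "; mutant mu = ", mut[1], ", s = ", mut[2], ")", call. = FALSE)
  rep$mean_r - mean(rep$w * exp(d))
}

lambda_ctx <- function(ctx, res, mut) {
  mean(vapply(ctx$reps, lambda_rep, numeric(1), res = res, mut = mut))
}

check_interior <- function(x, h) {
  if (x[1] - h <= 0 || x[1] + h >= 1 || x[2] - h <= 0)
    stop("finite-difference stencil leaves the admissible trait region ",
         "at (mu = ", x[1], ", s = ", x[2], ") with step ", h,
         call. = FALSE)
}

gradient_ctx <- function(ctx, x, h = ctx$cfg$fd_step) {
  check_interior(x, h)
  c(g_mu = (lambda_ctx(ctx, x, c(x[1] + h, x[2])) -
              lambda_ctx(ctx, x, c(x[1] - h, x[2]))) / (2 * h),
    g_s = (lambda_ctx(ctx, x, c(x[1], x[2] + h)) -
             lambda_ctx(ctx, x, c(x[1], x[2] - h))) / (2 * h))
}

hessian_ctx <- function(ctx, x, h = 1e-3) {
  check_interior(x, h)
  l00 <- lambda_ctx(ctx, x, x)
  lpp <- lambda_ctx(ctx, x, x + c(h, h))
  lpm <- lambda_ctx(ctx, x, x + c(h, -h))
  lmp <- lambda_ctx(ctx, x, x + c(-h, h))
  lmm <- lambda_ctx(ctx, x, x + c(-h, -h))
  lp0 <- lambda_ctx(ctx, x, x + c(h, 0))
  lm0 <- lambda_ctx(ctx, x, x + c(-h, 0))
  l0p <- lambda_ctx(ctx, x, x + c(0, h))
  l0m <- lambda_ctx(ctx, x, x + c(0, -h))
  H <- matrix(c((lp0 - 2 * l00 + lm0) / h^2,
                (lpp - lpm - lmp + lmm) / (4 * h^2),
                (lpp - lpm - lmp + lmm) / (4 * h^2),
                (l0p - 2 * l00 + l0m) / h^2), 2, 2,
              dimnames = list(c("mu", "s"), c("mu", "s")))
  H
}

resolve_ctx <- function(regime, params, cfg) {
  if (inherits(regime, "resident_context")) regime
  else resident_context(regime, params, cfg)
}

#' Invasion fitness of a rare mutant
#'
#' Long-run average per-capita growth rate of a rare mutant introduced
#' into the resident's stationary fluctuating attractor: the resident is
#' simulated alone along the frozen noise sequence, and the average of
#' `r(tau_t) * (1 - alpha_MN(tau_t) * N_t / k(tau_t))` is taken over the
#' post-burn-in window. The mutant never feeds back on the resident (true
#' rarity limit). A resident is selectively neutral against itself, so
#' `invasion_fitness(x, x, ...)` is of order `1/window`.
#'
#' @param resident,mutant [tpc_shape()] objects (or length-2 `(mu, s)`
#'   vectors).
#' @param regime A [thermal_regime()].
#' @param params A [demography_params()].
#' @param cfg An [invasion_config()].
#' @return The invasion fitness (a real number; positive means the mutant
#'   can invade).
#' @examples
#' reg <- thermal_regime(sigma_eps = 0.5, seed = 1)
#' cfg <- invasion_config(horizon_L = 5e3, burn_in = 500)
#' invasion_fitness(tpc_shape(0.3, 0.05), tpc_shape(0.31, 0.05),
#'                  reg, demography_params(), cfg)
#' @export
invasion_fitness <- function(resident, mutant, regime, params, cfg) {
  resident <- as_tpc_shape(resident); mutant <- as_tpc_shape(mutant)
  ctx <- resolve_ctx(regime, params, cfg)
  lambda_ctx(ctx, c(resident$mu, resident$s), c(mutant$mu, mutant$s))
}

#' Selection gradient at a resident strategy
#'
#' Central finite differences of the invasion fitness with respect to the
#' mutant's `mu` and `s`, evaluated at the resident and computed on one
#' frozen noise sequence shared by all four stencil points (common random
#' numbers), so repeated evaluation with the same seed is bit-identical.
#'
#' @param resident A [tpc_shape()] (or `(mu, s)` vector).
#' @inheritParams invasion_fitness
#' @return An object of class `"selection_gradient"`: numeric `c(g_mu, g_s)`
#'   with the seed, averaging length and step recorded as attributes.
#' @export
selection_gradient <- function(resident, regime, params, cfg) {
  resident <- as_tpc_shape(resident)
  ctx <- resolve_ctx(regime, params, cfg)
  g <- gradient_ctx(ctx, c(resident$mu, resident$s))
  structure(g, class = "selection_gradient",
            seed = ctx$seed, horizon_L = ctx$cfg$horizon_L,
            burn_in = ctx$cfg$burn_in, fd_step = ctx$cfg$fd_step)
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat("Selection gradient: g_mu =", format(x[["g_mu"]], digits = 6),
      ", g_s =", format(x[["g_s"]], digits = 6), "\n")
  cat("  (L =", attr(x, "horizon_L"), ", burn-in =", attr(x, "burn_in"),
      ", fd step =", attr(x, "fd_step"), ", seed =", attr(x, "seed"), ")\n")
  invisible(x)
}

#' Hessian of invasion fitness in the mutant traits
#'
#' Symmetric 2x2 matrix of second derivatives of the invasion fitness with
#' respect to the mutant `(mu, s)`, evaluated at the resident on the frozen
#' noise sequence. Negative definiteness at a singular strategy means no
#' nearby mutant can invade (evolutionary stability); a positive eigenvalue
#' signals disruptive selection.
#'
#' @inheritParams selection_gradient
#' @param fd_step_hess Step for the second-difference stencil (the
#'   curvature scale tolerates, and benefits from, a larger step than the
#'   gradient).
#' @return An object of class `"fitness_hessian"`: list with `entries`
#'   (the symmetrised matrix), `eigenvalues` (sorted decreasing), and the
#'   raw asymmetry `|H12 - H21|` before symmetrisation (identically 0 for
#'   this stencil; retained for reporting).
#' @export
fitness_hessian <- function(resident, regime, params, cfg,
                            fd_step_hess = 1e-3) {
  resident <- as_tpc_shape(resident)
  ctx <- resolve_ctx(regime, params, cfg)
  H <- hessian_ctx(ctx, c(resident$mu, resident$s), h = fd_step_hess)
  structure(list(entries = H,
                 eigenvalues = sort(eigen(H, symmetric = TRUE,
                                          only.values = TRUE)$values,
                                    decreasing = TRUE),
                 asymmetry = abs(H[1, 2] - H[2, 1]),
                 seed = ctx$seed),
            class = "fitness_hessian")
}

#' @export
print.fitness_hessian <- function(x, ...) {
  cat("Invasion-fitness Hessian (mutant traits):\n")
  print(x$entries)
  cat("eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}
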