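# Temperature-dependent demographic rates: a saturating-exponential
# intrinsic growth rate and a bell-shaped carrying capacity, both defined
# on the open temperature interval (0, 1). The critical thermal limits are
# fixed at 0 and 1 and carried only for reporting.

#' Demographic parameters of the temperature-dependent Ricker model
#'
#' Bundles the parameters of the intrinsic growth rate
#' \deqn{r(\tau) = r_0 e^{-c/\tau} + r_1}
#' and of the carrying capacity
#' \deqn{k(\tau) = k_0 e^{-(\tau - \tau_m)^2 / \sigma_k}.}
#'
#' The growth rate is strictly increasing in temperature and bounded below
#' by `r1`; the capacity peaks at `k0` when `tau = tau_m` and falls off on
#' both sides. Defaults are the reference values used throughout:
#' `r0 = c = r1 = 0.1`, `k0 = 2`, `tau_m = 0.5`, `sigma_k = 0.05`. The
#' alternate reference values `r0 = 5`, `k0 = 1` produce periodic and
#' chaotic population dynamics in the noise-free limit.
#'
#' @param r0 Scaling constant of the growth rate (> 0).
#' @param c Steepness of the growth response (> 0).
#' @param r1 Baseline growth rate near zero temperature (> 0).
#' @param k0 Scaling constant of the carrying capacity (> 0).
#' @param tau_m Temperature of peak capacity, in (0, 1).
#' @param sigma_k Breadth of the capacity response (> 0).
#' @return An object of class `"demography_params"`. The fixed critical
#'   thermal limits are reported as `ctau_min = 0` and `ctau_max = 1`.
#' @examples
#' p <- demography_params()
#' growth_rate(0.25, p)
#' carrying_capacity(0.25, p)
#' @export
demography_params <- function(r0 = 0.1, c = 0.1, r1 = 0.1,
                              k0 = 2, tau_m = 0.5, sigma_k = 0.05) {
  vals <- c(r0 = r0, c = c, r1 = r1, k0 = k0, sigma_k = sigma_k)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all of r0, c, r1, k0, sigma_k must be finite and > 0",
         call. = FALSE)
  if (!is.finite(tau_m) || tau_m <= 0 || tau_m >= 1)
    stop("'tau_m' must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(r0 = r0, c = c, r1 = r1, k0 = k0, tau_m = tau_m,
                 sigma_k = sigma_k, ctau_min = 0, ctau_max = 1),
            class = "demography_params")
}

#' @export
print.demography_params <- function(x, ...) {
  cat("Demography: r(tau) = ", x$r0, " exp(-", x$c, "/tau) + ", x$r1,
      ";  k(tau) = ", x$k0, " exp(-(tau - ", x$tau_m, ")^2/", x$sigma_k,
      ")\n", sep = "")
  invisible(x)
}

check_tau_domain <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) ||
      any(tau <= 0) || any(tau >= 1))
    stop("temperature must lie strictly inside (0, 1)", call. = FALSE)
}

#' Intrinsic growth rate at a given temperature
#'
#' Saturating exponential `r0 * exp(-c / tau) + r1`; strictly increasing on
#' (0, 1) and bounded below by `r1`. Vectorised over `tau`.
#'
#' @param tau Temperature(s), strictly inside (0, 1).
#' @param params A [demography_params()].
#' @return Growth rate(s).
#' @export
growth_rate <- function(tau, params) {
  stopifnot(inherits(params, "demography_params"))
  check_tau_domain(tau)
  params$r0 * exp(-params$c / tau) + params$r1
}

#' Carrying capacity at a given temperature
#'
#' Bell-shaped `k0 * exp(-(tau - tau_m)^2 / sigma_k)`; maximal (`k0`) at
#' `tau = tau_m` and symmetric about it. Vectorised over `tau`.
#'
#' @inheritParams growth_rate
#' @return Carrying capacity value(s).
#' @export
carrying_capacity <- function(tau, params) {
  stopifnot(inherits(params, "demography_params"))
  check_tau_domain(tau)
  params$k0 * exp(-(tau - params$tau_m)^2 / params$sigma_k)
}
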