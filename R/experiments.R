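# Experiment orchestration: named presets for the reference parameter
# bundles, sweeps of the singular strategy over noise magnitude and
# fluctuation frequency, and temperature histograms with the singular TPC
# overlaid.

PRESET_NAMES <- c("fig2a", "fig2b", "fig3_low", "fig3_high",
                  "fig4_m025", "fig4_m04", "fig5_top", "fig5_bottom")

#' Reference experiment presets
#'
#' Returns the full parameter bundle for one of the named reference
#' experiments: the low/high-noise vector-field regimes (`fig2a`,
#' `fig2b`), the matching population-dynamics regimes (`fig3_low`,
#' `fig3_high`), the two sweep configurations over noise magnitude and
#' frequency (`fig4_m025`, `fig4_m04`), and the slow-oscillation
#' histogram regimes without and with noise (`fig5_top`, `fig5_bottom`).
#' All share the reference demography `r0 = c = r1 = 0.1`, `k0 = 2`,
#' `tau_m = 0.5`, `sigma_k = 0.05` and the thermal baseline `tau0 = 0.5`.
#'
#' @param name One of `"fig2a"`, `"fig2b"`, `"fig3_low"`, `"fig3_high"`,
#'   `"fig4_m025"`, `"fig4_m04"`, `"fig5_top"`, `"fig5_bottom"`.
#' @param seed Noise-stream seed stored in the thermal regime.
#' @return An `"experiment_config"` list with elements `thermal`,
#'   `growth`, `capacity`, `invasion`, `canonical` and (for the sweep
#'   presets) `sweep`.
#' @examples
#' preset("fig2b")$thermal$sigma_eps  # 1.5
#' @export
preset <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% PRESET_NAMES))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid names: ", paste(PRESET_NAMES, collapse = ", "),
         call. = FALSE)
  thermal <- switch(name,
    fig2a = , fig3_low =
      thermal_regime(0.5, 0.25, 13 * pi / 20, 0.5, seed),
    fig2b = , fig3_high =
      thermal_regime(0.5, 0.25, 13 * pi / 20, 1.5, seed),
    fig4_m025 = thermal_regime(0.5, 0.25, 13 * pi / 20, 0.5, seed),
    fig4_m04 = thermal_regime(0.5, 0.4, 13 * pi / 20, 0.5, seed),
    fig5_top = thermal_regime(0.5, 0.4, pi / 20, 0, seed),
    fig5_bottom = thermal_regime(0.5, 0.4, pi / 20, 1.1282, seed))
  cfg <- list(thermal = thermal,
              growth = list(r0 = 0.1, c = 0.1, r1 = 0.1),
              capacity = list(k0 = 2, tau_m = 0.5, sigma_k = 0.05),
              invasion = invasion_config(),
              canonical = canonical_config())
  if (name %in% c("fig4_m025", "fig4_m04"))
    cfg$sweep <- sweep_spec(m = thermal$m, master_seed = seed)
  structure(c(list(preset = name), cfg), class = "experiment_config")
}

params_from_config <- function(config) {
  demography_params(r0 = config$growth$r0, c = config$growth$c,
                    r1 = config$growth$r1, k0 = config$capacity$k0,
                    tau_m = config$capacity$tau_m,
                    sigma_k = config$capacity$sigma_k)
}

#' Specification of a (sigma_eps, omega) singularity sweep
#'
#' @param sigma_eps_grid Increasing noise magnitudes inside (0, 2).
#' @param omega_grid Increasing frequencies inside (0, 2*pi].
#' @param m Sine magnitude held fixed across the sweep.
#' @param tau0 Vertical shift of the thermal regime.
#' @param params A [demography_params()].
#' @param inv_cfg An [invasion_config()]. Sweeps default to a shorter
#'   averaging window (L = 2e4) than single-regime analyses; cell-level
#'   results then carry correspondingly larger stochastic error.
#' @param can_cfg A [canonical_config()].
#' @param master_seed Master seed; each cell's noise seed is derived
#'   deterministically from it and the cell index, so cells are
#'   independent yet the sweep is bit-reproducible.
#' @param continuation Warm-start each cell's singularity search from its
#'   predecessor (cells are visited in serpentine order).
#' @param init Initial guess for the first cell.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(sigma_eps_grid = c(0.2, 0.5, 0.8, 1.1, 1.4, 1.7),
                       omega_grid = c(pi / 2, 13 * pi / 20, pi,
                                      13 * pi / 10, 7 * pi / 4, 2 * pi),
                       m = 0.25, tau0 = 0.5,
                       params = demography_params(),
                       inv_cfg = invasion_config(horizon_L = 2e4),
                       can_cfg = canonical_config(),
                       master_seed = 1L,
                       continuation = TRUE,
                       init = c(mu = 0.2, s = 0.06)) {
  stopifnot(length(sigma_eps_grid) >= 1, all(diff(sigma_eps_grid) > 0),
            all(sigma_eps_grid > 0), all(sigma_eps_grid < 2),
            length(omega_grid) >= 1, all(diff(omega_grid) > 0),
            all(omega_grid > 0), all(omega_grid <= 2 * pi))
  structure(list(sigma_eps_grid = sigma_eps_grid, omega_grid = omega_grid,
                 m = m, tau0 = tau0, params = params, inv_cfg = inv_cfg,
                 can_cfg = can_cfg, master_seed = as.integer(master_seed),
                 continuation = isTRUE(continuation), init = init),
            class = "sweep_spec")
}

cell_seed <- function(master_seed, idx) {
  as.integer((as.numeric(master_seed) + 7919 * idx) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Run a singularity sweep over noise magnitude and frequency
#'
#' Locates and classifies the singular strategy in every
#' `(sigma_eps, omega)` cell of the grid. Cells are visited in serpentine
#' order with optional warm starting; a failed cell is recorded (columns
#' set to `NA`, `failed = TRUE`) without aborting the sweep, but more than
#' 20% failures raise an error carrying the partial results in its
#' `partial` field. With `file` set, the result table is written
#' atomically (temp file then rename) as CSV.
#'
#' @param spec A [sweep_spec()].
#' @param file Optional CSV output path.
#' @return A data frame of class `"sweep_result"` with one row per cell:
#'   `sigma_eps`, `omega`, `mu_star`, `s_star`, `tau_opt_star`,
#'   `breadth_star`, `breadth_sq_star`, `shape_class`, `verdict`,
#'   `residual`, `boundary`, `seed`, `failed`.
#' @export
run_sweep <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  nseps <- length(spec$sigma_eps_grid); nom <- length(spec$omega_grid)
  cells <- list(); idx <- 0L
  for (j in seq_len(nom)) {
    ii <- if (j %% 2 == 1) seq_len(nseps) else rev(seq_len(nseps))
    for (i in ii) {
      idx <- idx + 1L
      cells[[idx]] <- c(i = i, j = j, idx = idx)
    }
  }
  rows <- vector("list", length(cells))
  guess <- spec$init
  for (cell in cells) {
    se <- spec$sigma_eps_grid[cell["i"]]
    om <- spec$omega_grid[cell["j"]]
    seed <- cell_seed(spec$master_seed, cell["idx"])
    reg <- thermal_regime(spec$tau0, spec$m, om, se, seed)
    rep <- tryCatch(
      find_singularity(guess, reg, spec$params, spec$inv_cfg,
                       spec$can_cfg),
      error = function(e) e)
    if (inherits(rep, "error")) {
      rows[[cell["idx"]]] <- data.frame(
        sigma_eps = se, omega = om, mu_star = NA_real_, s_star = NA_real_,
        tau_opt_star = NA_real_, breadth_star = NA_real_,
        breadth_sq_star = NA_real_, shape_class = NA_character_,
        verdict = NA_character_, residual = NA_real_, boundary = NA,
        seed = seed, failed = TRUE)
      guess <- spec$init
    } else {
      rows[[cell["idx"]]] <- data.frame(
        sigma_eps = se, omega = om, mu_star = rep$mu_star,
        s_star = rep$s_star, tau_opt_star = rep$tau_opt_star,
        breadth_star = rep$breadth_star,
        breadth_sq_star = rep$breadth_sq_star,
        shape_class = rep$shape_class$label, verdict = rep$verdict,
        residual = rep$grad_norm, boundary = rep$boundary, seed = seed,
        failed = FALSE)
      if (spec$continuation && !rep$boundary)
        guess <- c(mu = rep$mu_star, s = rep$s_star)
      else if (!spec$continuation) guess <- spec$init
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sigma_eps, out$omega), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  fail_rate <- mean(out$failed)
  if (fail_rate > 0.2) {
    cond <- simpleError(sprintf(
      "sweep failed in %.0f%% of cells (> 20%%); partial results attached",
      100 * fail_rate))
    cond$partial <- out
    stop(cond)
  }
  if (!is.null(file)) {
    tmp <- paste0(file, ".tmp")
    utils::write.csv(format(out, digits = 12), tmp, row.names = FALSE,
                     quote = FALSE)
    file.rename(tmp, file)
  }
  out
}

#' Temperature histogram with the singular TPC overlaid
#'
#' Bins a long realisation of the temperature process into a
#' density-normalised histogram over (0, 1) and evaluates the singular
#' TPC density at the bin centres, side by side, reproducing the standard
#' comparison of where temperatures fall versus where singular competitive
#' performance peaks.
#'
#' @param regime A [thermal_regime()].
#' @param params A [demography_params()].
#' @param inv_cfg An [invasion_config()].
#' @param bins Number of equal-width bins over (0, 1).
#' @param singularity Optional precomputed `"singularity_report"`; when
#'   `NULL` the singular strategy is located first with
#'   [find_singularity()].
#' @param horizon Length of the temperature series binned (defaults to the
#'   averaging length of `inv_cfg`).
#' @param init Initial guess passed to the singularity search.
#' @return A data frame with columns `bin_center`, `frequency` (histogram
#'   density: bin mass / bin width) and `tpc_density`, with the singular
#'   strategy attached as attribute `"singularity"`. A constant
#'   (zero-variance) series collapses to a single occupied bin with a
#'   warning.
#' @export
temperature_histogram_with_tpc <- function(regime, params,
                                           inv_cfg = invasion_config(),
                                           bins = 50,
                                           singularity = NULL,
                                           horizon = inv_cfg$horizon_L,
                                           init = c(mu = 0.2, s = 0.08)) {
  stopifnot(bins >= 1)
  ts <- generate_temperature(regime, horizon)
  if (stats::sd(ts$values) == 0)
    warning("degenerate (constant) temperature series: ",
            "histogram occupies a single bin")
  breaks <- seq(0, 1, length.out = bins + 1)
  h <- graphics::hist(ts$values, breaks = breaks, plot = FALSE)
  if (is.null(singularity))
    singularity <- find_singularity(init, regime, params, inv_cfg)
  shape <- tpc_shape(singularity$mu_star, singularity$s_star)
  data.frame(bin_center = h$mids,
             frequency = h$density,
             tpc_density = beta_density(pmin(pmax(h$mids, 1e-9), 1 - 1e-9),
                                        shape)) -> out
  attr(out, "singularity") <- c(mu = singularity$mu_star,
                                s = singularity$s_star)
  out
}
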