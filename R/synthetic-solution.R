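## Synthetic solution-phase data. Each generator implements the forward
## model its paired analysis operation inverts, so at zero noise the
## analysis recovers the generating parameters exactly; at the default 1%
## multiplicative noise the generators emulate instrument-scale scatter.

#' Simulate a fluorescence quenching titration
#'
#' Linear Stern-Volmer model: F = F0 / (1 + K_SV [Q]). Modified
#' Stern-Volmer model: the quenched fraction x solves the 1:1 binding
#' quadratic \code{hsa x^2 - (K_D + hsa + [AD]) x + [AD] = 0}
#' (the exact inverse of the double-log regression, which identifies the
#' quenched fraction with the bound fraction of the protein), and
#' F = F0 (1 - x). F0 is fixed at 100 a.u.; each intensity is multiplied
#' by (1 + e), e ~ N(0, noise_sd_rel); non-positive draws are resampled
#' with a warning.
#'
#' @param spec \code{\link{generator_spec}}.
#' @param model \code{"linear_sv"} or \code{"modified_sv"}.
#' @param concs Quencher/titrant concentrations, M, strictly increasing.
#' @param K_SV Stern-Volmer constant for \code{linear_sv}, M^-1.
#' @param K_D Dissociation constant for \code{modified_sv}, M.
#' @param hsa_conc Fixed protein concentration for \code{modified_sv}, M.
#' @return \code{\link{titration_table}} (F0 = 100 recorded as a
#'   zero-concentration row).
#' @export
gen_quenching <- function(spec, model = c("linear_sv", "modified_sv"),
                          concs = seq(2e-6, 20e-6, length.out = 10),
                          K_SV = paper_defaults()$K_SV,
                          K_D = paper_defaults()$K_D_fluor,
                          hsa_conc = paper_defaults()$hsa_conc_fluor) {
  model <- match.arg(model)
  stopifnot(all(concs > 0), all(diff(concs) > 0))
  F0 <- 100
  f_true <- if (model == "linear_sv") {
    F0 / (1 + K_SV * concs)
  } else {
    b <- K_D + hsa_conc + concs
    x <- (b - sqrt(b^2 - 4 * hsa_conc * concs)) / (2 * hsa_conc)
    F0 * (1 - x)
  }
  f_obs <- with_spec_seed(spec, {
    out <- f_true * (1 + stats::rnorm(length(f_true), 0, spec$noise_sd_rel))
    bad <- which(out <= 0)
    while (length(bad)) {
      warning("resampling ", length(bad), " non-positive intensity draw(s)")
      out[bad] <- f_true[bad] *
        (1 + stats::rnorm(length(bad), 0, spec$noise_sd_rel))
      bad <- which(out <= 0)
    }
    out
  })
  titration_table(c(0, concs), c(F0, f_obs), analyte_label = "AD",
                  fixed_species_conc = if (model == "modified_sv") hsa_conc
                  else NA_real_)
}

#' Simulate an ITC experiment
#'
#' Noiseless heats from \code{\link{simulate_isotherm}}, then 1%
#' multiplicative noise plus additive baseline noise (default SD
#' 0.1 ucal, emulating peak-integration error).
#'
#' @param spec \code{\link{generator_spec}} (its \code{noise_sd_rel} is
#'   the multiplicative component).
#' @param design List with \code{cell_volume_uL}, \code{temperature_K},
#'   \code{cell_conc}, \code{syringe_conc}, \code{injection_volumes_uL}
#'   (default: the reference 208 uL / 30 uM protein / 900 uM titrant /
#'   19 x 2 uL design).
#' @param params \code{\link{binding_params}} (default: the reference
#'   K_d 13.4 uM, dH -4.02 kcal/mol, n 6).
#' @param n_agg,cmc Micelle parameters.
#' @param baseline_sd Additive noise SD, ucal (default 0.1).
#' @return \code{\link{injection_table}} with noisy heats.
#' @export
gen_itc <- function(spec, design = paper_defaults()$itc_design,
                    params = NULL, n_agg = paper_defaults()$N_agg,
                    cmc = paper_defaults()$CMC, baseline_sd = 0.1) {
  if (is.null(params)) {
    pd <- paper_defaults()
    params <- binding_params(pd$K_D_itc, pd$delta_H, pd$n_sites,
                             design$temperature_K)
  }
  tab <- injection_table(design$injection_volumes_uL,
                         rep(0, length(design$injection_volumes_uL)),
                         design$cell_volume_uL, design$temperature_K,
                         design$cell_conc, design$syringe_conc)
  q <- as.numeric(simulate_isotherm(tab, params, n_agg, cmc))
  q_obs <- with_spec_seed(spec, {
    q * (1 + stats::rnorm(length(q), 0, spec$noise_sd_rel)) +
      stats::rnorm(length(q), 0, baseline_sd)
  })
  tab$injections$heat_ucal <- q_obs
  tab
}

# helix basis: two negative Gaussian bands (208 pi-pi*, 222 n-pi*),
# calibrated so the 208 nm value is exactly -33000 at 100% helix
.helix_basis <- function(lambda) {
  g <- exp(-((lambda - 208) / 7)^2) + exp(-((lambda - 222) / 7)^2)
  g208 <- exp(0) + exp(-((208 - 222) / 7)^2)
  -33000 * g / g208
}

# coil basis: single band calibrated to -4000 at 208 nm
.coil_basis <- function(lambda) {
  g <- exp(-((lambda - 198) / 9)^2)
  -4000 * g / exp(-((208 - 198) / 9)^2)
}

#' Simulate a far-UV CD spectrum
#'
#' MRE(lambda) is the helicity-weighted sum of a helix basis (two negative
#' Gaussian bands at 208 and 222 nm, depth calibrated so MRE208 inverts
#' the helicity calibration exactly) and a coil basis (MRE208 = -4000).
#' MRE is converted to observed millidegrees by
#' mdeg = MRE x 10 Cp n l, and multiplicative noise is added.
#'
#' @param spec \code{\link{generator_spec}}.
#' @param helix_pct Helix percentage in [0, 100].
#' @param params \code{\link{cd_params}} (concentration, residues, path).
#' @param lambda Wavelength grid, nm (default 200-260 by 0.5).
#' @return \code{\link{spectrum_table}} of wavelength vs mdeg.
#' @export
gen_cd_spectrum <- function(spec, helix_pct,
                            params = cd_params(2e-6, 585L, 0.1),
                            lambda = seq(200, 260, by = 0.5)) {
  if (helix_pct < 0 || helix_pct > 100)
    stop("domain error: helix_pct must be in [0, 100]", call. = FALSE)
  h <- helix_pct / 100
  mre <- h * .helix_basis(lambda) + (1 - h) * .coil_basis(lambda)
  mdeg <- mre * 10 * params$Cp * params$n_res * params$path_cm
  mdeg_obs <- with_spec_seed(spec, {
    mdeg * (1 + stats::rnorm(length(mdeg), 0, spec$noise_sd_rel))
  })
  spectrum_table(lambda, mdeg_obs, x_unit = "nm")
}

#' Simulate a two-state thermal melt
#'
#' Sigmoid theta(T) = theta_F + (theta_U - theta_F)/(1 + exp((T_M - T)/w))
#' sampled every 1 degC over 25-95 degC, plus multiplicative noise on the
#' transition amplitude.
#'
#' @param spec \code{\link{generator_spec}}.
#' @param T_M Melting temperature, degC.
#' @param width Transition width w, degC (default 3).
#' @param baselines Numeric pair (folded, unfolded) ellipticity, mdeg.
#' @param T_grid Temperature grid, degC.
#' @return \code{\link{spectrum_table}} with temperature on x.
#' @export
gen_melt_curve <- function(spec, T_M, width = 3,
                           baselines = c(-20, -4), T_grid = seq(25, 95, 1)) {
  stopifnot(length(baselines) == 2L, width > 0)
  theta <- baselines[1] + (baselines[2] - baselines[1]) /
    (1 + exp((T_M - T_grid) / width))
  amp <- abs(baselines[2] - baselines[1])
  theta_obs <- with_spec_seed(spec, {
    theta + stats::rnorm(length(theta), 0, spec$noise_sd_rel * amp)
  })
  spectrum_table(T_grid, theta_obs, x_unit = "degC")
}
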