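#' Reference binding and spectroscopy constants
#'
#' Frozen experimental constants for the HSA / amphiphilic-dendrimer (AD)
#' nanomicelle system that the synthetic-data generators use as their
#' default "true" parameters. All concentrations are molar, energies are
#' kcal/mol, temperatures Kelvin unless the name says otherwise.
#'
#' @return Named list:
#' \describe{
#'   \item{K_SV}{Stern-Volmer quenching constant, 4.9e4 M^-1.}
#'   \item{K_D_fluor}{Dissociation constant from the modified Stern-Volmer
#'     regression, 22.9e-6 M.}
#'   \item{K_D_itc}{Dissociation constant from ITC, 13.4e-6 M.}
#'   \item{delta_H}{Binding enthalpy per mole of protein bound, -4.02 kcal/mol.}
#'   \item{n_sites}{Independent protein sites per micelle, 6.}
#'   \item{N_agg}{Micelle aggregation number, 17.}
#'   \item{CMC}{Critical micellar concentration, 4.5e-6 M (midpoint of the
#'     reported 3.2--5.7 uM range).}
#'   \item{helix_free}{Alpha-helix percentage of the unbound protein, 59.3.}
#'   \item{helix_bound_max_AD}{Helix percentage at the highest AD
#'     concentration, 56.1.}
#'   \item{T_M_free}{Default melting temperature of the free protein, 65 degC.}
#'   \item{dT_M_bound}{Melting-temperature depression on micelle binding,
#'     3 degC.}
#'   \item{hsa_conc_fluor}{Fixed protein concentration in the quenching
#'     assay, 2e-6 M.}
#'   \item{n_res}{Protein residue count (HSA), 585.}
#'   \item{path_cm}{CD cell path length tied to the helicity formula, 0.1 cm.}
#'   \item{itc_design}{List with the printed titration design: cell_volume_uL
#'     208, temperature_K 298, cell_conc 30e-6 M, syringe_conc 900e-6 M,
#'     19 injections of 2 uL.}
#' }
#' @export
paper_defaults <- function() {
  list(
    K_SV = 4.9e4,
    K_D_fluor = 22.9e-6,
    K_D_itc = 13.4e-6,
    delta_H = -4.02,
    n_sites = 6,
    N_agg = 17,
    CMC = 4.5e-6,
    helix_free = 59.3,
    helix_bound_max_AD = 56.1,
    T_M_free = 65,
    dT_M_bound = 3,
    hsa_conc_fluor = 2e-6,
    n_res = 585L,
    path_cm = 0.1,
    itc_design = list(
      cell_volume_uL = 208,
      temperature_K = 298,
      cell_conc = 30e-6,
      syringe_conc = 900e-6,
      injection_volumes_uL = rep(2, 19)
    )
  )
}

#' Generator specification
#'
#' Bundles the random seed and relative noise level shared by all synthetic
#' generators. Identical specs produce bit-identical output.
#'
#' @param seed Integer seed.
#' @param noise_sd_rel Standard deviation of the multiplicative Gaussian
#'   noise, as a fraction of the signal (default 0.01). Set to 0 for
#'   noiseless data.
#' @param ... Stage-specific parameters stored alongside (passed through to
#'   individual generators).
#' @return Object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(seed = 1L, noise_sd_rel = 0.01, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(noise_sd_rel) || noise_sd_rel < 0)
    stop("noise_sd_rel must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), noise_sd_rel = noise_sd_rel,
                 extra = list(...)),
            class = "generator_spec")
}

# Gas constant in kcal mol^-1 K^-1 (standard state 1 M)
.R_KCAL <- 1.9872e-3

# run generator body under its own RNG stream, restoring global state
with_spec_seed <- function(spec, expr) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  expr
}
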