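## Micelle-aware one-set-of-sites ITC analysis.
##
## The titrant self-assembles: above the critical micellar concentration
## (CMC) added amphiphile partitions into micelles of N_agg monomers, and
## the micelle - not the monomer - is the species carrying n independent,
## identical protein binding sites. Total amphiphile is converted to
## micelle concentration by mass conservation
## [AD_tot] = [AD_mon] + N_agg x [AD_mic], and the classic 1:1 mass-action
## quadratic then gives the bound-complex concentration per injection.

#' Partition total amphiphile into monomer and micelle
#'
#' Mass-conservation split: below the CMC everything is monomeric; above
#' it the monomer pool is pinned at the CMC and the excess is micellar,
#' \code{ad_micelle = (ad_total - cmc) / n_agg}.
#'
#' @param ad_total Total amphiphile concentration, M.
#' @param n_agg Aggregation number (monomers per micelle), >= 1.
#' @param cmc Critical micellar concentration, M.
#' @return List of class \code{"micelle_state"}: \code{ad_total},
#'   \code{ad_monomer}, \code{ad_micelle}, \code{n_agg}. The invariant
#'   \code{ad_monomer + n_agg * ad_micelle == ad_total} holds exactly.
#' @export
micelle_concentration <- function(ad_total, n_agg, cmc) {
  if (ad_total < 0 || cmc < 0 || n_agg < 1)
    stop("domain error: ad_total, cmc must be >= 0 and n_agg >= 1",
         call. = FALSE)
  if (ad_total <= cmc) {
    mon <- ad_total; mic <- 0
  } else {
    mic <- (ad_total - cmc) / n_agg
    mon <- ad_total - n_agg * mic  # exact complement, not 'cmc'
  }
  structure(list(ad_total = ad_total, ad_monomer = mon, ad_micelle = mic,
                 n_agg = n_agg), class = "micelle_state")
}

#' Binding parameters for the one-set-of-sites model
#'
#' @param K_d Dissociation constant, M (> 0).
#' @param delta_H Binding enthalpy per mole of protein bound, kcal/mol.
#' @param n_sites Independent identical protein sites per micelle (> 0).
#' @param T Temperature, K.
#' @return List of class \code{"binding_params"}.
#' @export
binding_params <- function(K_d, delta_H, n_sites, T = 298) {
  stopifnot(K_d > 0, n_sites > 0, T > 0)
  structure(list(K_d = K_d, delta_H = delta_H, n_sites = n_sites, T = T),
            class = "binding_params")
}

# bound complex from the 1:1 mass-action quadratic, numerically stable form
.bound_complex <- function(H, S, K_d) {
  b <- H + S + K_d
  disc <- b * b - 4 * H * S
  disc[disc < 0 & disc > -1e-25] <- 0
  stopifnot(all(disc >= 0))
  # smaller root via the conjugate form (avoids cancellation)
  2 * H * S / (b + sqrt(disc))
}

#' Simulate a one-set-of-sites ITC isotherm
#'
#' Forward model of the integrated injection heats under the overflow
#' (perfusion) dilution convention: at each injection every species
#' already in the cell is diluted by (1 - dV/V0) while the new aliquot
#' adds dV * c_syringe / V0. The syringe amphiphile concentration is
#' converted once to micelle concentration via
#' \code{\link{micelle_concentration}} (the syringe is far above the CMC).
#' Bound complex comes from the mass-action quadratic; the injection heat
#' is the change in cell heat content plus the displaced-volume
#' correction:
#' \deqn{\delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2.}
#'
#' @param design \code{\link{injection_table}} (heats ignored) or a list
#'   with \code{cell_volume_uL}, \code{cell_conc}, \code{syringe_conc},
#'   \code{injections$volume_uL}.
#' @param params \code{\link{binding_params}}.
#' @param n_agg,cmc Micelle aggregation number and CMC (M).
#' @return Numeric vector of per-injection heats in ucal, with attribute
#'   \code{"molar_ratio"} giving the cell [protein]/[micelle] ratio after
#'   each injection.
#' @export
simulate_isotherm <- function(design, params, n_agg = 17, cmc = 4.5e-6) {
  stopifnot(inherits(params, "binding_params"))
  V0 <- design$cell_volume_uL  # volumes cancel in concentrations; uL ok
  dV <- design$injections$volume_uL
  stopifnot(V0 > 0, all(dV > 0))
  mic_syr <- micelle_concentration(design$syringe_conc, n_agg, cmc)$ad_micelle
  H <- design$cell_conc   # protein, M
  M <- 0                  # micelle, M
  V0_L <- V0 * 1e-6
  Q_prev <- 0
  heats <- numeric(length(dV))
  ratio <- numeric(length(dV))
  for (i in seq_along(dV)) {
    f <- 1 - dV[i] / V0
    H <- H * f
    M <- M * f + (dV[i] / V0) * mic_syr
    S <- params$n_sites * M
    HS <- .bound_complex(H, S, params$K_d)
    Q <- HS * params$delta_H * V0_L * 1e9  # kcal -> ucal
    heats[i] <- Q - Q_prev + (dV[i] / V0) * (Q + Q_prev) / 2
    ratio[i] <- if (M > 0) H / M else Inf
    Q_prev <- Q
  }
  attr(heats, "molar_ratio") <- ratio
  heats
}

#' Gibbs energy / enthalpy / entropy decomposition
#'
#' \eqn{\Delta G = RT \ln K_d} (dissociation constant in M, standard state
#' 1 M, R = 1.9872e-3 kcal/mol/K) and \eqn{-T\Delta S = \Delta G - \Delta H}.
#'
#' @param K_d Dissociation constant, M.
#' @param delta_H Binding enthalpy, kcal/mol.
#' @param T Temperature, K.
#' @return List of class \code{"thermo_triplet"}: \code{delta_G},
#'   \code{delta_H}, \code{minus_T_delta_S} (kcal/mol). The closure
#'   \code{delta_G = delta_H + minus_T_delta_S} holds to machine precision.
#' @export
derive_thermodynamics <- function(K_d, delta_H, T = 298) {
  stopifnot(K_d > 0, T > 0)
  dG <- .R_KCAL * T * log(K_d)
  structure(list(delta_G = dG, delta_H = delta_H,
                 minus_T_delta_S = dG - delta_H),
            class = "thermo_triplet")
}

#' @export
print.thermo_triplet <- function(x, ...) {
  cat(sprintf("  dG    = %7.3f kcal/mol\n  dH    = %7.3f kcal/mol\n  -TdS  = %7.3f kcal/mol\n",
              x$delta_G, x$delta_H, x$minus_T_delta_S))
  invisible(x)
}

# SSE of the isotherm with (delta_H [, offset]) profiled out analytically:
# model heats are linear in delta_H, so the inner solve is least squares
.itc_sse <- function(log10_Kd, n_sites, design, q_obs, n_agg, cmc, w,
                     fit_offset) {
  p <- binding_params(10^log10_Kd, -1, n_sites, 298)
  g <- as.numeric(simulate_isotherm(design, p, n_agg, cmc))  # heats at dH=-1
  X <- if (fit_offset) cbind(g, 1) else cbind(g)
  XtW <- t(X * w)
  beta <- tryCatch(solve(XtW %*% X, XtW %*% q_obs),
                   error = function(e) matrix(c(0, 0)[seq_len(ncol(X))]))
  resid <- q_obs - X %*% beta
  list(sse = sum(w * resid^2), delta_H = -beta[1],
       offset = if (fit_offset) beta[2] else 0)
}

#' Fit the one-set-of-sites ITC model
#'
#' Nonlinear least squares of \code{\link{simulate_isotherm}} against the
#' measured integrated heats, over (K_d, delta_H, and optionally n_sites).
#' delta_H (and the optional constant heat offset) enter the model
#' linearly and are profiled out; the outer search over
#' (log10 K_d, log n_sites) uses Nelder-Mead from 8 multi-starts with K_d
#' log-spaced over 1e-9..1e-3 M, keeping the best sum of squares.
#'
#' @param experiment \code{\link{injection_table}} with measured heats.
#' @param n_agg,cmc Micelle parameters entering the mass-conservation
#'   transform.
#' @param fit_n Float the stoichiometry n_sites (default TRUE); when FALSE
#'   it is fixed at \code{n_fixed}.
#' @param n_fixed Fixed n_sites when \code{fit_n = FALSE}.
#' @param discard_first Drop the first injection before fitting (common
#'   practice for the diffusion-compromised first aliquot; default FALSE).
#' @param fit_offset Also estimate a constant per-injection heat offset.
#' @param weights Optional per-injection weights (default uniform).
#' @return Object of class \code{"itc_fit"}: \code{params}
#'   (\code{\link{binding_params}}), \code{se} (standard errors of K_d,
#'   delta_H, n_sites), \code{thermo} (\code{\link{thermo_triplet}} at the
#'   design temperature), \code{reduced_chi2}, \code{n_discarded},
#'   \code{fitted}, \code{molar_ratio}, \code{flag}.
#' @export
fit_one_site <- function(experiment, n_agg = 17, cmc = 4.5e-6, fit_n = TRUE,
                         n_fixed = 6, discard_first = FALSE,
                         fit_offset = FALSE, weights = NULL) {
  stopifnot(inherits(experiment, "injection_table"))
  design <- experiment
  q_obs <- experiment$injections$heat_ucal
  n_discard <- 0L
  fit_idx <- seq_along(q_obs)
  if (discard_first) {
    fit_idx <- fit_idx[-1]
    n_discard <- 1L
  }
  if (length(fit_idx) < 5L)
    stop("fit error: fewer than 5 usable injections", call. = FALSE)
  w_full <- if (is.null(weights)) rep(1, length(q_obs)) else weights
  w <- w_full
  w[setdiff(seq_along(q_obs), fit_idx)] <- 0

  # n_sites start: sites ~ protein at the steepest drop of |q| (inflection)
  dq <- diff(abs(q_obs[fit_idx]))
  i_inf <- fit_idx[which.min(dq)]
  mic_syr <- micelle_concentration(design$syringe_conc, n_agg, cmc)$ad_micelle
  Hc <- design$cell_conc; Mc <- 0
  for (i in seq_len(i_inf)) {
    f <- 1 - design$injections$volume_uL[i] / design$cell_volume_uL
    Hc <- Hc * f
    Mc <- Mc * f + design$injections$volume_uL[i] / design$cell_volume_uL *
      mic_syr
  }
  n0 <- if (Mc > 0) max(0.5, min(50, Hc / Mc)) else 1

  obj <- function(theta) {
    n_sites <- if (fit_n) exp(theta[2]) else n_fixed
    .itc_sse(theta[1], n_sites, design, q_obs, n_agg, cmc, w, fit_offset)$sse
  }
  starts <- seq(-9, -3, length.out = 8)
  best <- NULL
  for (s in starts) {
    th0 <- if (fit_n) c(s, log(n0)) else s
    opt <- if (fit_n)
      stats::optim(th0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    else
      stats::optim(th0, obj, method = "Brent", lower = -12, upper = 0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fit error: no start converged", call. = FALSE)
  th <- best$par
  K_d <- 10^th[1]
  n_sites <- if (fit_n) exp(th[2]) else n_fixed
  inner <- .itc_sse(th[1], n_sites, design, q_obs, n_agg, cmc, w, fit_offset)
  delta_H <- inner$delta_H
  flag <- if (th[1] <= -9 + 1e-6 || th[1] >= -3 + 1) "K_d_at_bound" else "ok"

  # standard errors from the numerical Hessian of the full SSE in
  # (log10 Kd, dH, log n); sigma^2 from the residual variance
  full_sse <- function(p) {
    pr <- binding_params(10^p[1], p[2], exp(p[3]), 298)
    mdl <- as.numeric(simulate_isotherm(design, pr, n_agg, cmc)) +
      inner$offset
    sum(w * (q_obs - mdl)^2)
  }
  p_hat <- c(th[1], delta_H, log(n_sites))
  n_par <- if (fit_n) 3 else 2
  n_use <- length(fit_idx)
  sigma2 <- best$value / max(1, n_use - n_par - fit_offset)
  se <- rep(NA_real_, 3)
  Hm <- tryCatch(stats::optimHess(p_hat, full_sse), error = function(e) NULL)
  if (!is.null(Hm)) {
    cv <- tryCatch(solve(Hm / 2) * sigma2, error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) se <- sqrt(diag(cv))
  }
  se_out <- c(K_d = log(10) * K_d * se[1], delta_H = se[2],
              n_sites = n_sites * se[3])

  params <- binding_params(K_d, delta_H, n_sites, design$temperature_K)
  fitted <- as.numeric(simulate_isotherm(design, params, n_agg, cmc)) +
    inner$offset
  mr <- attr(simulate_isotherm(design, params, n_agg, cmc), "molar_ratio")
  structure(list(
    params = params,
    se = se_out,
    thermo = derive_thermodynamics(K_d, delta_H, design$temperature_K),
    reduced_chi2 = sigma2,
    n_discarded_injections = n_discard,
    offset = inner$offset,
    fitted = fitted,
    observed = q_obs,
    molar_ratio = mr,
    sse = best$value,
    flag = flag, n_agg = n_agg, cmc = cmc), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-set-of-sites ITC fit (micelle mass-conservation transform)\n")
  cat(sprintf("  K_d     = %.4g M (se %.2g)\n", x$params$K_d, x$se["K_d"]))
  cat(sprintf("  dH      = %.4g kcal/mol (se %.2g)\n",
              x$params$delta_H, x$se["delta_H"]))
  cat(sprintf("  n_sites = %.3g (se %.2g)\n", x$params$n_sites,
              x$se["n_sites"]))
  cat(sprintf("  reduced chi^2 = %.4g, discarded injections = %d\n",
              x$reduced_chi2, x$n_discarded_injections))
  print(x$thermo)
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.itc_fit <- function(object, ...)
  c(K_d = object$params$K_d, delta_H = object$params$delta_H,
    n_sites = object$params$n_sites)

#' @export
predict.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) object$observed - object$fitted

#' @export
plot.itc_fit <- function(x, ...) {
  graphics::plot(x$molar_ratio, x$observed, xlab = "[protein]/[micelle]",
                 ylab = "heat (ucal)", main = "ITC isotherm", ...)
  graphics::lines(x$molar_ratio, x$fitted, col = 2)
  invisible(x)
}
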