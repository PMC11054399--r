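## Circular dichroism analysis: mean residue ellipticity at 208 nm,
## alpha-helix percentage from the MRE208 calibration, and two-state
## thermal-melt fitting at 222 nm.

#' CD cell and sample parameters
#'
#' @param Cp Molar protein concentration, M.
#' @param n_res Number of residues in the protein (585 for HSA).
#' @param path_cm Cell path length, cm (default 0.1).
#' @return List of class \code{"cd_params"}.
#' @export
cd_params <- function(Cp, n_res = 585L, path_cm = 0.1) {
  stopifnot(Cp > 0, n_res > 0, path_cm > 0)
  structure(list(Cp = Cp, n_res = as.integer(n_res), path_cm = path_cm),
            class = "cd_params")
}

#' Mean residue ellipticity at 208 nm
#'
#' MRE208 = observed CD (mdeg) / (10 Cp n l) with Cp in mol/L, n the
#' residue count and l the path in cm. The observed ellipticity at 208 nm
#' is obtained by linear interpolation between the bracketing samples.
#'
#' @param spectrum \code{\link{spectrum_table}} of wavelength (nm) vs
#'   ellipticity (mdeg); 208 nm must lie within its range.
#' @param params \code{\link{cd_params}}.
#' @return MRE at 208 nm, deg cm^2 dmol^-1.
#' @export
mre_at_208 <- function(spectrum, params) {
  stopifnot(inherits(spectrum, "spectrum_table"),
            inherits(params, "cd_params"))
  if (208 < min(spectrum$x) || 208 > max(spectrum$x))
    stop("domain error: 208 nm outside the spectrum range [",
         min(spectrum$x), ", ", max(spectrum$x), "]", call. = FALSE)
  mdeg <- stats::approx(spectrum$x, spectrum$y, xout = 208)$y
  mdeg / (10 * params$Cp * params$n_res * params$path_cm)
}

#' Alpha-helix percentage from MRE208
#'
#' Helicity calibration against the reference mean residue ellipticities
#' of pure alpha-helix (-33,000 deg cm^2 dmol^-1) and beta/coil
#' (-4,000 deg cm^2 dmol^-1) at 208 nm:
#' helix \% = (-MRE208 - 4000) / 29000 x 100. Values outside [0, 100]
#' (possible for noisy spectra) are clamped and flagged.
#'
#' @param mre208 Mean residue ellipticity at 208 nm, deg cm^2 dmol^-1.
#' @return Helix percentage in [0, 100], with attribute
#'   \code{"out_of_range"} (logical).
#' @export
helix_fraction <- function(mre208) {
  raw <- (-mre208 - 4000) / (33000 - 4000) * 100
  out <- raw < 0 | raw > 100
  structure(pmin(100, pmax(0, raw)), out_of_range = out)
}

#' Fit a two-state thermal melt
#'
#' Nonlinear least squares of the two-state sigmoid
#' \deqn{\theta(T) = \theta_F + (\theta_U - \theta_F)/(1 + e^{(T_M - T)/w})}
#' to an ellipticity-vs-temperature curve. Initial values: T_M at the
#' maximum absolute finite-difference slope, baselines from the first and
#' last 10\% of points. Falls back to a (T_M, width) grid search with
#' linear baselines if the Levenberg-Marquardt run fails.
#'
#' @param melt \code{\link{spectrum_table}} with temperature (degC) on x.
#' @return Object of class \code{"melt_fit"}: \code{T_M} and \code{width}
#'   (degC), \code{se_T_M}, \code{baselines} (folded, unfolded; mdeg),
#'   \code{flag} (\code{"boundary"} if T_M is at the scanned edge).
#' @export
fit_melting <- function(melt) {
  stopifnot(inherits(melt, "spectrum_table"))
  T <- melt$x; y <- melt$y
  if (length(T) < 10L)
    stop("fit error: need at least 10 temperature points", call. = FALSE)
  if (T[1] > T[length(T)]) { T <- rev(T); y <- rev(y) }
  slope <- diff(y) / diff(T)
  if (all(abs(slope - mean(slope)) < 1e-12 * (abs(mean(slope)) + 1)))
    stop("fit error: no transition (constant derivative)", call. = FALSE)
  i_inf <- which.max(abs(slope))
  Tm0 <- (T[i_inf] + T[i_inf + 1]) / 2
  k <- max(2L, ceiling(length(T) * 0.1))
  thF0 <- mean(y[seq_len(k)])
  thU0 <- mean(y[seq(length(y) - k + 1L, length(y))])
  if (abs(thU0 - thF0) < .Machine$double.eps * 100)
    stop("fit error: no transition (flat baselines)", call. = FALSE)
  dat <- data.frame(T = T, y = y)
  model <- y ~ thF + (thU - thF) / (1 + exp((Tm - T) / w))
  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = dat,
                      start = list(thF = thF0, thU = thU0, Tm = Tm0, w = 2),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # grid fallback: (Tm, w) grid, baselines solved linearly per node
    grid <- expand.grid(Tm = seq(min(T), max(T), by = 0.1),
                        w = seq(0.5, 10, by = 0.25))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      s <- 1 / (1 + exp((grid$Tm[g] - T) / grid$w[g]))
      cf <- stats::lm.fit(cbind(1, s), y)$coefficients
      sse <- sum((y - cf[1] - cf[2] * s)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(sse = sse, Tm = grid$Tm[g], w = grid$w[g],
                     thF = cf[1], thU = cf[1] + cf[2])
    }
    res <- list(T_M = best$Tm, width = best$w, se_T_M = NA_real_,
                baselines = c(folded = best$thF, unfolded = best$thU),
                sse = best$sse)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients["Tm", "Std. Error"],
                   error = function(e) NA_real_)
    res <- list(T_M = unname(cf["Tm"]), width = unname(abs(cf["w"])),
                se_T_M = se,
                baselines = c(folded = unname(cf["thF"]),
                              unfolded = unname(cf["thU"])),
                sse = sum(stats::resid(fit)^2))
  }
  res$flag <- if (res$T_M <= min(T) || res$T_M >= max(T)) "boundary" else "ok"
  res$data <- dat
  structure(res, class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state thermal melt fit\n")
  cat(sprintf("  T_M   = %.2f degC (se %.3g)\n  width = %.2f degC\n",
              x$T_M, x$se_T_M, x$width))
  cat(sprintf("  baselines: folded %.3g, unfolded %.3g mdeg\n",
              x$baselines[1], x$baselines[2]))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.melt_fit <- function(object, ...)
  c(T_M = object$T_M, width = object$width,
    theta_F = unname(object$baselines[1]),
    theta_U = unname(object$baselines[2]))

#' @export
predict.melt_fit <- function(object, T = NULL, ...) {
  if (is.null(T)) T <- object$data$T
  thF <- object$baselines[1]; thU <- object$baselines[2]
  unname(thF + (thU - thF) / (1 + exp((object$T_M - T) / object$width)))
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$data$T, x$data$y, xlab = "temperature (degC)",
                 ylab = "ellipticity (mdeg)", main = "thermal melt", ...)
  Ts <- seq(min(x$data$T), max(x$data$T), length.out = 200)
  graphics::lines(Ts, predict(x, Ts), col = 2)
  invisible(x)
}

#' Helicity from a CD spectrum
#'
#' Convenience composition of \code{\link{mre_at_208}} and
#' \code{\link{helix_fraction}}.
#'
#' @param spectrum \code{\link{spectrum_table}} (wavelength, mdeg).
#' @param params \code{\link{cd_params}}.
#' @return List of class \code{"helicity_result"}: \code{mre208},
#'   \code{helix_pct}, \code{out_of_range}.
#' @export
helicity_from_spectrum <- function(spectrum, params) {
  mre <- mre_at_208(spectrum, params)
  h <- helix_fraction(mre)
  structure(list(mre208 = mre, helix_pct = as.numeric(h),
                 out_of_range = attr(h, "out_of_range")),
            class = "helicity_result")
}

#' @export
print.helicity_result <- function(x, ...) {
  cat(sprintf("MRE208 = %.0f deg cm^2 dmol^-1  ->  helix = %.1f %%%s\n",
              x$mre208, x$helix_pct,
              if (isTRUE(x$out_of_range)) " (clamped)" else ""))
  invisible(x)
}
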