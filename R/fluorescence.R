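## Fluorescence quenching analysis. The intrinsic tryptophan fluorescence
## of the protein is quenched by the titrant; the Stern-Volmer slope
## quantifies quenching and the modified (double-logarithmic) Stern-Volmer
## regression yields the dissociation constant of the complex.

# F0 resolution: explicit argument wins, else the zero-quencher row
.resolve_F0 <- function(t, F0) {
  if (!is.null(F0)) {
    stopifnot(F0 > 0)
    return(F0)
  }
  z <- which(t$conc == 0)
  if (length(z)) return(t$intensity[z[1]])
  stop("F0 not supplied and no zero-quencher row present", call. = FALSE)
}

#' Fit the Stern-Volmer quenching model
#'
#' Ordinary least squares of F0/F against quencher concentration:
#' F0/F = 1 + K_SV [Q]. The intercept is left free (not constrained to 1)
#' as a diagnostic; the slope is the Stern-Volmer constant K_SV.
#'
#' @param t \code{\link{titration_table}} (concentrations in M).
#' @param F0 Fluorescence without quencher. Defaults to the intensity of a
#'   zero-concentration row when one is present.
#' @return Object of class \code{"sv_fit"}: \code{K_SV} (M^-1),
#'   \code{se_K_SV}, \code{intercept}, \code{r_squared}, \code{flag}
#'   (\code{"ok"}, \code{"no_quenching"} or \code{"negative_K_SV"}), plus
#'   the underlying data. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{residuals}.
#' @export
fit_stern_volmer <- function(t, F0 = NULL) {
  stopifnot(inherits(t, "titration_table"))
  F0 <- .resolve_F0(t, F0)
  q <- t$conc
  ratio <- F0 / t$intensity
  if (length(q) < 3L) stop("fit error: fewer than 3 points", call. = FALSE)
  fit <- stats::lm(ratio ~ q)
  # summary.lm warns on exactly collinear (noise-free or constant) input;
  # both are legitimate cases here and handled by the flag below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  flag <- "ok"
  r2 <- sm$r.squared
  if (all(abs(ratio - ratio[1]) < 1e-12)) {
    # no quenching at all: slope and R^2 are degenerate
    slope <- 0
    flag <- "no_quenching"
    r2 <- 0
  } else if (slope < 0) flag <- "negative_K_SV"
  if (flag == "negative_K_SV")
    warning("fitted K_SV is negative: no quenching with increasing [Q]")
  structure(list(
    K_SV = slope,
    se_K_SV = if (flag == "no_quenching") 0 else unname(sm$coefficients[2, 2]),
    intercept = if (flag == "no_quenching") 1 else unname(stats::coef(fit)[1]),
    r_squared = max(0, min(1, r2)),
    flag = flag, F0 = F0, data = data.frame(conc = q, ratio = ratio),
    lm = fit), class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Stern-Volmer quenching fit\n")
  cat(sprintf("  K_SV      = %.4g M^-1 (se %.2g)\n", x$K_SV, x$se_K_SV))
  cat(sprintf("  intercept = %.4f\n  R^2       = %.4f\n",
              x$intercept, x$r_squared))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.sv_fit <- function(object, ...)
  c(K_SV = object$K_SV, intercept = object$intercept)

#' @export
predict.sv_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc
  object$intercept + object$K_SV * conc
}

#' @export
residuals.sv_fit <- function(object, ...)
  object$data$ratio - predict.sv_fit(object)

#' Fit the modified Stern-Volmer (double-log) binding model
#'
#' Linear regression of log10((F0-F)/F) on
#' log10([AD] - (F0-F)[HSA]/F0), the free-titrant concentration after
#' accounting for the bound fraction. The dissociation constant is
#' K_D = 10^(-intercept); the slope is reported as a diagnostic and is
#' close to 1 for a single independent binding site.
#'
#' @param t \code{\link{titration_table}} of titrant concentration (M)
#'   vs intensity.
#' @param F0 Fluorescence without titrant (default: zero-concentration row).
#' @param hsa_conc Fixed protein concentration in M (default: the table's
#'   \code{fixed_species_conc} attribute).
#' @return Object of class \code{"msv_fit"}: \code{K_D} (M), \code{se_K_D},
#'   \code{slope}, \code{r_squared}, \code{n_excluded}.
#' @export
fit_modified_stern_volmer <- function(t, F0 = NULL, hsa_conc = NULL) {
  stopifnot(inherits(t, "titration_table"))
  F0 <- .resolve_F0(t, F0)
  if (is.null(hsa_conc)) hsa_conc <- attr(t, "fixed_species_conc")
  if (is.null(hsa_conc) || is.na(hsa_conc))
    stop("hsa_conc not supplied and not recorded in the table",
         call. = FALSE)
  keep <- t$conc > 0
  q <- t$conc[keep]; f <- t$intensity[keep]
  dF <- F0 - f
  free_ad <- q - dF * hsa_conc / F0
  ok <- dF > 0 & f > 0 & free_ad > 0
  if (any(!ok))
    warning(sum(!ok), " point(s) excluded (no quenching or negative free ",
            "titrant)")
  if (sum(ok) < 3L)
    stop("fit error: fewer than 3 usable points after exclusions",
         call. = FALSE)
  y <- log10(dF[ok] / f[ok])
  x <- log10(free_ad[ok])
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  intc <- unname(stats::coef(fit)[1])
  se_int <- unname(sm$coefficients[1, 2])
  K_D <- 10^(-intc)
  structure(list(
    K_D = K_D,
    se_K_D = log(10) * K_D * se_int,  # delta method on the intercept
    slope = unname(stats::coef(fit)[2]),
    r_squared = sm$r.squared,
    n_excluded = sum(!ok),
    F0 = F0, hsa_conc = hsa_conc,
    data = data.frame(log_free_ad = x, log_ratio = y),
    lm = fit), class = "msv_fit")
}

#' @export
print.msv_fit <- function(x, ...) {
  cat("Modified Stern-Volmer binding fit\n")
  cat(sprintf("  K_D   = %.4g M (se %.2g)\n", x$K_D, x$se_K_D))
  cat(sprintf("  slope = %.4f (diagnostic, ~1 expected)\n  R^2   = %.4f\n",
              x$slope, x$r_squared))
  if (x$n_excluded > 0) cat("  excluded points:", x$n_excluded, "\n")
  invisible(x)
}

#' @export
summary.msv_fit <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.msv_fit <- function(object, ...)
  c(K_D = object$K_D, slope = object$slope)

#' Locate peaks in an excitation-emission matrix
#'
#' Masks the first-order Rayleigh scattering diagonal
#' (|lambda_em - lambda_ex| <= halfwidth), then reports local maxima whose
#' intensity exceeds mean + 3 SD of the unmasked cells, sorted by
#' intensity, descending.
#'
#' @param eem Intensity matrix, rows indexed by \code{lambda_ex}, columns
#'   by \code{lambda_em}.
#' @param lambda_ex,lambda_em Monotone axis vectors (nm).
#' @param rayleigh_halfwidth Half-width of the diagonal mask, nm
#'   (default 10).
#' @return \code{data.frame} with columns \code{lambda_ex},
#'   \code{lambda_em}, \code{intensity} (possibly zero rows).
#' @export
locate_eem_peaks <- function(eem, lambda_ex, lambda_em,
                             rayleigh_halfwidth = 10) {
  stopifnot(is.matrix(eem), nrow(eem) == length(lambda_ex),
            ncol(eem) == length(lambda_em))
  if (any(diff(lambda_ex) <= 0) || any(diff(lambda_em) <= 0))
    stop("axes must be strictly increasing", call. = FALSE)
  dl <- abs(outer(lambda_ex, lambda_em, function(a, b) b - a))
  masked <- dl <= rayleigh_halfwidth
  vals <- eem[!masked]
  empty <- data.frame(lambda_ex = numeric(0), lambda_em = numeric(0),
                      intensity = numeric(0))
  if (!length(vals)) return(empty)
  thresh <- mean(vals) + 3 * stats::sd(vals)
  if (!is.finite(thresh)) thresh <- mean(vals)
  nr <- nrow(eem); nc <- ncol(eem)
  hits <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (masked[i, j] || eem[i, j] <= thresh) next
    nb <- eem[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (eem[i, j] >= max(nb))
      hits[[length(hits) + 1L]] <- c(lambda_ex[i], lambda_em[j], eem[i, j])
  }
  if (!length(hits)) return(empty)
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("lambda_ex", "lambda_em", "intensity")
  out[order(-out$intensity), , drop = FALSE]
}
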