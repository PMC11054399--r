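## Shrake-Rupley solvent-accessible surface area.

# van der Waals radii (Angstrom) used when the atom table carries no
# explicit radius column
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90)

# quasi-uniform points on the unit sphere (Fibonacci lattice);
# deterministic, so SASA is reproducible at fixed n
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places \code{n_points} quasi-uniform test points on each atom's
#' expanded sphere (radius r_i + probe); a point is exposed when it lies
#' outside every neighbouring expanded sphere. The atom's area is the
#' exposed fraction times \eqn{4\pi (r_i + probe)^2}.
#'
#' @param traj \code{\link{trajectory}}.
#' @param sel Atom indices (default all); only selected atoms contribute
#'   area and occlusion.
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @param frame Frame index (default 1).
#' @param radii Optional named vector of per-element radii overriding the
#'   built-in van der Waals table; a \code{radius} column in the atom
#'   table takes precedence over both.
#' @return List of class \code{"sasa_result"}: \code{total} (A^2),
#'   \code{per_residue} (named chain:resid), \code{per_atom},
#'   \code{probe}, \code{n_sphere_points}.
#' @export
sasa <- function(traj, sel = NULL, probe = 1.4, n_points = 960L,
                 frame = 1L, radii = NULL) {
  stopifnot(inherits(traj, "trajectory"), probe >= 0, n_points >= 12)
  sel <- .resolve_sel(traj, sel)
  xyz <- .frame_xyz(traj, sel, frame)
  tbl <- .VDW_RADII
  if (!is.null(radii)) tbl[names(radii)] <- radii
  if (!is.null(traj$atoms$radius)) {
    r <- traj$atoms$radius[sel]
  } else {
    r <- unname(tbl[toupper(traj$atoms$element[sel])])
    if (anyNA(r)) {
      bad <- which(is.na(r))[1]
      stop("unknown radius for atom ", sel[bad], " (element '",
           traj$atoms$element[sel[bad]], "')", call. = FALSE)
    }
  }
  R <- r + probe
  n <- length(sel)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbour lists from the pairwise distance matrix (desk-scale systems)
  D <- .cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < R[i] + R & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      exposed <- exposed & d2 > R[j]^2
      if (!any(exposed)) break
    }
    area[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  key <- paste(traj$atoms$chain[sel], traj$atoms$resid[sel], sep = ":")
  per_res <- tapply(area, factor(key, levels = unique(key)), sum)
  structure(list(total = sum(area),
                 per_residue = per_res,
                 per_atom = area,
                 probe = probe, n_sphere_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d residue(s) (probe %.2f A, %d points)\n",
              x$total, length(x$per_residue), x$probe, x$n_sphere_points))
  invisible(x)
}

#' Protein:micelle stoichiometry from surface areas
#'
#' Ratio of the micelle's solvent-accessible surface area to the area of
#' the protein surface patch it binds, with a nearest-integer suggestion
#' for the number of proteins accommodated.
#'
#' @param sasa_big Micelle SASA, A^2.
#' @param sasa_patch Protein binding-patch SASA, A^2.
#' @return List of class \code{"stoichiometry"}: \code{ratio},
#'   \code{nearest_integer}.
#' @export
stoichiometry_estimate <- function(sasa_big, sasa_patch) {
  if (!(sasa_big > 0) || !(sasa_patch > 0))
    stop("domain error: both areas must be > 0", call. = FALSE)
  ratio <- sasa_big / sasa_patch
  structure(list(ratio = ratio, nearest_integer = round(ratio)),
            class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("surface-area stoichiometry: %.1f (~%d proteins per micelle)\n",
              x$ratio, x$nearest_integer))
  invisible(x)
}
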