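## Per-frame structure/trajectory operations: radius of gyration and
## gyration-tensor shape, protein-micelle contact fingerprints,
## salt-bridge persistence, and radial distribution functions around the
## micelle centre of mass. All operations are embarrassingly per-frame
## and invariant to frame processing order.

# frame f coordinates of selected atoms as an n x 3 matrix
.frame_xyz <- function(traj, sel, f) {
  x <- traj$coords[sel, , f, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

.com <- function(xyz, m) colSums(xyz * m) / sum(m)

#' Radius of gyration per frame
#'
#' \eqn{R_g^2 = \sum_i m_i |r_i - r_{COM}|^2 / \sum_i m_i} (unit masses
#' when \code{mass_weighted = FALSE}).
#'
#' @param traj \code{\link{trajectory}}.
#' @param sel Integer atom indices (default all atoms), see
#'   \code{\link{atom_select}}.
#' @param mass_weighted Use atomic masses (default TRUE).
#' @return List of class \code{"rg_result"}: \code{per_frame} (Angstrom),
#'   \code{mean}, \code{sd}.
#' @export
radius_of_gyration <- function(traj, sel = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_sel(traj, sel)
  m <- if (mass_weighted) traj$atoms$mass[sel] else rep(1, length(sel))
  rg <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- .frame_xyz(traj, sel, f)
    com <- .com(xyz, m)
    d2 <- rowSums(sweep(xyz, 2, com)^2)
    sqrt(sum(m * d2) / sum(m))
  }, numeric(1))
  structure(list(per_frame = rg, mean = mean(rg),
                 sd = if (length(rg) > 1) stats::sd(rg) else 0),
            class = "rg_result")
}

#' Gyration tensor and ellipsoid semi-axes per frame
#'
#' Mass-weighted second-moment tensor
#' \eqn{S_{ab} = \sum_i m_i (r_{ia}-COM_a)(r_{ib}-COM_b)/\sum_i m_i};
#' eigenvalues are sorted descending and
#' \eqn{\lambda_1+\lambda_2+\lambda_3 = R_g^2}. Semi-axes use the uniform
#' solid-ellipsoid convention \eqn{a_i = \sqrt{5\lambda_i}} by default
#' (for a uniform ellipsoid the second moment along a principal axis is
#' \eqn{a_i^2/5}); \code{semi_axis_scale = "literal"} gives
#' \eqn{a_i = \sqrt{\lambda_i}}.
#'
#' @param traj \code{\link{trajectory}}.
#' @param sel Atom indices (default all).
#' @param mass_weighted Use atomic masses (default TRUE).
#' @param semi_axis_scale \code{"uniform"} (sqrt(5 lambda), default) or
#'   \code{"literal"} (sqrt(lambda)).
#' @return List of class \code{"gyration_result"}: \code{per_frame}
#'   data.frame (Rg, lambda1..3, a, b, c), \code{mean} and \code{sd}
#'   rows, \code{degenerate} flag (any eigenvalue numerically zero).
#' @export
gyration_tensor <- function(traj, sel = NULL, mass_weighted = TRUE,
                            semi_axis_scale = c("uniform", "literal")) {
  semi_axis_scale <- match.arg(semi_axis_scale)
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_sel(traj, sel)
  m <- if (mass_weighted) traj$atoms$mass[sel] else rep(1, length(sel))
  k <- if (semi_axis_scale == "uniform") 5 else 1
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    xyz <- .frame_xyz(traj, sel, f)
    com <- .com(xyz, m)
    d <- sweep(xyz, 2, com)
    S <- crossprod(d * m, d) / sum(m)
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0  # clip numerical noise
    c(Rg = sqrt(sum(ev)), lambda1 = ev[1], lambda2 = ev[2], lambda3 = ev[3],
      a = sqrt(k * ev[1]), b = sqrt(k * ev[2]), c = sqrt(k * ev[3]))
  })
  pf <- as.data.frame(do.call(rbind, rows))
  tol <- max(pf$lambda1, 1) * 1e-10
  structure(list(
    per_frame = pf,
    mean = colMeans(pf),
    sd = if (nrow(pf) > 1) vapply(pf, stats::sd, numeric(1)) else
      stats::setNames(rep(0, ncol(pf)), names(pf)),
    degenerate = any(pf$lambda2 < tol | pf$lambda3 < tol),
    semi_axis_scale = semi_axis_scale), class = "gyration_result")
}

#' @export
print.gyration_result <- function(x, ...) {
  cat(sprintf("gyration tensor over %d frame(s):\n", nrow(x$per_frame)))
  cat(sprintf("  Rg = %.2f +/- %.2f A\n", x$mean["Rg"], x$sd["Rg"]))
  cat(sprintf("  semi-axes (%s): %.2f, %.2f, %.2f A\n", x$semi_axis_scale,
              x$mean["a"], x$mean["b"], x$mean["c"]))
  if (x$degenerate) cat("  flag: rank-deficient (zero eigenvalue)\n")
  invisible(x)
}

# cross pairwise distance matrix between two coordinate sets
.cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Per-residue protein-micelle contact fingerprint
#'
#' For every residue of the protein selection and every frame, the
#' minimum distance between the residue's atoms and any atom of the
#' micelle selection; a residue is in contact in a frame when that
#' minimum is below the cutoff. The contact frequency is the fraction of
#' frames in contact.
#'
#' @param traj \code{\link{trajectory}}.
#' @param protein_sel,micelle_sel Disjoint atom-index selections.
#' @param cutoff Contact cutoff, Angstrom (default 6.5).
#' @return List of class \code{"contact_fingerprint"}:
#'   \code{fingerprint} data.frame (chain, resid, frequency),
#'   \code{min_dist} residues x frames matrix of minimum distances,
#'   \code{cutoff}, \code{n_frames}.
#' @export
contact_fingerprint <- function(traj, protein_sel, micelle_sel,
                                cutoff = 6.5) {
  stopifnot(inherits(traj, "trajectory"))
  protein_sel <- .resolve_sel(traj, protein_sel, "protein_sel")
  micelle_sel <- .resolve_sel(traj, micelle_sel, "micelle_sel")
  if (length(intersect(protein_sel, micelle_sel)))
    stop("selection error: protein and micelle selections overlap",
         call. = FALSE)
  key <- paste(traj$atoms$chain[protein_sel], traj$atoms$resid[protein_sel],
               sep = ":")
  groups <- split(seq_along(protein_sel), factor(key, levels = unique(key)))
  nf <- n_frames(traj)
  md <- matrix(NA_real_, length(groups), nf,
               dimnames = list(names(groups), NULL))
  for (f in seq_len(nf)) {
    D <- .cross_dist(.frame_xyz(traj, protein_sel, f),
                     .frame_xyz(traj, micelle_sel, f))
    md[, f] <- vapply(groups, function(g)
      min(D[g, , drop = FALSE]), numeric(1))
  }
  freq <- rowMeans(md < cutoff)
  ids <- do.call(rbind, strsplit(names(groups), ":", fixed = TRUE))
  structure(list(
    fingerprint = data.frame(chain = ids[, 1],
                             resid = as.integer(ids[, 2]),
                             frequency = unname(freq),
                             stringsAsFactors = FALSE),
    min_dist = md, cutoff = cutoff, n_frames = nf),
    class = "contact_fingerprint")
}

#' @export
print.contact_fingerprint <- function(x, ...) {
  cat(sprintf("contact fingerprint: %d residue(s), %d frame(s), cutoff %.1f A\n",
              nrow(x$fingerprint), x$n_frames, x$cutoff))
  cat(sprintf("  residues ever in contact: %d\n",
              sum(x$fingerprint$frequency > 0)))
  invisible(x)
}

#' Salt-bridge occupancy and persistence
#'
#' A cation group and an anion group (groups are (chain, resid) pairs of
#' the respective selections) are bridged in a frame when the minimum
#' distance between their charged atoms is at most \code{dist_cutoff};
#' a bridge is stable when its occupancy over frames reaches the
#' persistence threshold.
#'
#' @param traj \code{\link{trajectory}}.
#' @param cation_sel,anion_sel Atom selections; every atom must carry the
#'   matching \code{charge_class} annotation.
#' @param dist_cutoff Bridging distance between charged heavy atoms,
#'   Angstrom (default 4.0).
#' @param persistence Occupancy fraction defining a stable bridge
#'   (default 0.5).
#' @return List of class \code{"salt_bridges"}: \code{bridges} data.frame
#'   (cation, anion, occupancy, stable) for every pair ever bridged,
#'   \code{fraction_stable_cations} (cationic groups with at least one
#'   stable bridge / all cationic groups), thresholds and group counts.
#' @export
salt_bridges <- function(traj, cation_sel, anion_sel, dist_cutoff = 4.0,
                         persistence = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  cation_sel <- .resolve_sel(traj, cation_sel, "cation_sel")
  anion_sel <- .resolve_sel(traj, anion_sel, "anion_sel")
  if (!all(traj$atoms$charge_class[cation_sel] == "cationic"))
    stop("selection error: cation_sel contains non-cationic atoms",
         call. = FALSE)
  if (!all(traj$atoms$charge_class[anion_sel] == "anionic"))
    stop("selection error: anion_sel contains non-anionic atoms",
         call. = FALSE)
  ckey <- paste(traj$atoms$chain[cation_sel], traj$atoms$resid[cation_sel],
                sep = ":")
  akey <- paste(traj$atoms$chain[anion_sel], traj$atoms$resid[anion_sel],
                sep = ":")
  cg <- split(seq_along(cation_sel), factor(ckey, levels = unique(ckey)))
  ag <- split(seq_along(anion_sel), factor(akey, levels = unique(akey)))
  nf <- n_frames(traj)
  occ <- matrix(0, length(cg), length(ag),
                dimnames = list(names(cg), names(ag)))
  for (f in seq_len(nf)) {
    D <- .cross_dist(.frame_xyz(traj, cation_sel, f),
                     .frame_xyz(traj, anion_sel, f))
    for (i in seq_along(cg)) for (j in seq_along(ag))
      if (min(D[cg[[i]], ag[[j]]]) <= dist_cutoff)
        occ[i, j] <- occ[i, j] + 1
  }
  occ <- occ / nf
  stable <- occ >= persistence
  idx <- which(occ > 0, arr.ind = TRUE)
  bridges <- data.frame(
    cation = rownames(occ)[idx[, 1]],
    anion = colnames(occ)[idx[, 2]],
    occupancy = occ[idx],
    stable = stable[idx],
    stringsAsFactors = FALSE)
  bridges <- bridges[order(-bridges$occupancy), , drop = FALSE]
  structure(list(
    bridges = bridges,
    fraction_stable_cations = mean(apply(stable, 1, any)),
    n_cationic_groups = length(cg), n_anionic_groups = length(ag),
    dist_cutoff = dist_cutoff, persistence = persistence,
    n_frames = nf), class = "salt_bridges")
}

#' @export
print.salt_bridges <- function(x, ...) {
  cat(sprintf("salt bridges: %d pair(s) ever bridged, %d stable (occupancy >= %.2f)\n",
              nrow(x$bridges), sum(x$bridges$stable), x$persistence))
  cat(sprintf("  stable cationic terminals: %.1f %% of %d\n",
              100 * x$fraction_stable_cations, x$n_cationic_groups))
  invisible(x)
}

#' Radial distribution of target atoms around a reference centre of mass
#'
#' Histograms the distances of target atoms from the per-frame
#' (mass-weighted) centre of mass of the reference selection, averaged
#' over frames. \code{mode = "gr"} normalises each shell by its volume
#' and by the mean target density inside the r_max sphere (so a uniform
#' gas gives g(r) = 1); \code{mode = "count"} reports the raw mean count
#' per shell.
#'
#' @param traj \code{\link{trajectory}}.
#' @param ref_sel Reference selection (COM source).
#' @param target_sel Target atoms to histogram.
#' @param bin_width Bin width, Angstrom (default 0.5).
#' @param r_max Histogram range, Angstrom.
#' @param mode \code{"gr"} (default) or \code{"count"}.
#' @return List of class \code{"rdf_result"}: \code{bin_centers},
#'   \code{g} (or counts), \code{mode}, \code{empty} flag.
#' @export
rdf_from_com <- function(traj, ref_sel, target_sel, bin_width = 0.5,
                         r_max = 60, mode = c("gr", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory"), bin_width > 0,
            r_max > bin_width)
  ref_sel <- .resolve_sel(traj, ref_sel, "ref_sel")
  target_sel <- if (is.null(target_sel)) integer(0) else as.integer(target_sel)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (!length(target_sel)) {
    return(structure(list(bin_centers = centers,
                          g = rep(0, length(centers)), mode = mode,
                          empty = TRUE), class = "rdf_result"))
  }
  mref <- traj$atoms$mass[ref_sel]
  nf <- n_frames(traj)
  counts <- rep(0, length(centers))
  n_within <- 0
  for (f in seq_len(nf)) {
    com <- .com(.frame_xyz(traj, ref_sel, f), mref)
    d <- sqrt(rowSums(sweep(.frame_xyz(traj, target_sel, f), 2, com)^2))
    d <- d[d <= r_max]
    n_within <- n_within + length(d)
    counts <- counts + tabulate(findInterval(d, breaks, left.open = TRUE,
                                             all.inside = TRUE),
                                nbins = length(centers))
  }
  counts <- counts / nf
  g <- if (mode == "count") counts else {
    shell_vol <- 4 / 3 * pi * diff(breaks^3)
    rho <- (n_within / nf) / (4 / 3 * pi * r_max^3)
    counts / (shell_vol * rho)
  }
  structure(list(bin_centers = centers, g = g, mode = mode, empty = FALSE),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("RDF (%s): %d bins up to %.1f A%s\n", x$mode,
              length(x$bin_centers), max(x$bin_centers) +
                diff(x$bin_centers[1:2]) / 2,
              if (x$empty) " [empty target selection]" else ""))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$bin_centers, x$g, type = "l", xlab = "r (A)",
                 ylab = if (x$mode == "gr") "g(r)" else "mean count",
                 ...)
  invisible(x)
}
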