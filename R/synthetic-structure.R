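## Synthetic structures: an ideal polyalanine backbone built from internal
## coordinates (fixture for the secondary-structure operator) and a
## bead-scale micelle + protein-corona complex with planted contacts
## (fixture for every other trajectory operator). Bead scale suffices:
## the analysis operators depend only on coordinates and labels.

# place atom D given A-B-C with |C-D| = bond, angle(B,C,D) and
# torsion(A,B,C,D) in degrees (natural extension reference frame)
.nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
         nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * nrm
}

# standard backbone geometry (lengths A, angles degrees)
.BB <- list(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
            ang_N_CA_C = 111.2, ang_CA_C_N = 116.2, ang_C_N_CA = 121.7,
            ang_CA_C_O = 120.8, omega = 180)

#' Generate an ideal backbone chain (single frame)
#'
#' Builds an N/CA/C/O polyalanine backbone from internal coordinates at
#' the given dihedrals. The defaults (phi = -57, psi = -47) give a
#' canonical alpha-helix (1.5 A rise, ~100 deg twist per residue);
#' \code{phi = psi = 180} gives the fully extended chain.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone dihedrals, degrees.
#' @param chain Chain identifier (default "A").
#' @param offset Numeric length-3 translation applied to all atoms.
#' @return Single-frame \code{\link{trajectory}} with 4 backbone atoms
#'   per residue.
#' @export
gen_ideal_helix <- function(n_res, phi = -57, psi = -47, chain = "A",
                            offset = c(0, 0, 0)) {
  stopifnot(n_res >= 1)
  g <- .BB
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$N_CA, 0, 0)
  a <- g$ang_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + g$CA_C * c(-cos(a), sin(a), 0)
  if (n_res > 1) for (i in 2:n_res) {
    N[i, ] <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$C_N, g$ang_CA_C_N, psi)
    CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                           g$N_CA, g$ang_C_N_CA, g$omega)
    C[i, ] <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                          g$CA_C, g$ang_N_CA_C, phi)
  }
  for (i in seq_len(n_res)) {
    O[i, ] <- if (i < n_res)
      .nerf_place(N[i + 1, ], CA[i, ], C[i, ], g$C_O, g$ang_CA_C_O, 180)
    else
      .nerf_place(N[i, ], CA[i, ], C[i, ], g$C_O, g$ang_CA_C_O, psi + 180)
  }
  xyz <- matrix(NA_real_, 4 * n_res, 3)
  for (i in seq_len(n_res))
    xyz[(4 * i - 3):(4 * i), ] <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
  xyz <- sweep(xyz, 2, offset, "+")
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resname = "ALA",
    resid = rep(seq_len(n_res), each = 4L),
    chain = chain,
    stringsAsFactors = FALSE)
  trajectory(xyz, atoms)
}

# quasi-uniform directions on the unit sphere (shared Fibonacci lattice)
.fib_dirs <- function(n) .sphere_points(n)

#' Generate a toy micelle + protein-corona trajectory
#'
#' Builds a bead-scale complex: a central micelle of 17 three-bead
#' amphiphiles (tail / linker / cationic head at radii 15 / 28 / 40 A,
#' overall R_g about 30 A) surrounded by \code{n_proteins} 50-bead
#' "protein" chains on a 36-44 A shell with a mix of cationic, anionic
#' and neutral bead residues. For each planted pair the named protein
#' residue (made anionic) sits 3.5 A from its own cationic head bead in
#' exactly \code{ceiling(occupancy * n_frames)} frames and beyond 10 A
#' from every micelle bead otherwise. All other beads get a small
#' per-frame thermal jitter.
#'
#' Micelle beads live on chain "M": tail+linker share a residue (resname
#' AMP, neutral) and each head bead is its own residue (resname HDC,
#' cationic) so heads form distinct charged groups. Protein chains are
#' "A", "B", ... with one bead per residue.
#'
#' @param spec \code{\link{generator_spec}}.
#' @param n_proteins Number of protein chains (default 6).
#' @param n_frames Number of frames (default 20).
#' @param planted List of \code{list(chain=, resid=, occupancy=)} entries.
#' @param n_res_protein Beads per protein chain (default 50).
#' @param jitter_sd Thermal jitter SD per coordinate, Angstrom
#'   (default 0.2).
#' @return \code{\link{trajectory}} with attribute \code{"planted"}: a
#'   data.frame (chain, resid, occupancy, head_resid, n_contact_frames)
#'   naming the cationic head residue used by each planted pair.
#' @export
gen_toy_complex <- function(spec, n_proteins = 6L, n_frames = 20L,
                            planted = list(), n_res_protein = 50L,
                            jitter_sd = 0.2) {
  stopifnot(n_proteins >= 1, n_frames >= 1)
  for (p in planted)
    if (p$occupancy < 0 || p$occupancy > 1)
      stop("domain error: occupancy must be in [0, 1]", call. = FALSE)
  n_amph <- 17L
  dirs <- .fib_dirs(n_amph)
  mic_xyz <- NULL; mic_atoms <- NULL
  for (k in seq_len(n_amph)) {
    u <- dirs[k, ]
    mic_xyz <- rbind(mic_xyz, 15 * u, 28 * u, 40 * u)
    mic_atoms <- rbind(mic_atoms, data.frame(
      name = c("TL", "LN", "HD"),
      element = "C",
      resname = c("AMP", "AMP", "HDC"),
      resid = c(2L * k - 1L, 2L * k - 1L, 2L * k),
      chain = "M", stringsAsFactors = FALSE))
  }
  # protein chains: clustered caps on a shell, mixed charge pattern
  res_pattern <- c("LYS", "GLU", "GLY", "SER", "ALA")
  built <- with_spec_seed(spec, {
    pdirs <- .fib_dirs(n_proteins + 2L)[seq_len(n_proteins) + 1L, ,
                                        drop = FALSE]
    prot_xyz <- NULL; prot_atoms <- NULL
    for (c_i in seq_len(n_proteins)) {
      centre <- pdirs[c_i, ]
      # random orthonormal frame around the chain centre direction
      aux <- if (abs(centre[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- c(centre[2] * aux[3] - centre[3] * aux[2],
              centre[3] * aux[1] - centre[1] * aux[3],
              centre[1] * aux[2] - centre[2] * aux[1])
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(centre[2] * e1[3] - centre[3] * e1[2],
              centre[3] * e1[1] - centre[1] * e1[3],
              centre[1] * e1[2] - centre[2] * e1[1])
      th <- stats::runif(n_res_protein, 0, 2 * pi)
      cap <- stats::runif(n_res_protein, 0, 0.35)  # angular spread, rad
      r <- stats::runif(n_res_protein, 36, 44)
      u <- t(vapply(seq_len(n_res_protein), function(i) {
        v <- cos(cap[i]) * centre +
          sin(cap[i]) * (cos(th[i]) * e1 + sin(th[i]) * e2)
        v / sqrt(sum(v^2))
      }, numeric(3)))
      prot_xyz <- rbind(prot_xyz, u * r)
      prot_atoms <- rbind(prot_atoms, data.frame(
        name = "BB", element = "C",
        resname = rep_len(res_pattern, n_res_protein),
        resid = seq_len(n_res_protein),
        chain = LETTERS[c_i], stringsAsFactors = FALSE))
    }
    atoms <- rbind(mic_atoms, prot_atoms)
    base <- rbind(mic_xyz, prot_xyz)
    n_atoms <- nrow(base)

    # planted pairs: fix residue identity, assign one head bead each
    pl <- NULL
    frozen <- integer(0)  # atoms excluded from jitter
    if (length(planted)) {
      if (length(planted) > n_amph)
        stop("domain error: more planted pairs than head beads",
             call. = FALSE)
      pl <- do.call(rbind, lapply(seq_along(planted), function(ii) {
        p <- planted[[ii]]
        ai <- which(atoms$chain == p$chain & atoms$resid == p$resid)
        if (length(ai) != 1L)
          stop("domain error: planted residue ", p$chain, ":", p$resid,
               " not found", call. = FALSE)
        hi <- 3L * ii  # head bead of amphiphile ii
        atoms$resname[ai] <<- "GLU"
        data.frame(chain = p$chain, resid = p$resid,
                   occupancy = p$occupancy,
                   head_resid = atoms$resid[hi],
                   atom_index = ai, head_index = hi,
                   n_contact_frames = ceiling(p$occupancy * n_frames),
                   stringsAsFactors = FALSE)
      }))
      frozen <- c(pl$atom_index, pl$head_index)
    }
    atoms$charge_class <- charge_class_from_resname(atoms$resname)

    coords <- array(NA_real_, c(n_atoms, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      fr <- base
      jit <- matrix(stats::rnorm(3L * n_atoms, 0, jitter_sd), n_atoms, 3L)
      if (length(frozen)) jit[frozen, ] <- 0
      fr <- fr + jit
      if (!is.null(pl)) for (ii in seq_len(nrow(pl))) {
        head_pos <- base[pl$head_index[ii], ]
        u <- head_pos / sqrt(sum(head_pos^2))
        fr[pl$atom_index[ii], ] <- if (f <= pl$n_contact_frames[ii])
          head_pos + 3.5 * u   # in contact: 3.5 A outward of the head
        else
          55 * u               # detached: > 10 A from every micelle bead
      }
      coords[, , f] <- fr
    }
    list(coords = coords, atoms = atoms, pl = pl)
  })
  traj <- trajectory(built$coords, built$atoms)
  if (!is.null(built$pl))
    attr(traj, "planted") <- built$pl[, c("chain", "resid", "occupancy",
                                          "head_resid", "n_contact_frames")]
  traj
}
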