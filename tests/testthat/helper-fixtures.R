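# Shared fixtures and independent oracles, built in code at test time.

# random point-cloud trajectory (n atoms, nf frames), unit-ish masses
random_cloud <- function(n, nf = 1, scale = 10, seed = 1) {
  set.seed(seed)
  coords <- array(stats::rnorm(n * 3 * nf, sd = scale), c(n, 3, nf))
  trajectory(coords, data.frame(
    name = "X", element = "C", resname = "GLY",
    resid = seq_len(n), chain = "A"))
}

# brute-force mass-weighted radius of gyration (double loop, no matrix ops)
rg_brute <- function(xyz, m) {
  com <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) com <- com + m[i] * xyz[i, ]
  com <- com / sum(m)
  s <- 0
  for (i in seq_len(nrow(xyz)))
    s <- s + m[i] * sum((xyz[i, ] - com)^2)
  sqrt(s / sum(m))
}

# brute-force per-residue minimum distance (triple loop)
min_dist_brute <- function(xyz_p, resid_p, xyz_m) {
  out <- numeric(0)
  for (r in unique(resid_p)) {
    best <- Inf
    for (i in which(resid_p == r)) for (j in seq_len(nrow(xyz_m))) {
      d <- sqrt(sum((xyz_p[i, ] - xyz_m[j, ])^2))
      if (d < best) best <- d
    }
    out <- c(out, best)
  }
  out
}

# bisection solve of the 1:1 mass-action equation for the bound complex:
# (H - x)(S - x) = K_d * x, x in [0, min(H, S)]
bound_bisect <- function(H, S, K_d, tol = 1e-18) {
  f <- function(x) (H - x) * (S - x) - K_d * x
  lo <- 0; hi <- min(H, S)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# exposed area of two intersecting spheres (spherical-cap closed form);
# returns the total exposed area of both expanded spheres
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  cap1 <- 2 * pi * R1 * (R1 - x1)
  cap2 <- 2 * pi * R2 * (R2 - x2)
  4 * pi * R1^2 - cap1 + 4 * pi * R2^2 - cap2
}

# two extended (phi = psi = 180) 8-residue chains arranged as a flat
# parallel sheet: 4.8 A perpendicular spacing, 1.2 A axial stagger
sheet_fixture <- function(n = 8) {
  u <- c(1, 1, 0) / sqrt(2)   # strand axis of the extended chain
  v <- c(1, -1, 0) / sqrt(2)  # in-plane perpendicular
  off <- -4.8 * v + 1.2 * u
  c1 <- gen_ideal_helix(n, phi = 180, psi = 180, chain = "A")
  c2 <- gen_ideal_helix(n, phi = 180, psi = 180, chain = "B", offset = off)
  trajectory(rbind(c1$coords[, , 1], c2$coords[, , 1]),
             rbind(c1$atoms, c2$atoms))
}

# standard toy complex with two planted pairs used across tests
toy_with_planted <- function(seed = 5, n_frames = 10,
                             occ = c(0.6, 0.4)) {
  gen_toy_complex(generator_spec(seed), n_frames = n_frames,
                  planted = list(
                    list(chain = "A", resid = 10, occupancy = occ[1]),
                    list(chain = "B", resid = 5, occupancy = occ[2])))
}

# apply a rigid-body motion (rotation + translation) to every frame
rigid_move <- function(traj, seed = 1) {
  set.seed(seed)
  for (f in seq_len(n_frames(traj))) {
    M <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::rnorm(3, sd = 20)
    traj$coords[, , f] <- traj$coords[, , f] %*% Q +
      matrix(shift, nrow = dim(traj$coords)[1], ncol = 3, byrow = TRUE)
  }
  traj
}
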