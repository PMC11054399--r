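test_that("radius of gyration: point masses and brute-force agreement", {
  single <- trajectory(matrix(c(1, 2, 3), 1),
                       data.frame(name = "X", element = "C",
                                  resname = "GLY", resid = 1, chain = "A"))
  expect_equal(radius_of_gyration(single)$mean, 0)
  cube <- trajectory(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
                     data.frame(name = "X", element = "C", resname = "GLY",
                                resid = 1:8, chain = "A"))
  expect_equal(radius_of_gyration(cube)$mean, sqrt(3), tolerance = 1e-12)
  for (seed in 1:20) {
    tr <- random_cloud(50, seed = seed)
    tr$atoms$mass <- stats::runif(50, 1, 20)
    got <- radius_of_gyration(tr)$per_frame
    expect_equal(got, rg_brute(tr$coords[, , 1], tr$atoms$mass),
                 tolerance = 1e-10)
  }
})

test_that("gyration tensor: trace identity, degeneracy, sphere moments", {
  line <- trajectory(cbind(seq(-5, 5, 1), 0, 0),
                     data.frame(name = "X", element = "C", resname = "GLY",
                                resid = 1:11, chain = "A"))
  g <- gyration_tensor(line)
  expect_equal(g$mean[["lambda2"]], 0, tolerance = 1e-12)
  expect_equal(g$mean[["lambda3"]], 0, tolerance = 1e-12)
  expect_true(g$degenerate)

  tr <- random_cloud(200, nf = 3, seed = 5)
  g2 <- gyration_tensor(tr)
  rg <- radius_of_gyration(tr)
  for (f in 1:3) {
    expect_equal(g2$per_frame$lambda1[f] + g2$per_frame$lambda2[f] +
                   g2$per_frame$lambda3[f],
                 rg$per_frame[f]^2, tolerance = 1e-9)
  }

  # uniform solid sphere of radius R: each eigenvalue R^2/5
  set.seed(11)
  n <- 10000
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * 30 * stats::runif(n)^(1 / 3)
  sph <- trajectory(pts, data.frame(name = "X", element = "C",
                                    resname = "GLY", resid = seq_len(n),
                                    chain = "A"))
  gs <- gyration_tensor(sph)
  for (ax in c("a", "b", "c"))
    expect_equal(gs$mean[[ax]], 30, tolerance = 0.02)
})

test_that("reported complex semi-axes close with the reported R_g", {
  # sqrt((a^2+b^2+c^2)/5) must reproduce R_g under the sqrt(5 lambda)
  # semi-axis convention
  axes <- c(81.8, 80.2, 71.4)
  rg <- sqrt(sum(axes^2) / 5)
  expect_equal(rg, 60.01, tolerance = 0.01 * 60.01)
})

test_that("contact fingerprint matches all-pairs brute force", {
  set.seed(9)
  tr <- random_cloud(60, nf = 3, scale = 6)
  tr$atoms$resid <- rep(1:12, each = 5)
  tr$atoms$chain <- rep(c("A", "M"), c(30, 30))
  prot <- 1:30; mic <- 31:60
  cf <- contact_fingerprint(tr, prot, mic, cutoff = 6.5)
  for (f in 1:3) {
    md <- min_dist_brute(tr$coords[prot, , f], tr$atoms$resid[prot],
                         tr$coords[mic, , f])
    expect_equal(unname(cf$min_dist[, f]), md, tolerance = 1e-10)
  }
  expect_equal(cf$fingerprint$frequency,
               unname(rowMeans(cf$min_dist < 6.5)))
  expect_error(contact_fingerprint(tr, 1:30, 25:60), "overlap")
})

test_that("contacts and salt bridges are rigid-motion invariant", {
  tc <- toy_with_planted()
  mic <- atom_select(tc, chain = "M")
  prot <- atom_select(tc, chain = LETTERS[1:6])
  cf0 <- contact_fingerprint(tc, prot, mic)
  tc_m <- rigid_move(tc, seed = 31)
  cf1 <- contact_fingerprint(tc_m, prot, mic)
  expect_equal(cf1$fingerprint$frequency, cf0$fingerprint$frequency,
               tolerance = 1e-9)

  pl <- attr(tc, "planted")
  cat_sel <- atom_select(tc, chain = "M", resid = pl$head_resid)
  ani_sel <- c(atom_select(tc, chain = "A", resid = 10),
               atom_select(tc, chain = "B", resid = 5))
  sb0 <- salt_bridges(tc, cat_sel, ani_sel)
  sb1 <- salt_bridges(tc_m, cat_sel, ani_sel)
  expect_equal(sb1$bridges$occupancy, sb0$bridges$occupancy)

  # frame permutation leaves frequencies unchanged
  perm <- sample(n_frames(tc))
  tc_p <- tc
  tc_p$coords <- tc$coords[, , perm, drop = FALSE]
  cf2 <- contact_fingerprint(tc_p, prot, mic)
  expect_equal(cf2$fingerprint$frequency, cf0$fingerprint$frequency)
})

test_that("salt bridges: occupancy, stability threshold, monotonicity", {
  tc <- toy_with_planted(occ = c(0.6, 0.4))
  pl <- attr(tc, "planted")
  cat_sel <- atom_select(tc, chain = "M", resid = pl$head_resid)
  ani_sel <- c(atom_select(tc, chain = "A", resid = 10),
               atom_select(tc, chain = "B", resid = 5))
  sb <- salt_bridges(tc, cat_sel, ani_sel)
  expect_equal(sort(sb$bridges$occupancy), c(0.4, 0.6))
  expect_equal(sb$fraction_stable_cations, 0.5)
  expect_identical(sb$bridges$stable, sb$bridges$occupancy >= 0.5)

  # a pair planted in every frame is a fully occupied stable bridge
  tc1 <- gen_toy_complex(generator_spec(14), n_frames = 8,
                         planted = list(list(chain = "C", resid = 3,
                                             occupancy = 1)))
  pl1 <- attr(tc1, "planted")
  sb1 <- salt_bridges(tc1,
                      atom_select(tc1, chain = "M", resid = pl1$head_resid),
                      atom_select(tc1, chain = "C", resid = 3))
  expect_equal(sb1$bridges$occupancy, 1.0)
  expect_true(sb1$bridges$stable)

  # fraction_stable is non-increasing in persistence and under a
  # tightened distance cutoff
  fr <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(p)
    salt_bridges(tc, cat_sel, ani_sel,
                 persistence = p)$fraction_stable_cations, 0)
  expect_true(all(diff(fr) <= 0))
  fr_d <- vapply(c(5, 4, 3.4, 3), function(d)
    salt_bridges(tc, cat_sel, ani_sel,
                 dist_cutoff = d)$fraction_stable_cations, 0)
  expect_true(all(diff(fr_d) <= 0))

  neut <- atom_select(tc, chain = "A", resname = "GLY")
  expect_error(salt_bridges(tc, neut, ani_sel), "non-cationic")
})

test_that("RDF: point masses, ideal gas, planted protein shell", {
  ref <- trajectory(matrix(0, 1, 3),
                    data.frame(name = "X", element = "C", resname = "GLY",
                               resid = 1, chain = "M"))
  two <- trajectory(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                    data.frame(name = "X", element = "C", resname = "GLY",
                               resid = 1:3, chain = c("M", "A", "A")))
  r <- rdf_from_com(two, 1, 2:3, bin_width = 0.5, r_max = 20,
                    mode = "count")
  expect_equal(sum(r$g), 2)
  expect_equal(r$g[r$bin_centers == 9.75 | r$bin_centers == 10.25][1] +
                 r$g[r$bin_centers == 10.25], 2)

  # uniform gas inside the histogram sphere: g(r) ~ 1
  set.seed(10)
  n <- 40000
  box <- matrix(stats::runif(3 * n, -50, 50), ncol = 3)
  gas <- trajectory(rbind(c(0, 0, 0), box),
                    data.frame(name = "X", element = "C", resname = "GLY",
                               resid = seq_len(n + 1),
                               chain = c("M", rep("A", n))))
  rg <- rdf_from_com(gas, 1, 2:(n + 1), bin_width = 2, r_max = 48)
  mid <- rg$bin_centers > 5 & rg$bin_centers < 24
  counts <- rg$g  # Poisson noise scales with expected shell count
  expect_true(all(abs(rg$g[mid] - 1) < 0.5))
  expect_equal(mean(rg$g[mid]), 1, tolerance = 0.05)

  # toy complex: protein beads concentrate in the 35-45 A shell around
  # the micelle COM, overlapping the 40 A cationic head layer
  tc <- gen_toy_complex(generator_spec(2), n_frames = 5)
  mic <- atom_select(tc, chain = "M")
  prot <- atom_select(tc, chain = LETTERS[1:6])
  rc <- rdf_from_com(tc, mic, prot, bin_width = 0.5, r_max = 60,
                     mode = "count")
  shell <- rc$bin_centers > 34.75 & rc$bin_centers < 45.25
  expect_gte(sum(rc$g[shell]) / sum(rc$g), 0.95)

  r_empty <- rdf_from_com(tc, mic, integer(0))
  expect_true(r_empty$empty)
  expect_true(all(r_empty$g == 0))
})

test_that("SASA: closed forms, burial, and rigid-motion invariance", {
  one <- trajectory(matrix(0, 1, 3),
                    data.frame(name = "X", element = "C", resname = "GLY",
                               resid = 1, chain = "A", radius = 1.6))
  expect_equal(sasa(one)$total, 4 * pi * 3^2, tolerance = 1e-9)

  # two equal spheres vs the spherical-cap closed form
  for (d in c(2.0, 3.0, 3.9)) {
    two <- trajectory(rbind(c(0, 0, 0), c(d, 0, 0)),
                      data.frame(name = "X", element = "C",
                                 resname = "GLY", resid = 1:2, chain = "A",
                                 radius = 0.6))
    got <- sasa(two)$total
    expect_equal(got, two_sphere_area(2, 2, d), tolerance = 0.02)
  }

  # centre atom fully enclosed by an icosahedral shell
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  ico <- ico / sqrt(1 + phi^2) * 2.5
  shell <- trajectory(rbind(c(0, 0, 0), ico),
                      data.frame(name = "X", element = "C",
                                 resname = "GLY", resid = 1:13,
                                 chain = "A", radius = c(1.0, rep(2, 12))))
  s <- sasa(shell)
  expect_equal(s$per_atom[1], 0)
  expect_equal(s$total, sum(s$per_residue), tolerance = 1e-6)

  # rotation/translation invariance on the toy complex micelle
  tc <- gen_toy_complex(generator_spec(4), n_frames = 1)
  mic <- atom_select(tc, chain = "M")
  s0 <- sasa(tc, mic)$total
  s1 <- sasa(rigid_move(tc, 7), mic)$total
  expect_equal(s1, s0, tolerance = 0.005)
})

test_that("surface-area stoichiometry behaves as a pure ratio", {
  st <- stoichiometry_estimate(35618, 5835)
  expect_equal(round(st$ratio, 1), 6.1)
  expect_equal(st$nearest_integer, 6)
  expect_equal(stoichiometry_estimate(1200, 1200)$ratio, 1.0)
  expect_equal(stoichiometry_estimate(35618 * 3.7, 5835 * 3.7)$ratio,
               st$ratio, tolerance = 1e-12)
  expect_error(stoichiometry_estimate(100, 0), "domain error")
})

test_that("secondary structure: helix, sheet, and degraded input", {
  ss <- assign_secondary_structure(gen_ideal_helix(20))
  interior <- ss$assignment$ss[3:17]
  expect_gte(mean(interior == "H"), 0.8)

  sheet <- sheet_fixture()
  ss_e <- assign_secondary_structure(sheet)
  byres <- ss_e$assignment
  interior_e <- byres$ss[byres$resid %in% 3:6]
  expect_gte(mean(interior_e == "E"), 0.75)
  expect_equal(ss_e$fractions[["H"]], 0)

  # residue with missing backbone atoms falls back to coil with warning
  h <- gen_ideal_helix(6)
  drop_o <- h
  keep <- !(drop_o$atoms$resid == 3 & drop_o$atoms$name == "O")
  drop_o <- trajectory(drop_o$coords[keep, , , drop = FALSE],
                       drop_o$atoms[keep, ])
  expect_warning(res <- assign_secondary_structure(drop_o),
                 "missing backbone")
  expect_identical(res$assignment$ss[res$assignment$resid == 3], "C")
})
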