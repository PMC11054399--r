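test_that("generators are deterministic in the spec seed", {
  a <- gen_quenching(generator_spec(42), "linear_sv")
  b <- gen_quenching(generator_spec(42), "linear_sv")
  expect_identical(a, b)
  expect_false(identical(
    a, gen_quenching(generator_spec(43), "linear_sv")))
  i1 <- gen_itc(generator_spec(7))
  i2 <- gen_itc(generator_spec(7))
  expect_identical(i1, i2)
  t1 <- gen_toy_complex(generator_spec(3), n_frames = 2)
  t2 <- gen_toy_complex(generator_spec(3), n_frames = 2)
  expect_identical(t1$coords, t2$coords)
})

test_that("linear quenching follows the closed form at zero noise", {
  t <- gen_quenching(generator_spec(1, 0), "linear_sv", K_SV = 1e4,
                     concs = c(5e-5, 1e-4, 2e-4))
  # F0/F = 1 + K_SV [Q]: at [Q] = 1e-4 and K_SV = 1e4, F = 100/2
  expect_equal(t$intensity[t$conc == 1e-4], 50)
  expect_equal(t$intensity[t$conc == 0], 100)
})

test_that("zero-noise titrations are exactly inverted by their fits", {
  sp <- generator_spec(1, 0)
  t1 <- gen_quenching(sp, "linear_sv", K_SV = 4.9e4)
  f1 <- suppressWarnings(fit_stern_volmer(t1))
  expect_equal(f1$K_SV, 4.9e4, tolerance = 1e-6)
  expect_equal(f1$intercept, 1, tolerance = 1e-6)

  t2 <- gen_quenching(sp, "modified_sv", K_D = 22.9e-6, hsa_conc = 2e-6)
  f2 <- fit_modified_stern_volmer(t2)
  expect_equal(f2$K_D, 22.9e-6, tolerance = 1e-6)
  expect_equal(f2$slope, 1, tolerance = 1e-6)
})

test_that("ITC generator: zero enthalpy gives pure-noise heats", {
  d <- paper_defaults()$itc_design
  p <- binding_params(1e-5, 0, 6)
  q0 <- gen_itc(generator_spec(1, 0), d, p, baseline_sd = 0)
  expect_equal(q0$injections$heat_ucal, rep(0, 19))
  qn <- gen_itc(generator_spec(1, 0), d, p, baseline_sd = 0.1)
  expect_lt(max(abs(qn$injections$heat_ucal)), 1)
  expect_gt(stats::sd(qn$injections$heat_ucal), 0)
})

test_that("doubling the syringe concentration halves the inflection index", {
  d <- paper_defaults()$itc_design
  d$injection_volumes_uL <- rep(2, 40)  # long titration to resolve both
  p <- binding_params(1e-6, -4, 6)     # tight binding, sharp inflection
  tab <- function(dd) injection_table(dd$injection_volumes_uL,
                                      rep(0, 40), dd$cell_volume_uL,
                                      dd$temperature_K, dd$cell_conc,
                                      dd$syringe_conc)
  q1 <- as.numeric(simulate_isotherm(tab(d), p))
  d2 <- d; d2$syringe_conc <- 2 * d$syringe_conc
  q2 <- as.numeric(simulate_isotherm(tab(d2), p))
  i1 <- which.min(diff(abs(q1)))
  i2 <- which.min(diff(abs(q2)))
  expect_lte(abs(i2 - ceiling(i1 / 2)), 1)
})

test_that("CD generator inverts the helicity calibration", {
  sp <- generator_spec(1, 0)
  cp <- cd_params(2e-6, 585L, 0.1)
  s100 <- gen_cd_spectrum(sp, 100, cp)
  expect_equal(helicity_from_spectrum(s100, cp)$helix_pct, 100,
               tolerance = 1e-9)
  s <- gen_cd_spectrum(sp, 59.3, cp)
  h <- helicity_from_spectrum(s, cp)
  expect_equal(h$mre208, -21197, tolerance = 1e-6)
  expect_equal(h$helix_pct, 59.3, tolerance = 1e-9)
  expect_error(gen_cd_spectrum(sp, 101, cp), "domain error")
})

test_that("melt generator hits the baseline midpoint at T_M", {
  sp <- generator_spec(1, 0)
  m <- gen_melt_curve(sp, T_M = 60, baselines = c(-20, -4))
  expect_equal(m$y[m$x == 60], (-20 + -4) / 2)
  fit <- fit_melting(gen_melt_curve(sp, T_M = 65))
  expect_equal(fit$T_M, 65, tolerance = 0.01)
})

test_that("toy complex plants contacts at the requested occupancy", {
  tc <- gen_toy_complex(generator_spec(9), n_frames = 10,
                        planted = list(list(chain = "A", resid = 7,
                                            occupancy = 1.0)))
  mic <- atom_select(tc, chain = "M")
  prot <- atom_select(tc, chain = LETTERS[1:6])
  fp <- contact_fingerprint(tc, prot, mic)$fingerprint
  expect_equal(fp$frequency[fp$chain == "A" & fp$resid == 7], 1.0)
  expect_error(gen_toy_complex(generator_spec(1), planted = list(
    list(chain = "A", resid = 1, occupancy = 1.5))), "domain error")
})

test_that("toy micelle has the designed ~30 A gyration radius", {
  tc <- gen_toy_complex(generator_spec(2), n_frames = 3)
  rg <- radius_of_gyration(tc, atom_select(tc, chain = "M"))
  expect_equal(rg$mean, 29.5, tolerance = 0.05)
})

test_that("ideal helix fixture: too-short and extended chains have no helix", {
  expect_equal(assign_secondary_structure(gen_ideal_helix(3))$fractions[["H"]],
               0)
  ext <- gen_ideal_helix(10, phi = 180, psi = 180)
  fr <- assign_secondary_structure(ext)$fractions
  expect_equal(fr[["H"]], 0)
  expect_equal(fr[["E"]], 0)
})
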