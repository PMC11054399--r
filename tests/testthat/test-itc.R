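test_that("micelle partition: branches and exact mass conservation", {
  below <- micelle_concentration(3e-6, 17, 4.5e-6)
  expect_equal(below$ad_monomer, 3e-6)
  expect_equal(below$ad_micelle, 0)
  above <- micelle_concentration(900e-6, 17, 4.5e-6)
  expect_equal(above$ad_micelle, (900e-6 - 4.5e-6) / 17)
  expect_equal(above$ad_monomer, 4.5e-6)
  set.seed(2)
  for (i in 1:1000) {
    tot <- stats::runif(1, 0, 2e-3)
    cmc <- stats::runif(1, 0, 1e-4)
    na <- sample(1:60, 1)
    ms <- micelle_concentration(tot, na, cmc)
    expect_identical(ms$ad_monomer + na * ms$ad_micelle, tot)
    expect_gte(ms$ad_monomer, 0)
    expect_gte(ms$ad_micelle, 0)
  }
  expect_error(micelle_concentration(-1e-6, 17, 4.5e-6), "domain error")
})

test_that("mass-action quadratic agrees with bisection", {
  set.seed(4)
  for (i in 1:1000) {
    H <- 10^stats::runif(1, -7, -3)
    S <- 10^stats::runif(1, -7, -3)
    K <- 10^stats::runif(1, -9, -3)
    x_quad <- coronathermo:::.bound_complex(H, S, K)
    x_bis <- bound_bisect(H, S, K)
    expect_equal(x_quad, x_bis, tolerance = 1e-9)
    expect_lte(x_quad, min(H, S))
  }
})

test_that("isotherm limits: zero enthalpy and stoichiometric binding", {
  d <- paper_defaults()$itc_design
  tab <- injection_table(d$injection_volumes_uL, rep(0, 19),
                         d$cell_volume_uL, d$temperature_K, d$cell_conc,
                         d$syringe_conc)
  q0 <- simulate_isotherm(tab, binding_params(1e-5, 0, 6))
  expect_equal(as.numeric(q0), rep(0, 19))

  # K_d -> 0: every pre-saturation injection converts all injected sites
  p <- binding_params(1e-15, -4.02, 6)
  q <- as.numeric(simulate_isotherm(tab, p))
  mic_syr <- micelle_concentration(d$syringe_conc, 17, 4.5e-6)$ad_micelle
  site_moles_per_inj <- 2e-6 * mic_syr * 6  # 2 uL of site-concentration
  expected <- -4.02 * site_moles_per_inj * 1e9  # kcal -> ucal
  expect_equal(q[1] / expected, 1, tolerance = 0.02)
  expect_equal(q[5] / expected, 1, tolerance = 0.02)
  # post-saturation heats vanish
  expect_lt(abs(q[19]), abs(q[1]) * 0.01)
  # saturation happens where sites match protein: [H]/[M] ~ n_sites
  mr <- attr(simulate_isotherm(tab, p), "molar_ratio") / p$n_sites
  trans <- which(abs(diff(abs(q))) == max(abs(diff(abs(q)))))
  expect_lt(abs(mr[trans] - 1), 0.35)
})

test_that("integrated heat is bounded by the saturable pool", {
  d <- paper_defaults()$itc_design
  tab <- injection_table(d$injection_volumes_uL, rep(0, 19),
                         d$cell_volume_uL, d$temperature_K, d$cell_conc,
                         d$syringe_conc)
  V0 <- d$cell_volume_uL * 1e-6
  for (kd in c(1e-15, 1e-7, 1e-5, 1e-4)) {
    p <- binding_params(kd, -4.02, 6)
    q <- as.numeric(simulate_isotherm(tab, p))
    mic_syr <- micelle_concentration(d$syringe_conc, 17, 4.5e-6)$ad_micelle
    cap <- 4.02 * min(d$cell_conc, 19 * 2 / 208 * mic_syr * 6) * V0 * 1e9
    expect_lte(sum(abs(q)), cap * 1.02)
  }
})

test_that("saturation decay: post-inflection heats shrink monotonically", {
  d <- paper_defaults()$itc_design
  tab <- injection_table(d$injection_volumes_uL, rep(0, 19),
                         d$cell_volume_uL, d$temperature_K, d$cell_conc,
                         d$syringe_conc)
  for (kd in c(1e-7, 1e-6, 13.4e-6)) {
    q <- abs(as.numeric(simulate_isotherm(tab, binding_params(kd, -4, 6))))
    i_inf <- which.max(abs(diff(q))) + 1L
    tail_q <- q[i_inf:19]
    expect_true(all(diff(tail_q) <= 1e-9))
  }
})

test_that("noiseless self-fit recovers the generating parameters", {
  it <- gen_itc(generator_spec(1, 0), baseline_sd = 0)
  fit <- fit_one_site(it)
  expect_equal(fit$params$K_d, 13.4e-6, tolerance = 1e-5)
  expect_equal(fit$params$delta_H, -4.02, tolerance = 1e-5)
  expect_equal(fit$params$n_sites, 6, tolerance = 1e-5)
  # thermodynamic closure on the fit result
  expect_equal(fit$thermo$delta_G,
               fit$thermo$delta_H + fit$thermo$minus_T_delta_S,
               tolerance = 1e-9)
})

test_that("converged fit beats an exhaustive parameter grid", {
  it <- gen_itc(generator_spec(8, 0.01))
  fit <- fit_one_site(it)
  grid_sse <- Inf
  for (lk in seq(-6, -4, length.out = 50)) {
    base <- coronathermo:::.itc_sse(lk, 1, it, it$injections$heat_ucal,
                                    17, 4.5e-6, rep(1, 19), FALSE)
    for (n in seq(2, 12, length.out = 10)) {
      r <- coronathermo:::.itc_sse(lk, n, it, it$injections$heat_ucal,
                                   17, 4.5e-6, rep(1, 19), FALSE)
      # inner solve profiles delta_H exactly, covering the 50x50x10 grid
      if (r$sse < grid_sse) grid_sse <- r$sse
    }
  }
  expect_lte(fit$sse, grid_sse + 1e-9)
})

test_that("discarding the first injection is honoured", {
  it <- gen_itc(generator_spec(3, 0.01))
  fit <- fit_one_site(it, discard_first = TRUE)
  expect_identical(fit$n_discarded_injections, 1L)
  expect_equal(fit$params$K_d, 13.4e-6, tolerance = 0.3)
})

test_that("thermodynamic decomposition matches closed forms", {
  expect_equal(derive_thermodynamics(1, -4, 298)$delta_G, 0)
  th <- derive_thermodynamics(13.4e-6, -4.02, 298)
  expect_equal(th$delta_G, 1.9872e-3 * 298 * log(13.4e-6), tolerance = 1e-12)
  expect_equal(th$delta_G, th$delta_H + th$minus_T_delta_S,
               tolerance = 1e-12)
})
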