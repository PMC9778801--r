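test_that("Nernst conversion reproduces the tabulated equilibrium constants", {
  expect_equal(nernst_keq(60, 1, 25), 11.023, tolerance = 1e-4)
  expect_identical(nernst_keq(0, 1, 25), 1)
  expect_equal(nernst_keq(-320, 1, 25), 2.78e-6, tolerance = 0.01)
  expect_equal(nernst_keq(260, 1, 25), 3.29e4, tolerance = 0.01)
  expect_equal(nernst_keq(769, 2, 25), 5.2e26, tolerance = 0.01)
  expect_error(nernst_keq(60, 1, 0), "positive")
  expect_error(nernst_keq(60, 3, 25), "1 or 2")
})

test_that("nernst_keq is monotone and multiplicative in the potential", {
  d <- seq(-400, 400, by = 40)
  expect_true(all(diff(nernst_keq(d, 1, 25)) > 0))
  for (a in c(-310, -45, 12, 260)) {
    for (b in c(-100, 7, 333)) {
      expect_equal(nernst_keq(a + b, 1, 25),
                   nernst_keq(a, 1, 25) * nernst_keq(b, 1, 25),
                   tolerance = 1e-12)
    }
  }
  # a two-electron step equals the squared one-electron step
  expect_equal(nernst_keq(150, 2, 25), nernst_keq(150, 1, 25)^2,
               tolerance = 1e-12)
})

test_that("basal parameter set matches the tabulated values", {
  ps <- base_ps
  expect_equal(ps$Keq[["Keq1"]], 11.023, tolerance = 1e-4)
  expect_equal(ps$k[["k1"]], 1e3)
  expect_equal(ps$Keq[["Keq7"]], 2778, tolerance = 1e-3)
  expect_equal(ps$Keq[["Keq14"]], 250)
  expect_equal(ps$Keq[["Keq16"]], 250)
  expect_equal(ps$k[["k14"]], 10)
  expect_equal(ps$k[["k16"]], 10)
  expect_equal(unname(ps$pools), rep(235, 4))
  expect_equal(ps$Vmax21, 5.6e4)
  expect_equal(ps$Km21, 50)
  expect_equal(ps$k22, 30)
  # printed (rounded) dependent constants recovered within 5 %
  expect_equal(ps$Keq[["Keq5"]], 0.03, tolerance = 0.05)
  expect_equal(ps$Keq[["Keq6"]], 0.289, tolerance = 0.05)
  expect_equal(ps$Keq[["Keq13"]], 2.4e-4, tolerance = 0.05)
  expect_equal(ps$Keq[["Keq15"]], 0.289, tolerance = 0.05)
  # cluster-chain consistency: Keq1*Keq2*Keq3 = exp((60-320+260)/vT) = 1
  expect_equal(ps$Keq[["Keq1"]] * ps$Keq[["Keq2"]] * ps$Keq[["Keq3"]], 1,
               tolerance = 1e-10)
})

test_that("detailed-balance propagation yields exact unit cycle products", {
  ps <- derive_dependent_keqs(base_ps)
  expect_equal(unname(cycle_products(ps)), rep(1, 4), tolerance = 1e-12)
  # independently multiply the printed constants: consistent only to ~5 %
  printed <- base_ps
  printed$Keq[c("Keq5", "Keq6", "Keq13", "Keq15")] <-
    c(0.03, 0.289, 2.4e-4, 0.289)
  printed$Keq[["Keq7"]] <- 2778
  printed$Keq[["Keq4"]] <- 4.17e-3
  cp <- cycle_products(printed)
  expect_true(all(abs(cp - 1) < 0.05))
  expect_false(all(abs(cp - 1) < 1e-10))
  # perturbing a dependent constant shows up linearly in its cycle
  doubled <- ps
  doubled$Keq[["Keq5"]] <- 2 * doubled$Keq[["Keq5"]]
  expect_equal(unname(cycle_products(doubled)[["cycle1"]]), 2,
               tolerance = 1e-12)
  broken <- base_ps
  broken$Keq[["Keq8"]] <- -1
  expect_error(derive_dependent_keqs(broken), "positive")
})

test_that("variants propagate binding constants through detailed balance", {
  v <- make_variant(base_ps, list(k14 = 1e-2, k16 = 1e-2))
  expect_equal(v$Keq[["Keq14"]], 0.25)
  expect_equal(v$Keq[["Keq16"]], 0.25)
  expect_equal(v$Keq[["Keq13"]], 0.24, tolerance = 1e-12)
  expect_equal(unname(cycle_products(v)), rep(1, 4), tolerance = 1e-12)

  v2 <- make_variant(base_ps, list(k10 = 1e-4, k12 = 1e-4))
  expect_equal(v2$Keq[["Keq10"]], 2e-6)
  expect_equal(v2$Keq[["Keq12"]], 2e-6)
  expect_equal(unname(cycle_products(v2)), rep(1, 4), tolerance = 1e-12)

  v3 <- make_variant(base_ps, list(km14 = 4e3, km16 = 4e3))
  expect_equal(v3$Keq[["Keq14"]], 2.5e-3)
  expect_equal(v3$Keq[["Keq13"]], 24, tolerance = 1e-12)

  # identity round trip
  same <- make_variant(base_ps, list())
  expect_equal(same$Keq, base_ps$Keq)
  expect_equal(same$k, base_ps$k)
  expect_equal(same$kr, base_ps$kr)

  expect_error(make_variant(base_ps, list(k99 = 1)), "unknown rate constant")
  expect_error(make_variant(base_ps, list(5)), "named")
  expect_error(make_variant(base_ps, list(pool_FAD = -5)), "nonnegative")
})

test_that("validation flags thermodynamic inconsistency", {
  expect_true(validate_parameters(base_ps))
  bad <- base_ps
  bad$Keq[["Keq5"]] <- bad$Keq[["Keq5"]] * 1.001
  expect_error(validate_parameters(bad), "detailed-balance")
})

test_that("unit conversions match the documented factors", {
  expect_equal(protein_to_concentration(0.209), 237, tolerance = 0.005)
  expect_equal(protein_to_concentration(0), 0)
  expect_equal(protein_to_concentration(1), 1137.5)
  expect_error(protein_to_concentration(-1), "nonnegative")
  expect_equal(flux_to_specific_rate(1), 220)
  expect_equal(flux_to_specific_rate(0), 0)
  expect_equal(flux_to_specific_rate(1000 / 220), 1000)
})
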