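test_that("zero-current potential matches the Nernstian closed form", {
  env <- sdh_env(fum = 1000, suc = 50)
  E_eq <- zero_current_potential(base_ps, env)
  expect_equal(E_eq, 12.5 * log(1000 / 50), tolerance = 1e-10)
  # With ROS off the net flux at E_eq is tiny: the tabulated constants
  # leave only the unlisted binding-order cycle (4,5 vs 9,10) open at the
  # ~4 % rounding level, whose residual circulation is a few uM/s against
  # peak fluxes of ~1e3 uM/s
  ps0 <- ros_off()
  ss <- steady_state(ps0, sdh_env(fum = 1000, suc = 50, E_out = E_eq),
                     method = "rootfind")
  expect_true(ss$converged)
  expect_lt(abs(ss$rates$V_rev_tot), 5)
  # closing that cycle (Keq9 from Keq4*Keq5/Keq10) kills the flux entirely
  psc <- ps0
  psc$Keq[["Keq9"]] <- psc$Keq[["Keq4"]] * psc$Keq[["Keq5"]] /
    psc$Keq[["Keq10"]]
  psc <- derive_dependent_keqs(psc)
  ssc <- steady_state(psc, sdh_env(fum = 1000, suc = 50, E_out = E_eq),
                      method = "rootfind")
  expect_lt(abs(ssc$rates$V_rev_tot), 1e-3)
  # and the flux changes sign across the zero-current potential
  v_lo <- steady_state(ps0, sdh_env(E_out = E_eq - 2),
                       method = "rootfind")$rates$V_rev_tot
  v_hi <- steady_state(ps0, sdh_env(E_out = E_eq + 2),
                       method = "rootfind")$rates$V_rev_tot
  expect_gt(v_lo, 0)
  expect_lt(v_hi, 0)
})

test_that("steady-state mass balance ties the relay rates together", {
  ps0 <- ros_off()
  for (E in c(-100, -300)) {
    ss <- steady_state(ps0, sdh_env(E_out = E))
    expect_true(ss$converged)
    V <- ss$rates$V
    vrev <- ss$rates$V_rev_tot
    expect_lt(max(rel_diff(V[1:3], vrev)), 1e-6)
    expect_lt(rel_diff(vrev, 2 * ss$rates$V_suc_tot), 1e-6)
  }
})

test_that("H2O2 efflux balances production at every steady state", {
  for (E in c(-80, -200)) {
    ss <- steady_state(base_ps, sdh_env(E_out = E))
    expect_true(ss$converged)
    expect_lt(rel_diff(unname(ss$rates$V["V22"]), ss$rates$VH2O2), 1e-6)
  }
})

test_that("electron bookkeeping accounts for the ROS diversion", {
  # flux entering the flavin pool leaves as succinate or as electrons on O2
  for (E in c(-60, -150)) {
    ss <- steady_state(base_ps, sdh_env(E_out = E))
    V <- ss$rates$V
    gap <- ss$rates$V_rev_tot - 2 * ss$rates$V_suc_tot
    expect_lt(rel_diff(gap, 2 * V[["V17"]] + V[["V18"]] + V[["V19"]]), 1e-6)
  }
})

test_that("integration and Newton steady states agree", {
  cases <- list(list(base_ps, -100), list(slow_release(), -80),
                list(slow_fum_binding(), -200))
  for (cs in cases) {
    cc <- crosscheck_steady_state(cs[[1]], sdh_env(E_out = cs[[2]]))
    expect_true(cc$agree, label = sprintf("crosscheck %s at %g mV",
                                          cs[[1]]$label, cs[[2]]))
    expect_lt(cc$max_rel_diff, 1e-4)
  }
})

test_that("a decoupled electrode leaves an E_out-independent equilibrium", {
  ps <- make_variant(ros_off(), list(k1 = 0), label = "no-electrode")
  a <- steady_state(ps, sdh_env(E_out = 0), method = "rootfind")
  b <- steady_state(ps, sdh_env(E_out = -300), method = "rootfind")
  expect_true(a$converged && b$converged)
  expect_lt(max(abs(a$state - b$state)) / max(ps$pools), 1e-6)
})

test_that("steady state is independent of the conserving initial state", {
  set.seed(0)
  for (ps in list(base_ps, slow_release())) {
    ref <- steady_state(ps, sdh_env(E_out = -80))
    for (i in 1:3) {
      init <- random_conserving_state(ps)
      ss <- steady_state(ps, sdh_env(E_out = -80), init = init)
      expect_true(ss$converged)
      expect_lt(max(abs(ss$state - ref$state)) / max(ps$pools), 1e-6)
    }
  }
})

test_that("conservation drifts below 1e-6 along a stiff trajectory", {
  set.seed(7)
  ps <- base_ps
  env <- sdh_env(E_out = -100)
  init <- random_conserving_state(ps)
  times <- c(0, 10^seq(-4, 5, by = 0.5))
  sol <- deSolve::lsoda(unname(init[species_names()]), times,
                        sdhrev:::.desolve_func, list(env = env, ps = ps),
                        jacfunc = sdhrev:::.desolve_jac,
                        jactype = "fullusr", rtol = 1e-10, atol = 1e-12)
  colnames(sol) <- c("time", species_names())
  fad_bound <- rowSums(sol[, c("FAD.fum", "FADH.fum", "FADH2.fum",
                               "FAD.suc", "FADH.suc", "FADH2.suc",
                               "FADH", "FADH2")])
  # nonnegativity of every dynamic species along the whole trajectory
  expect_gt(min(sol[, species_names()]), -1e-9)
  # each moiety stays within its pool total (complement nonnegative):
  # relative drift of the conserved sums below 1e-6
  tol <- 1e-6 * ps$pools[["FAD"]]
  expect_lt(max(fad_bound) - ps$pools[["FAD"]], tol)
  expect_lt(max(sol[, "Fe3S4red"]) - ps$pools[["Fe3S4"]], tol)
  expect_lt(max(sol[, "Fe4S4red"]) - ps$pools[["Fe4S4"]], tol)
  expect_lt(max(sol[, "Fe2S2red"]) - ps$pools[["Fe2S2"]], tol)
})
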