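test_that("the network has 22 kinetic processes over 13 dynamic species", {
  S <- stoichiometry_matrix()
  expect_identical(dim(S), c(13L, 22L))
  expect_identical(length(species_names()), 13L)
  expect_identical(length(base_ps$pools), 4L)   # conserved moieties
  r <- reaction_rates(default_state(base_ps), sdh_env(E_out = 0), base_ps)
  expect_identical(length(r$V), 22L)
})

test_that("stoichiometry closes every conserved moiety", {
  S <- stoichiometry_matrix()
  # FAD moiety: the eight dynamic flavin states plus free FAD, which is
  # consumed/produced by reactions 4, 8, 9, 17, 19
  fad_free <- numeric(22)
  fad_free[c(4, 9)] <- -1
  fad_free[c(8, 17, 19)] <- 1
  expect_equal(unname(colSums(S[4:11, ]) + fad_free), rep(0, 22))
  # each FeS pair: reduced form + oxidized complement (complement
  # stoichiometry is minus the reduced row restricted to its reactions)
  expect_equal(unname(S["Fe4S4red", c(2, 3)]), c(1, -1))
  # arithmetic on the stated stoichiometry
  V <- numeric(22); V[2] <- 5; V[3] <- 3
  expect_equal(unname(drop(S %*% V)["Fe4S4red"]), 2)
})

test_that("electrode reaction follows Butler-Volmer kinetics", {
  # at E_out = Em the Nernst ratio is 1:1, so equal concentrations are at
  # equilibrium (Keq1 = exp(60/25))
  expect_lt(abs(electrode_rate(117.5, 117.5, 60, base_ps)),
            1e-6 * base_ps$k[["k1"]] * 117.5)
  expect_equal(electrode_rate(235, 0, 0, base_ps), 2.35e5)
  ps0 <- base_ps
  ps0$k[["k1"]] <- 0
  expect_equal(electrode_rate(100, 50, -200, ps0), 0)
  expect_error(electrode_rate(-1, 0, 0, base_ps), "nonnegative")
})

test_that("dismutation and efflux rate laws hit their landmarks", {
  st <- default_state(base_ps)
  st[["O2sup"]] <- 50   # half saturation: Km21 = 50 uM
  st[["H2O2"]] <- 1
  r <- reaction_rates(st, sdh_env(E_out = 0), base_ps)
  expect_equal(unname(r$V["V21"]), 5.6e4 / 2)
  expect_equal(unname(r$V["V22"]), 30)
})

test_that("rates vanish at the closed-form chemical equilibrium", {
  # The tabulated constants are rounded and close only the four listed
  # cycles exactly. An exact equilibrium additionally needs the
  # binding-order cycle (4,5 vs 9,10) and the ROS triangle closed, so
  # derive Keq9, Keq18 and Keq20 from their partners first.
  ps <- base_ps
  ps$Keq[["Keq9"]] <- ps$Keq[["Keq4"]] * ps$Keq[["Keq5"]] /
    ps$Keq[["Keq10"]]
  ps <- derive_dependent_keqs(ps)   # refresh Keq13/Keq15 from the new Keq9
  ps$Keq[["Keq18"]] <- ps$Keq[["Keq9"]] * ps$Keq[["Keq19"]] /
    ps$Keq[["Keq11"]]
  ps$Keq[["Keq20"]] <- ps$Keq[["Keq2"]] * ps$Keq[["Keq3"]] *
    ps$Keq[["Keq9"]] * ps$Keq[["Keq19"]]
  # a full chemical equilibrium exists only at the zero-current potential
  # (the binding/release cycles close through the clamped fum and suc)
  for (cond in list(c(1000, 50), c(200, 200), c(50, 1000))) {
    env <- sdh_env(fum = cond[1], suc = cond[2])
    env$E_out <- zero_current_potential(ps, env)
    st <- equilibrium_state(ps, env)
    y <- unname(st[species_names()])
    V <- reaction_rates(st, env, ps, check = FALSE)$V
    gross <- sdhrev:::.rates_gross(y, env, ps)
    expect_true(all(abs(V[1:20]) <= 1e-8 * gross[1:20]),
                label = sprintf("equilibrium residuals at E = %g",
                                env$E_out))
  }
})

test_that("state validation rejects negative species", {
  st <- default_state(base_ps)
  st[["FADH"]] <- -1
  expect_error(reaction_rates(st, sdh_env(), base_ps), "negative")
  st2 <- default_state(base_ps)
  st2[["FAD.fum"]] <- 300   # free FAD complement would go negative
  expect_error(reaction_rates(st2, sdh_env(), base_ps), "negative")
})

test_that("ode_rhs matches stoichiometry times rates at random states", {
  set.seed(42)
  S <- stoichiometry_matrix()
  for (i in 1:5) {
    st <- random_conserving_state(base_ps)
    st[["O2sup"]] <- runif(1)
    st[["H2O2"]] <- runif(1, 0, 5)
    env <- sdh_env(E_out = runif(1, -300, 100))
    r <- reaction_rates(st, env, base_ps)
    expect_equal(unname(ode_rhs(st, env, base_ps)),
                 unname(drop(S %*% r$V)), tolerance = 1e-12)
  }
})
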