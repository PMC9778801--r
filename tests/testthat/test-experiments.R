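# Coarse grids keep these scans fast; the acceptance suite runs the fine
# 2 mV threshold localization.

test_that("threshold detector recovers a planted quadratic maximum", {
  set.seed(11)
  grid <- seq(0, -300, by = -10)
  for (i in 1:10) {
    E0 <- runif(1, -250, -50)     # planted vertex
    a <- runif(1, 0.001, 0.1)
    sweep <- data.frame(label = "planted", E_out = grid,
                        V_rev_tot = 100 - a * (grid - E0)^2,
                        converged = TRUE)
    th <- threshold_detect(sweep)
    expect_lt(abs(th$E_threshold - E0), 10)   # within one grid spacing
    expect_true(th$reliable)
  }
})

test_that("monotone curves yield no threshold", {
  grid <- seq(0, -200, by = -20)
  sweep <- data.frame(label = "mono", E_out = grid,
                      V_rev_tot = -grid, converged = TRUE)
  expect_true(is.na(threshold_detect(sweep)$E_threshold))
  one <- data.frame(label = "single", E_out = -100, V_rev_tot = 5,
                    converged = TRUE)
  th1 <- threshold_detect(one)
  expect_true(is.na(th1$E_threshold))
  expect_identical(nrow(th1), 1L)
})

test_that("basal succinate production grows monotonically with driving force", {
  sw <- eout_sweep(base_ps, grid = seq(0, -300, by = -30))
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$V_suc_tot) > 0))   # rows ordered by falling E_out
  expect_true(is.na(threshold_detect(sw, "V_suc_tot")$E_threshold))
})

test_that("slow succinate release produces an interior maximum", {
  sw <- eout_sweep(slow_release(), grid = seq(0, -200, by = -10))
  expect_true(all(sw$converged))
  th <- threshold_detect(sw)
  expect_false(is.na(th$E_threshold))
  expect_gt(th$E_threshold, -200)
  expect_lt(th$E_threshold, 0)
})

test_that("threshold moves to less negative potentials as release slows", {
  # k14 = k16 stepping down a decade at a time
  ths <- vapply(c(1, 0.1, 0.01), function(k) {
    sw <- eout_sweep(slow_release(k), grid = seq(20, -400, by = -20))
    threshold_detect(sw)$E_threshold
  }, 0)
  expect_false(any(is.na(ths)))
  expect_true(all(diff(ths) > 0))   # toward less negative E_out
})

test_that("flux decomposition sums to the total release per row", {
  sw <- eout_sweep(list(base_ps, slow_release()),
                   grid = c(-40, -120, -250))
  dec <- flux_decomposition(sw)
  expect_equal(dec$V8 + dec$V14 + dec$V16, dec$V_suc_tot, tolerance = 1e-12)
  # slow-release variant: release from the oxidized complex dominates over
  # the visible range of the hump
  d4 <- dec[dec$label != "basal" & dec$E_out == -40, ]
  expect_gt(d4$V8 / d4$V_suc_tot, 0.95)
})

test_that("fumarate titration is hyperbolic and thermodynamically signed", {
  fgrid <- c(0, 10^seq(1, 4, by = 0.5))
  tt <- fumarate_titration(slow_release(1e-2), fum_grid = fgrid,
                           E_out_set = c(-50, -150))
  expect_true(all(tt$converged))
  for (E in c(-50, -150)) {
    y <- tt$V_suc_tot[tt$E_out == E]
    expect_true(all(diff(y) > -1e-8))            # non-decreasing in fumarate
  }
  # in the trap-limited regime the curve saturates at the release capacity
  ysat <- tt$V_suc_tot[tt$E_out == -150]
  expect_lt(ysat[length(ysat)] - ysat[length(ysat) - 1], 0.05 * max(ysat))
  # no substrate, product present: no net succinate production possible
  expect_lte(tt$V_suc_tot[tt$fum == 0 & tt$E_out == -50][1], 0)
  # with slow succinate release the attainable rate drops with more
  # negative potential (the trap bites once the driving force is large)
  for (fm in c(1e3, 1e4)) {
    expect_lt(tt$V_suc_tot[tt$E_out == -150 & tt$fum == fm],
              tt$V_suc_tot[tt$E_out == -50 & tt$fum == fm])
  }
})

test_that("redox profiles stay within the pool totals", {
  sw <- eout_sweep(base_ps, grid = c(-20, -60, -200))
  rp <- redox_profile(sw)
  pools <- base_ps$pools
  expect_true(all(rp$Fe3S4red <= pools[["Fe3S4"]] + 1e-9))
  expect_true(all(rp$Fe2S2red <= pools[["Fe2S2"]] + 1e-9))
  expect_true(all(rp$FADH + rp$FADH2 <= pools[["FAD"]] + 1e-9))
  expect_true(all(rp$Fe3S4red + rp$Fe3S4ox - pools[["Fe3S4"]] < 1e-9))
  # the [3Fe-4S] cluster is nearly fully reduced already at -60 mV ...
  expect_gt(rp$Fe3S4red[rp$E_out == -60], 0.95 * pools[["Fe3S4"]])
  # ... while [2Fe-2S] approaches its maximum only at much lower potential
  expect_gt(rp$Fe2S2red[rp$E_out == -200], rp$Fe2S2red[rp$E_out == -60])
  expect_lt(rp$Fe2S2red[rp$E_out == -60], 0.85 * pools[["Fe2S2"]])
})

test_that("ROS scan reports both unit systems consistently", {
  sw <- ros_scan(base_ps, grid = c(-50, -150))
  expect_equal(sw$VH2O2_specific, 220 * sw$VH2O2, tolerance = 1e-12)
  expect_equal(sw$VH2O2, sw$V17 + sw$V21, tolerance = 1e-12)
  # switching the ROS reactions off silences H2O2 production
  sw0 <- ros_scan(ros_off(), grid = c(-50, -150))
  expect_lt(max(abs(sw0$VH2O2)), 1e-9)
})
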