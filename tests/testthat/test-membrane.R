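test_that("BK open probability: midpoint, saturation, Kd monotonicity", {
  p <- fls_membrane_params()
  vh <- bk_vhalf_analytic(p)
  expect_equal(bk_open_prob(vh, p$ca_uM, p), 0.5, tolerance = 1e-12)
  # calcium saturation drives the midpoint to v_h0 - dv_max
  expect_equal(bk_vhalf_analytic(p, ca_uM = 1e9), p$v_h0 - p$dv_max,
               tolerance = 1e-6)
  expect_equal(bk_vhalf_analytic(p, ca_uM = 0), p$v_h0)
  # at fixed (V, Ca), Po decreases as Kd grows, over a parameter grid
  for (v in c(-40, 0, 40, 120)) {
    po <- vapply(c(0.1, 0.3, 0.46, 1.05, 3),
                 function(kd) bk_open_prob(v, 0.35,
                                           membrane_params(kd_uM = kd,
                                                           v_h0 = p$v_h0,
                                                           dv_max = p$dv_max)),
                 numeric(1))
    expect_true(all(diff(po) < 0))
  }
  expect_error(bk_open_prob(0, -1, p), "ca_uM")
})

test_that("total_current limits and a hand-evaluated point", {
  leak_only <- membrane_params(g_bk_max = 0, g_kir = 0, g_leak = 6,
                               e_leak = -30)
  v <- seq(-80, 40, by = 20)
  expect_equal(total_current(v, leak_only), 6 * (v + 30) / 1000,
               tolerance = 1e-12)
  same_rev <- membrane_params(e_k = -50, e_leak = -50)
  expect_equal(total_current(-50, same_rev), 0, tolerance = 1e-12)

  # independent arithmetic at one point, all terms active
  p <- membrane_params(g_bk_max = 100, g_kir = 20, g_leak = 5,
                       e_k = -84.6, e_leak = -30, k_bk = 17.6,
                       v_h0 = 134.9, dv_max = 219.7, hill = 1,
                       kd_uM = 0.46, ca_uM = 0.35, k_out_mM = 5)
  v0 <- 10
  vh <- 134.9 - 219.7 * 0.35 / (0.35 + 0.46)
  po <- 1 / (1 + exp(-(v0 - vh) / 17.6))
  r <- 1 / (1 + exp((v0 - (-84.6) - 10) / 10))
  by_hand <- (100 * po * (v0 + 84.6) + 20 * r * (v0 + 84.6) +
                5 * (v0 + 30)) / 1000
  expect_equal(total_current(v0, p), by_hand, tolerance = 1e-12)
})

test_that("resting potential: limits, bracketing, grid-scan oracle", {
  expect_equal(resting_potential(membrane_params(g_bk_max = 0, g_kir = 0,
                                                 g_leak = 4,
                                                 e_leak = -30)),
               -30, tolerance = 1e-6)
  expect_equal(resting_potential(membrane_params(g_bk_max = 50, g_kir = 0,
                                                 g_leak = 0)),
               -84.6, tolerance = 1e-6)
  p <- fls_membrane_params()
  v_star <- resting_potential(p)
  expect_gt(v_star, min(p$e_k, p$e_leak))
  expect_lt(v_star, max(p$e_k, p$e_leak))
  # brute-force fine-grid zero crossing agrees to 1e-3 mV
  grid <- seq(p$e_k, p$e_leak, by = 1e-4)
  i <- which.min(abs(total_current(grid, p)))
  expect_lt(abs(grid[i] - v_star), 1e-3)
  expect_error(resting_potential(membrane_params(g_bk_max = 0, g_kir = 0,
                                                 g_leak = 0)),
               "conductance")
})

test_that("raising Kd depolarises both the midpoint and the resting potential", {
  kds <- c(0.2, 0.46, 0.8, 1.05, 2)
  p <- fls_membrane_params()
  vh <- vr <- numeric(length(kds))
  for (i in seq_along(kds)) {
    pk <- p; pk$kd_uM <- kds[i]
    vh[i] <- bk_vhalf_analytic(pk)
    vr[i] <- resting_potential(pk)
  }
  expect_true(all(diff(vh) > 0))
  expect_true(all(diff(vr) > 0))
})

test_that("simulated protocol flows through the analysis chain exactly", {
  p <- fls_membrane_params(g_kir = 10, g_leak = 3)
  proto <- fast_protocol()
  rec <- simulate_protocol(p, proto, capacitance_pF = 30)
  iv <- suppressWarnings(iv_curve(list(rec), "sustained", smooth_ms = 0))
  v <- proto$steps_mV
  expect_equal(iv$mean_pA_pF,
               total_current(v, p) - total_current(-80, p),
               tolerance = 1e-9)

  none <- membrane_params(g_bk_max = 0, g_kir = 0, g_leak = 0)
  # zero conductances: currents are identically zero (resting potential
  # is undefined there, so build the sweep check directly)
  expect_error(simulate_protocol(none, proto), "conductance")

  # chord conductance at E_rev = E_K of a BK-only model recovers g_BK*Po
  bk <- fls_membrane_params(g_kir = 0, g_leak = 0)
  rec2 <- simulate_protocol(bk, fast_protocol(steps_mV = seq(-60, 140,
                                                             by = 20)),
                            capacitance_pF = 30)
  iv2 <- suppressWarnings(iv_curve(list(rec2), "sustained", smooth_ms = 0,
                                   baseline_ms = 100))
  gv <- chord_conductance(iv2, bk$e_k)
  hold_term <- bk$g_bk_max * bk_open_prob(-80, bk$ca_uM, bk) *
    (-80 - bk$e_k)
  expected <- bk$g_bk_max * bk_open_prob(gv$v_mV, bk$ca_uM, bk) -
    hold_term / (gv$v_mV - bk$e_k)
  expect_equal(gv$g_pS_pF, expected, tolerance = 1e-9)
})

test_that("BK G-V midpoint: fit equals analytic; calibrated anchors hold", {
  p <- fls_membrane_params()
  expect_equal(bk_gv_midpoint(p), bk_vhalf_analytic(p), tolerance = 1e-6)
  expect_equal(bk_gv_midpoint(p), 40, tolerance = 1e-6)
  hi <- p; hi$kd_uM <- 1.05
  expect_equal(bk_gv_midpoint(hi), 80, tolerance = 1e-6)
  far <- p; far$kd_uM <- 1e9   # calcium-insensitive limit
  expect_equal(bk_gv_midpoint(far), p$v_h0, tolerance = 1e-4)
})

test_that("Kd sweep is strictly monotone, interpolable and refinement-stable", {
  p <- fls_membrane_params()
  sw <- kd_sweep(p, seq(0.1, 3, length.out = 30))
  expect_true(all(diff(sw$v_half_mV) > 0))
  expect_equal(sw$baseline_kd_uM, 0.46)
  expect_equal(sw$baseline_v_half_mV, 40, tolerance = 1e-6)

  single <- kd_sweep(p, 0.46)
  expect_equal(single$v_half_mV, 40, tolerance = 1e-6)

  fine <- kd_sweep(p, seq(0.1, 3, length.out = 60))
  probe <- seq(0.2, 2.8, by = 0.1)
  expect_lt(max(abs(sw$v_half_fun(probe) - fine$v_half_fun(probe))), 0.1)

  expect_error(kd_sweep(p, c(1, 0.5)), "increasing")
})

test_that("kd_for_shift inverts the sweep", {
  p <- fls_membrane_params()
  expect_equal(kd_for_shift(p, 0), 0.46, tolerance = 0.01)
  expect_equal(kd_for_shift(p, 40), 1.05, tolerance = 0.1)
  expect_lt(kd_for_shift(p, -10), 0.46)
  # inverse consistency across a range of shifts
  for (s in c(-20, 10, 25, 55)) {
    kd <- kd_for_shift(p, s)
    pk <- p; pk$kd_uM <- kd
    expect_equal(bk_gv_midpoint(pk) - 40, s, tolerance = 0.5)
  }
  expect_error(kd_for_shift(p, 500), "attainable")
})

test_that("driving force is Vm - E_ion with inward-negative convention", {
  expect_equal(driving_force(-50, -50), 0)
  expect_equal(driving_force(-50, 120), -170)
  vm <- seq(-90, 0, by = 10)
  expect_true(all(diff(driving_force(vm, 120)) > 0))
})
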