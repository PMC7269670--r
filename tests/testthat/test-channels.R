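test_that("boltzmann hits its midpoint exactly and is strictly monotone", {
  expect_identical(boltzmann(-64.5, -64.5, 6.6, "inact"), 0.5)
  expect_identical(boltzmann(0, 0, 3, "act"), 0.5)
  set.seed(42)
  for (i in 1:20) {
    vh <- runif(1, -90, 0)
    k <- runif(1, 2, 25)
    v <- sort(runif(50, -120, 40))
    act <- boltzmann(v, vh, k, "act")
    inact <- boltzmann(v, vh, k, "inact")
    expect_true(all(diff(act) >= 0))
    expect_true(all(diff(inact) <= 0))
    # strictly monotone away from floating-point saturation
    mid <- act > 1e-12 & act < 1 - 1e-12
    expect_true(all(diff(act[mid]) > 0))
    expect_true(all(act >= 0 & act <= 1))
  }
  expect_error(boltzmann(-60, -64.5, -1, "inact"), "k")
  expect_error(boltzmann(NaN, -64.5, 6.6, "inact"), "voltage")
})

test_that("slope calibration inverts the Boltzmann through printed anchors", {
  # availability anchors of the two I_SA variants
  k_tor <- calibrate_from_anchors(-64.5, -80, 0.913, "inact")
  expect_equal(k_tor, 6.594, tolerance = 1e-3)
  expect_equal(boltzmann(-80, -64.5, k_tor, "inact"), 0.913,
               tolerance = 1e-9)
  # with that slope, availability at -60 mV is ~1/3 of total
  expect_equal(boltzmann(-60, -64.5, k_tor, "inact"), 0.336,
               tolerance = 0.01)
  # activation working point of the TOR nucleated curve
  k_act <- calibrate_from_anchors(-16.4, -40, 0.10, "act")
  expect_equal(k_act, 10.74, tolerance = 1e-3)
  # degenerate midpoint anchor: any slope works, configured default returned
  expect_equal(calibrate_from_anchors(0, 0, 0.5, "act", default_k = 7), 7)
  expect_error(calibrate_from_anchors(-60, -50, 0.5, "inact"), "no Boltzmann")
  expect_error(calibrate_from_anchors(-60, -50, 1.2, "inact"), "strictly")
})

test_that("tau_h interpolation reproduces every anchor exactly and stays positive", {
  anchors <- cbind(v = c(-120, -85, -75, -65, -25),
                   tau = c(4.4, 29.8, 46.2, 58.2, 71.2))
  expect_identical(tau_h(-85, anchors), 29.8)
  expect_identical(tau_h(-120, anchors), 4.4)
  expect_identical(tau_h(anchors[, "v"], anchors), unname(anchors[, "tau"]))
  rs_anchors <- cbind(v = c(-120, -85, -75, -65, -25),
                      tau = c(3.3, 7.1, 8.0, 11.8, 18.8))
  expect_identical(tau_h(-85, rs_anchors), 7.1)
  v <- seq(-120, 70, by = 0.5)
  expect_true(all(tau_h(v, anchors) > 0))
  # clamped to end anchors outside the range
  expect_identical(tau_h(-140, anchors), 4.4)
  expect_identical(tau_h(40, anchors), 71.2)
  expect_error(tau_h(-50, cbind(v = c(-80, -40), tau = c(5, -1))), "positive")
  expect_error(tau_h(-50, cbind(v = -80, tau = 5)), "two")
})

test_that("channel current is ohmic, outward positive, zero at reversal", {
  ch <- isa_channel("tor")
  expect_identical(channel_current(ch, v = -90, m = 1, h = 1)$density_mA_cm2, 0)
  # 1 nS of open conductance over a 100 um^2 patch at -40 mV, E_K -90
  patch <- hh_channel("test", -90, gates = list(),
                      density = c(soma = 1e-3, dend = 0))
  out <- channel_current(patch, v = -40, m = 1, h = 1, area_um2 = 100)
  expect_equal(out$pA, 50, tolerance = 1e-12)
  expect_error(channel_current(ch, -40, m = 1.5, h = 1), "0, 1")
})

test_that("gating-modifier shift reproduces the measured conductance reduction", {
  tor <- isa_channel("tor", profile = "nucleated")
  expect_identical(apply_hptx(tor, 0)$gating, tor$gating)
  # shift up then down restores the original model
  back <- apply_hptx(apply_hptx(tor, 12.4), -12.4)
  expect_equal(back$gating$v_half_act, tor$gating$v_half_act)
  # conductance reduction at -30 mV from the +12.4 mV midpoint shift
  m0 <- boltzmann(-30, tor$gating$v_half_act, tor$gating$k_act, "act")
  sh <- apply_hptx(tor, 12.4)
  m1 <- boltzmann(-30, sh$gating$v_half_act, sh$gating$k_act, "act")
  reduction <- (1 - m1 / m0) * 100
  expect_gt(reduction, 50)  # measured 60 +/- 10 %
  expect_lt(reduction, 70)
  # the larger RS shift produces a larger relative reduction
  rs <- isa_channel("rs", profile = "nucleated")
  m0r <- boltzmann(-30, rs$gating$v_half_act, rs$gating$k_act, "act")
  shr <- apply_hptx(rs, 21.5)
  m1r <- boltzmann(-30, shr$gating$v_half_act, shr$gating$k_act, "act")
  expect_gt(1 - m1r / m0r, 1 - m1 / m0)
})

test_that("simulated gating relaxation matches the closed-form exponential", {
  m <- morph_standin(c(diam = 20, len = 20),
                     data.frame(len = numeric(0), diam = numeric(0)))
  cell <- build_cell("tor", morphology = m)
  for (nm in c("core_na", "core_kdr", "core_adapt", "isa_rs"))
    cell$channels[[nm]]$density[] <- 0
  st <- vclamp_stim(c(-80, -40), c(500, 200), rs_mohm = 0.001)
  tr <- integrate_cell(cell, st, record_channels = "isa_tor",
                       v_init = -80, theta = 1)
  g <- cell$channels$isa_tor$gating
  idx <- tr$time > 500
  trel <- tr$time[idx] - 500 - tr$dt  # command applied during the first step
  m_t <- boltzmann(-40, g$v_half_act, g$k_act, "act") +
    (boltzmann(-80, g$v_half_act, g$k_act, "act") -
       boltzmann(-40, g$v_half_act, g$k_act, "act")) * exp(-trel / g$tau_act)
  h_t <- boltzmann(-40, g$v_half_inact, g$k_inact, "inact") +
    (boltzmann(-80, g$v_half_inact, g$k_inact, "inact") -
       boltzmann(-40, g$v_half_inact, g$k_inact, "inact")) *
    exp(-trel / tau_h(-40, g$tau_inact_anchors))
  g_abs <- cell$channels$isa_tor$density[["soma"]] * soma_area_cm2() * 1e6
  i_exp <- g_abs * m_t * h_t * (-40 + 90)
  rel_err <- max(abs(tr$i_channel[idx, 1] - i_exp)) / max(abs(i_exp))
  expect_lt(rel_err, 1e-3)
})

test_that("presets respect the density mixture and compartment ratios", {
  pre <- isa_preset("tor")
  # 3:1 RS:TOR mixture (128:44 within rounding of the printed densities)
  expect_equal(pre$isa_rs$density[["soma"]] / pre$isa_tor$density[["soma"]],
               128 / 44, tolerance = 1e-12)
  for (ch in c(pre, isa_preset("rs"))) {
    expect_equal(ch$density[["soma"]] / ch$density[["dend"]], 2.96,
                 tolerance = 0.05)
  }
})
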