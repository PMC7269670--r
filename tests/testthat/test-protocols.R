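# Protocol round-trips on the calibrated channel models. These use the
# template (population-mean) cells, so the values are deterministic.

test_that("leak subtraction leaves ~zero current when I_SA density is zero", {
  cell <- tpl_rs()
  cell$channels$isa_rs$density[] <- 0
  act <- run_activation_protocol(cell, "whole_cell",
                                 steps = c(-80, -40, -20))
  expect_true(all(abs(act$curve$peak_pa) < 1))
})

test_that("activation protocol reports peaks and excludes zero driving force", {
  act <- memo("act_tor", run_activation_protocol(
    tpl_tor(), "whole_cell", steps = c(-90, -70, -40, -20)))
  expect_true(is.na(act$curve$g_us[act$curve$step == -90]))
  expect_true(all(diff(act$curve$peak_pa[act$curve$step >= -70]) > 0))
  expect_false(act$flagged)
})

test_that("whole-cell I_SA amplitudes at -40 mV match the recorded currents", {
  pk_tor <- run_activation_protocol(tpl_tor(), "whole_cell",
                                    steps = -40)$curve$peak_pa
  pk_rs <- run_activation_protocol(tpl_rs(), "whole_cell",
                                   steps = -40)$curve$peak_pa
  expect_lt(abs(pk_tor - 683) / 683, 0.2)
  expect_lt(abs(pk_rs - 148) / 148, 0.2)
  expect_gt(pk_tor, pk_rs)
})

test_that("nucleated clamp keeps the command within 1 mV", {
  act <- run_activation_protocol(tpl_ctor(), "nucleated",
                                 steps = c(-40, 0, 40))
  expect_lt(act$clamp_escape_mv, 1)
  expect_false(act$flagged)
})

test_that("steady-state inactivation reproduces the calibrated availability curve", {
  inact <- memo("inact_ctor", run_inactivation_protocol(tpl_ctor()))
  expect_false(inact$flagged)
  expect_gt(inact$fit$r_squared, 0.995)
  expect_lt(abs(inact$fit$v_half - (-64.5)), 2)
  # ~91% of the current is available at -80 mV, ~1/3 at -60 mV
  expect_lt(abs(inact$availability_at(-80) - 0.913), 0.03)
  expect_lt(abs(inact$availability_at(-60) - 0.357) / 0.357, 0.10)
  # the RS variant's curve is right-shifted and much shallower
  inact_rs <- memo("inact_crs", run_inactivation_protocol(tpl_crs()))
  expect_gt(inact_rs$fit$v_half, inact$fit$v_half + 5)
  expect_gt(inact_rs$fit$k, inact$fit$k)
})

test_that("recovery protocol round-trips the channel's tau_h", {
  for (cfg in list(list(cell = tpl_ctor(), variant = "tor", v = -85),
                   list(cell = tpl_crs(), variant = "rs", v = -85))) {
    rec <- memo(paste0("rec_", cfg$variant),
                run_recovery_protocol(cfg$cell, cfg$v))
    expect_false(rec$flagged)
    g <- cfg$cell$channels[[paste0("isa_", cfg$variant)]]$gating
    tau_model <- tau_h(cfg$v, g$tau_inact_anchors)
    expect_lt(abs(rec$tau - tau_model) / tau_model, 0.10)
  }
})

test_that("a zero-length recovery interval leaves the current inactivated", {
  cell <- tpl_ctor()
  rec <- memo("rec_tor", run_recovery_protocol(cell, -85))
  # area at the shortest interval is a small fraction of the recovered area
  a <- rec$curve$area_pc
  expect_lt((a[1] - 0) / max(a), 0.35)
  expect_gt(max(a), 0)
  expect_true(all(diff(a) > -1e-6))  # recovery is monotone
})

test_that("inactivation time constants of the current decay match the anchors", {
  decay_tau <- function(cell) {
    act <- run_activation_protocol(cell, "whole_cell", steps = -25)
    trc <- act$traces[["-25"]]
    pk <- which.max(trc$i_nA)
    sel <- seq(pk, length(trc$i_nA))
    fit_exponential(trc$time[sel] - trc$time[pk], trc$i_nA[sel])$tau
  }
  expect_lt(abs(decay_tau(tpl_ctor()) - 71.2) / 71.2, 0.10)
  expect_lt(abs(decay_tau(tpl_crs()) - 18.8) / 18.8, 0.10)
})

test_that("charge density integrates the isolated I_SA current", {
  q_tor <- measure_charge(build_channel_cell("tor", profile = "nucleated"))
  q_rs <- measure_charge(build_channel_cell("rs", profile = "nucleated"))
  # both carry inhibitory charge at the threshold-range step
  expect_gt(q_tor, 0.02)
  expect_gt(q_rs, 0.02)
  # zero driving force: no charge
  expect_equal(measure_charge(tpl_ctor(), step_mv = -90), 0,
               tolerance = 1e-6)
})

test_that("holding-current search settles the cell at the target potential", {
  cell <- tpl_tor()
  for (target in c(-80, -60)) {
    hold <- find_holding_current(cell, target)
    tr <- integrate_cell(cell, iclamp_stim(hold, 1500), v_init = target,
                         record_dt = 1)
    expect_lt(abs(mean(tr$v[tr$time > 1200, 1]) - target), 1)
  }
})
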