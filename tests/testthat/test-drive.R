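test_that("package-onset equation evaluates exactly", {
  f <- function(fr) (1000 / fr) * 0.633 + 69.25112 * 0.67747^fr + 1000 / fr
  expect_equal(eq1_onset(8), f(8), tolerance = 1e-12)
  expect_equal(eq1_onset(8), 207.20, tolerance = 1e-2)
  expect_equal(eq1_onset(1), 1679.92, tolerance = 1e-2)
  expect_lt(eq1_onset(1000), 2)  # both frequency-dependent terms vanish
  expect_error(eq1_onset(0), "> 0")
  expect_error(eq1_onset(-3), "> 0")
})

test_that("event trains are seeded, counted and bounded as specified", {
  cell <- tpl_rs()
  spec <- oscillatory_drive_spec(8, 50, seed = 123)
  tr1 <- generate_drive(spec, cell)
  tr2 <- generate_drive(spec, cell)
  expect_identical(tr1$events, tr2$events)  # determinism contract
  # one package per cycle over the simulated duration (the >= 5 s floor
  # extends an 8 Hz run to 40 cycles), 50 events each, none lost
  n_packages <- length(seq(1000 / 8 / 2, spec$duration, by = 1000 / 8))
  expect_identical(sum(tr1$events$kind == "exc"), 50L * n_packages)
  expect_identical(spec$duration, max(20 * 1000 / 8, 5000))
  expect_true(all(tr1$events$time >= 0 & tr1$events$time <= spec$duration))
  expect_true(!is.unsorted(tr1$events$time))
  expect_true(all(tr1$events$amp >= 0))  # truncated at zero
  # different seed, different train
  tr3 <- generate_drive(oscillatory_drive_spec(8, 50, seed = 124), cell)
  expect_false(identical(tr1$events$time, tr3$events$time))
})

test_that("excitatory amplitudes follow the specified distribution", {
  cell <- tpl_rs()
  spec <- oscillatory_drive_spec(10, 600, seed = 7)  # 12000 exc events
  ev <- generate_drive(spec, cell)$events
  amp <- ev$amp[ev$kind == "exc"]
  expect_gt(length(amp), 1e4)
  expect_equal(mean(amp), 0.22, tolerance = 0.05)  # 0.22 +/- 0.01 nS target
  expect_equal(sd(amp), sqrt(0.01), tolerance = 0.1)
  inh <- ev$amp[ev$kind == "inh"]
  expect_equal(mean(inh), 2, tolerance = 0.05)
})

test_that("synaptic waveform peaks at the event amplitude and scales linearly", {
  t <- seq(0, 40, by = 0.001)
  g <- synapse_waveform(0.22, 5, t, tau_rise = 0.5, tau_decay = 3)
  expect_identical(g[t < 5], rep(0, sum(t < 5)))
  expect_equal(max(g), 0.22, tolerance = 1e-4)
  # closed-form biexponential integral: amp * f * (tau_d - tau_r)
  tp <- 0.5 * 3 / (3 - 0.5) * log(3 / 0.5)
  fnorm <- 1 / (exp(-tp / 3) - exp(-tp / 0.5))
  expect_equal(sum(g) * 0.001, 0.22 * fnorm * (3 - 0.5), tolerance = 1e-3)
  g2 <- synapse_waveform(0.44, 5, t, tau_rise = 0.5, tau_decay = 3)
  expect_equal(sum(g2), 2 * sum(g), tolerance = 1e-9)
})

test_that("subthreshold drive oscillates around rest at the input frequency", {
  cell <- tpl_rs()
  spec <- oscillatory_drive_spec(8, 150, seed = 11)
  train <- generate_drive(spec, cell)
  tr <- integrate_cell(cell, iclamp_stim(0, spec$duration), events = train,
                       record_dt = 0.5)
  v <- tr$v[, 1]
  expect_gt(min(v), -78)                 # troughs above -78 mV
  expect_lt(max(v), -32.5)               # peaks below threshold + 5 mV
  expect_lt(abs(mean(v) - (-64.7)), 4)   # mean near rest
  pk <- torsim:::.spectral_peak(tr$time, v)
  expect_lt(abs(pk - 8), 0.5)            # spectral peak at the drive frequency
})

test_that("paired phenotype runs share bit-identical event trains", {
  pair <- build_cell_pair(seed = 2)
  spec <- oscillatory_drive_spec(10, 100, seed = 9)
  t_rs <- generate_drive(spec, pair$rs)
  t_tor <- generate_drive(spec, pair$tor)
  expect_identical(t_rs$events, t_tor$events)
})

test_that("event trains round-trip through CSV", {
  cell <- tpl_rs()
  train <- generate_drive(oscillatory_drive_spec(8, 20, seed = 3), cell)
  path <- tempfile(fileext = ".csv")
  write_events_csv(train, path)
  back <- read_events_csv(path)
  expect_equal(back$time, train$events$time, tolerance = 1e-12)
  expect_equal(back$amp, train$events$amp, tolerance = 1e-12)
  expect_identical(back$kind, train$events$kind)
  expect_identical(back$comp, train$events$comp)
  expect_match(attr(back, "meta"), "seed=3")
})
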