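test_that("spike detection applies the slope criterion and rejects artefacts", {
  t <- seq(0, 500, by = 0.025)
  flat <- list(time = t, v = rep(-65, length(t)))
  expect_identical(length(detect_spikes(flat)$times), 0L)

  # constructed ramp-and-spike with a known 50 mV/ms crossing: slope is
  # 20 mV/ms until t = 100 ms, then 100 mV/ms up to a peak
  dt <- 0.025
  v <- rep(-65, length(t))
  ramp <- t >= 95 & t < 100
  v[ramp] <- -65 + 20 * (t[ramp] - 95)
  spike <- t >= 100 & t < 101
  v[spike] <- v[sum(t < 100)] + 100 * (t[spike] - 100)
  after <- t >= 101
  v[after] <- pmax(-65, v[sum(t < 101)] - 150 * (t[after] - 101))
  st <- detect_spikes(list(time = t, v = v))
  expect_identical(length(st$times), 1L)
  expect_equal(st$times[1], 100, tolerance = 2 * dt)

  # a fast passive charging transient that never peaks above -15 mV
  v2 <- -80 + 30 * (1 - exp(-pmax(0, t - 100) / 0.2))
  expect_identical(length(detect_spikes(list(time = t, v = v2))$times), 0L)
})

test_that("spike detection is invariant to subthreshold offsets and finer sampling", {
  cell <- tpl_rs()
  hold <- find_holding_current(cell, -60)
  tr <- integrate_cell(cell, iclamp_stim(c(hold, hold + 500), c(1000, 500)),
                       v_init = -60)
  st <- detect_spikes(tr, onset_ms = 1000)
  expect_gt(length(st$times), 3)
  shifted <- list(time = tr$time, v = tr$v[, 1] + 2)
  st2 <- detect_spikes(shifted, onset_ms = 1000)
  expect_equal(st$times, st2$times, tolerance = 0.1)
  # bins sum to the total post-onset count
  expect_identical(sum(st$bins), length(st$times[st$times >= 1000]))
})

test_that("a calibrated step yields the requested firing rate", {
  cell <- tpl_rs()
  cal <- calibrate_step(cell, from_mv = -60, rate_hz = 15)
  expect_false(cal$failed)
  expect_gte(cal$rate_hz, 10)
  expect_lte(cal$rate_hz, 20)
})

test_that("exponential fits recover known time constants", {
  x <- seq(0, 200, by = 4)
  f0 <- fit_exponential(x, 5 * exp(-x / 30) + 1)
  expect_equal(f0$tau, 30, tolerance = 1e-6)
  expect_equal(f0$offset, 1, tolerance = 1e-6)
  # 5% noise: tau within 10% (median over seeds)
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    y <- 5 * exp(-x / 30) + 1 + rnorm(length(x), 0, 0.25)
    abs(fit_exponential(x, y)$tau - 30) / 30
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  # two components recovered within 15% (sampling resolves both scales)
  x2 <- c(seq(0, 20, by = 0.5), seq(22, 250, by = 4))
  y2 <- 3 * exp(-x2 / 2) + 2 * exp(-x2 / 50)
  f2 <- fit_exponential(x2, y2, n_components = 2)
  expect_equal(f2$tau[1], 2, tolerance = 0.15)
  expect_equal(f2$tau[2], 50, tolerance = 0.15)
})

test_that("Boltzmann fits recover generating parameters", {
  v <- seq(-100, -30, by = 5)
  y <- 0.97 * boltzmann(v, -64.5, 6.6, "inact")
  fit <- fit_boltzmann(v, y, "inact")
  expect_equal(fit$v_half, -64.5, tolerance = 1e-3)
  expect_equal(fit$k, 6.6, tolerance = 1e-3)
  expect_equal(fit$amplitude, 0.97, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999)
})

test_that("membrane-potential dependence fitting handles flat responses", {
  pre <- seq(-90, -50, by = 5)
  # voltage-dependent cell: delay falls steeply with depolarisation
  d <- 300 * boltzmann(pre, -70, 4, "inact") + 20
  p <- boltzmann(pre, -67, 4, "act")
  fits <- mp_dependence_curves(pre, d, p)
  expect_equal(fits$delay_fit$v_half, -70, tolerance = 1)
  expect_equal(fits$prob_fit$v_half, -67, tolerance = 1)
  # flat (no MP dependence): fit degenerates gracefully, no error, and the
  # fitted curve carries almost no voltage dependence over the window
  set.seed(1)
  flat <- mp_dependence_curves(pre, 30 + rnorm(length(pre), 0, 0.5),
                               pmin(1, 0.95 + rnorm(length(pre), 0, 0.01)))
  expect_true(all(is.finite(coef(flat$prob_fit))))
  expect_lt(diff(range(predict(flat$prob_fit, pre))), 0.2)
})

test_that("silencing percentages and band summaries follow the definition", {
  sw <- data.frame(
    cell = rep(1:2, each = 4),
    freq = rep(c(2, 10, 12, 40), 2),
    strength = 1, rep = 1, seed = 1,
    rate_rs = c(10, 8, 6, 5, 10, 9, 7, 5),
    rate_tor = c(9, 6, 3, 4.5, 9.5, 5, 4, 4.6))
  sw$pct_change <- (sw$rate_rs - sw$rate_tor) / sw$rate_rs * 100
  class(sw) <- c("sweep_result", "data.frame")
  expect_equal(sw$pct_change[2], 25)  # 8 - 6 of 8
  bs <- band_summary(sw)
  mid <- bs$mean_pct[bs$band == "8-15"]
  # rows (8,6)->25, (6,3)->50, (9,5)->44.4, (7,4)->42.9
  expect_equal(mid, mean(c(25, 50, 100 * 4 / 9, 100 * 3 / 7)),
               tolerance = 1e-9)
  # RS 10 spikes vs TOR 6 spikes is a 40% reduction
  expect_equal((10 - 6) / 10 * 100, 40)
  # output-range restriction drops out-of-range baselines
  bs2 <- band_summary(sw, output_range = c(4, 6))
  expect_identical(bs2$n[bs2$band == "8-15"], 1L)
})

test_that("spectral peak finder locates a known frequency", {
  t <- seq(0, 5000, by = 0.5)
  v <- -64 + 3 * sin(2 * pi * 8.2 * t / 1000) + rnorm(length(t), 0, 0.2)
  expect_lt(abs(torsim:::.spectral_peak(t, v) - 8.2), 0.3)
})
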