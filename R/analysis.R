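#' Detect action potentials by the 50 mV/ms slope criterion
#'
#' A spike is registered where dV/dt crosses the slope threshold upward; the
#' crossing time and voltage are recorded (the voltage at the 50 mV/ms point
#' is the operational spike threshold). Crossings closer than the refractory
#' limit are merged, and a crossing only counts if the excursion actually
#' peaks above -15 mV shortly afterwards, which rejects fast passive
#' charging transients.
#'
#' @param trace a `trace_set` (somatic voltage is used) or a list with
#'   `time` and `v`.
#' @param slope_threshold mV/ms, default 50.
#' @param onset_ms stimulus onset; delays are measured from here.
#' @param window_ms window for the AP-probability count (default first
#'   150 ms after onset).
#' @param bin_ms bin width for spike counts (default 50 ms).
#' @param refractory_ms merge limit for multiple crossings of one spike.
#' @return object of class `spike_stats`: `times` (ms), `threshold_v` (mV at
#'   each crossing), `first_delay` (ms from onset, `NA` if no spike after
#'   onset), `n_window`, `any_in_window`, `bins` (counts per bin from onset),
#'   `rate_hz` (over the post-onset trace).
#' @export
detect_spikes <- function(trace, slope_threshold = 50, onset_ms = 0,
                          window_ms = 150, bin_ms = 50, refractory_ms = 2) {
  tm <- trace$time
  v <- if (is.matrix(trace$v)) trace$v[, 1] else trace$v
  dt <- tm[2] - tm[1]
  if (dt > 0.1) warning("sampling too coarse to resolve the slope criterion",
                        " (dt = ", dt, " ms)")
  dv <- c(0, diff(v)) / dt
  cross <- which(dv >= slope_threshold & c(0, head(dv, -1)) < slope_threshold)
  win <- max(1L, round(3 / dt))
  ok <- vapply(cross, function(i)
    max(v[i:min(length(v), i + win)]) > -15, logical(1))
  cross <- cross[ok]
  if (length(cross) > 1)
    cross <- cross[c(TRUE, diff(tm[cross]) > refractory_ms)]
  times <- tm[cross]
  thr_v <- v[cross]
  post <- times[times >= onset_ms]
  dur_post <- max(tm) - onset_ms
  nb <- max(1L, ceiling(dur_post / bin_ms))
  bins <- tabulate(pmin(nb, 1L + floor((post - onset_ms) / bin_ms)), nb)
  structure(
    list(times = times, threshold_v = thr_v,
         first_delay = if (length(post)) post[1] - onset_ms else NA_real_,
         n_window = sum(post < onset_ms + window_ms),
         any_in_window = any(post < onset_ms + window_ms),
         bins = bins, bin_ms = bin_ms,
         rate_hz = length(post) / dur_post * 1000,
         onset_ms = onset_ms),
    class = "spike_stats")
}

#' @export
print.spike_stats <- function(x, ...) {
  cat(sprintf("<spike_stats> %d spikes, first delay %.1f ms, %d in first window, %.1f Hz\n",
              length(x$times), x$first_delay, x$n_window, x$rate_hz))
  invisible(x)
}

#' Membrane-potential dependence curves of firing
#'
#' Boltzmann fits of the first-spike delay and of the AP probability in the
#' early response window against the preceding membrane potential, the
#' quantification used to characterise state-dependent (TOR) firing. The
#' delay is normalised to [0, 1] per cell before fitting; the probability
#' curve uses the fraction of trials (or the normalised early spike count)
#' directly.
#'
#' @param prepulse_mv preceding membrane potentials (mV).
#' @param delay_ms first-AP delays (ms); `NA` (no spike) is treated as the
#'   maximum observed delay.
#' @param p_window AP probability (or normalised count) in the early window.
#' @return list with `delay_fit` and `prob_fit` (class `boltzmann_fit`), and
#'   the normalised delay curve.
#' @export
mp_dependence_curves <- function(prepulse_mv, delay_ms, p_window) {
  stopifnot(length(prepulse_mv) >= 6)
  d <- delay_ms
  d[is.na(d)] <- max(d, na.rm = TRUE)
  rng <- range(d)
  dn <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else rep(0, length(d))
  delay_fit <- fit_boltzmann(prepulse_mv, dn, direction = "inact")
  prob_fit <- fit_boltzmann(prepulse_mv, p_window, direction = "act")
  list(delay_fit = delay_fit, prob_fit = prob_fit,
       delay_norm = dn, prepulse_mv = prepulse_mv)
}

#' Paired-simulation silencing map over frequency and drive strength
#'
#' For every (cell, input frequency, strength, repeat) combination, one
#' seeded event train is generated and run through both the RS and the TOR
#' configuration of the same cell. The percentage change in firing is
#' `(rate_RS - rate_TOR) / rate_RS * 100`, computed only where the RS
#' configuration fired.
#'
#' @param cells list of cell pairs, each `list(rs = , tor = )` built on the
#'   same morphology (see [build_cell_pair()]).
#' @param freqs input package frequencies (Hz).
#' @param strengths events-per-package levels.
#' @param n_rep independent event-train repeats per condition.
#' @param seed base seed; per-condition seeds are derived from it by a fixed
#'   counter scheme so that paired runs share trains and runs are
#'   reproducible.
#' @param max_rs_rate grid cells with RS rate above this (Hz) are dropped
#'   (drive set to produce < 50 Hz).
#' @param progress print one line per condition.
#' @return object of class `sweep_result`: data.frame with columns `cell`,
#'   `freq`, `strength`, `rep`, `seed`, `rate_rs`, `rate_tor`, `pct_change`.
#' @export
silencing_map <- function(cells, freqs, strengths, n_rep = 2, seed = 1,
                          max_rs_rate = 50, progress = FALSE) {
  out <- list()
  k <- 0L
  for (ci in seq_along(cells)) {
    pair <- cells[[ci]]
    stopifnot(!is.null(pair$rs), !is.null(pair$tor))
    for (fi in seq_along(freqs)) {
      for (si in seq_along(strengths)) {
        for (r in seq_len(n_rep)) {
          sub <- .sub_seed(seed, ci, fi, si, r)
          spec <- oscillatory_drive_spec(freqs[fi], strengths[si], seed = sub)
          train <- generate_drive(spec, pair$rs)
          rate <- function(cell) {
            tr <- integrate_cell(cell, iclamp_stim(0, spec$duration),
                                 events = train, record_dt = 0.05)
            detect_spikes(tr)$rate_hz
          }
          r_rs <- rate(pair$rs)
          r_tor <- rate(pair$tor)
          k <- k + 1L
          out[[k]] <- data.frame(
            cell = ci, freq = freqs[fi], strength = strengths[si],
            rep = r, seed = sub, rate_rs = r_rs, rate_tor = r_tor,
            pct_change = if (r_rs > 0) (r_rs - r_tor) / r_rs * 100 else NA)
          if (progress)
            message(sprintf("cell %d f %g Hz s %d rep %d: RS %.2f Hz TOR %.2f Hz",
                            ci, freqs[fi], strengths[si], r, r_rs, r_tor))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[is.na(res$rate_rs) | res$rate_rs <= max_rs_rate, ]
  class(res) <- c("sweep_result", "data.frame")
  res
}

# deterministic sub-seed scheme (kept below 2^31)
.sub_seed <- function(base, cell, freq_i, strength_i, rep) {
  (base * 7919L + cell * 104729L + freq_i * 1299709L +
     strength_i * 15485863L + rep * 32452843L) %% 2147483629L
}

#' Band summary of the silencing map
#'
#' Mean percentage spike reduction per input-frequency band, restricted to
#' grid cells whose RS (baseline) output rate falls in the reference output
#' range (4-10 Hz by default, matching the quantification of the 8-15 Hz
#' band effect).
#'
#' @param sweep a `sweep_result`.
#' @param bands named list of `c(lo, hi)` input-frequency bands (Hz).
#' @param output_range baseline output-rate restriction (Hz).
#' @return data.frame with `band`, `mean_pct`, `sd_pct`, `n`; plus per-cell
#'   means in `attr(, "per_cell")`.
#' @export
band_summary <- function(sweep,
                         bands = list(`1-6` = c(1, 6), `8-15` = c(8, 15),
                                      `25-100` = c(25, 100)),
                         output_range = c(4, 10)) {
  keep <- !is.na(sweep$pct_change) &
    sweep$rate_rs >= output_range[1] & sweep$rate_rs <= output_range[2]
  s <- sweep[keep, ]
  rows <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    x <- s[s$freq >= b[1] & s$freq <= b[2], ]
    data.frame(band = bn, mean_pct = mean(x$pct_change),
               sd_pct = sd(x$pct_change), n = nrow(x))
  })
  out <- do.call(rbind, rows)
  per_cell <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    x <- s[s$freq >= b[1] & s$freq <= b[2], ]
    tapply(x$pct_change, x$cell, mean)
  })
  names(per_cell) <- names(bands)
  attr(out, "per_cell") <- per_cell
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d paired runs, %d cells, %d frequencies\n",
              nrow(x), length(unique(x$cell)), length(unique(x$freq))))
  NextMethod()
}

#' Build a phenotype pair on one morphology
#'
#' Convenience wrapper returning the RS- and TOR-configured versions of the
#' same stand-in cell (identical morphology, passive parameters and core
#' conductances; only the I_SA entries differ).
#'
#' @inheritParams build_cell
#' @return `list(rs = , tor = )` of `cck_cell`.
#' @export
build_cell_pair <- function(morphology = NULL, seed = NULL,
                            profile = c("whole_cell", "nucleated")) {
  profile <- match.arg(profile)
  if (is.null(morphology) && !is.null(seed))
    morphology <- make_morphologies(1, seed = seed)[[1]]
  list(rs = build_cell("rs", morphology, seed, profile),
       tor = build_cell("tor", morphology, seed, profile))
}

# dominant frequency of a (subthreshold) voltage trace, Hz
.spectral_peak <- function(time, v, f_min = 0.5) {
  dt <- (time[2] - time[1]) / 1000  # s
  x <- v - mean(v)
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(floor(n / 2))]
  fr <- (seq_len(floor(n / 2)) - 1) / (n * dt)
  sel <- fr >= f_min
  fr[sel][which.max(sp[sel])]
}
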