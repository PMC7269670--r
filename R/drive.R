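#' Width/onset scale of excitatory event packages (Eq. of the drive model)
#'
#' Frequency-dependent temporal scale of the Gaussian packages of excitatory
#' synaptic events used to build in vivo-like membrane potential
#' oscillations:
#' \deqn{onset(f) = \frac{1000}{f} 0.633 + 69.25112 \cdot 0.67747^{f} +
#'   \frac{1000}{f}}
#' with `f` in Hz and the result in ms. The last term is the package period;
#' the first two terms set the width of each package so that the membrane
#' potential keeps a sinusoid shape at every frequency.
#'
#' @param freq package frequency (Hz), > 0.
#' @return onset scale (ms).
#' @examples
#' eq1_onset(8)   # ~207.2 ms
#' @export
eq1_onset <- function(freq) {
  if (any(!is.finite(freq)) || any(freq <= 0)) stop("freq must be > 0")
  (1000 / freq) * 0.633 + 69.25112 * 0.67747^freq + 1000 / freq
}

# package standard deviation: the width terms of the onset equation are read
# as the full (+/- 3 sd) width of one Gaussian package
.package_sd <- function(freq) {
  ((1000 / freq) * 0.633 + 69.25112 * 0.67747^freq) / 6
}

#' Specify oscillatory synaptic drive
#'
#' Excitatory events are aggregated into Gaussian packages, one per cycle;
#' inhibitory events are uniform in time and keep the mean membrane
#' potential near rest. Event amplitudes follow normal distributions
#' truncated at zero (excitation mean 0.22 nS, variance 0.01 nS^2;
#' inhibition mean 2 nS, variance 0.1 nS^2). Simulations cover 20 cycles or
#' at least 5 s, whichever is longer.
#'
#' @param freq package frequency (Hz), 1-100.
#' @param events_per_package number of excitatory events per cycle (the
#'   swept "excitatory strength" parameter).
#' @param seed integer seed; event trains are fully reproducible.
#' @param inh_rate_hz rate of the uniform inhibitory event train (events/s),
#'   independent of the excitatory strength; the default was calibrated once
#'   so the mean membrane potential stays near the -64.7 mV rest at
#'   mid-range excitatory strength.
#' @param exc_mean,exc_var,inh_mean,inh_var amplitude distribution
#'   parameters (nS, nS^2).
#' @param width_mode `"width"` (default: the onset equation sets the package
#'   width, period = 1000/freq) or `"onset"` (literal reading: the equation
#'   value is used as the package period and the width scales with it).
#' @return object of class `osc_drive_spec`.
#' @export
oscillatory_drive_spec <- function(freq, events_per_package, seed = 1,
                                   inh_rate_hz = 400,
                                   exc_mean = 0.22, exc_var = 0.01,
                                   inh_mean = 2, inh_var = 0.1,
                                   width_mode = c("width", "onset")) {
  stopifnot(freq >= 1, freq <= 100, events_per_package >= 1)
  width_mode <- match.arg(width_mode)
  structure(
    list(freq = freq, events_per_package = as.integer(events_per_package),
         seed = as.integer(seed), inh_rate_hz = inh_rate_hz,
         exc = c(mean = exc_mean, var = exc_var),
         inh = c(mean = inh_mean, var = inh_var),
         duration = max(20 * 1000 / freq, 5000),
         width_mode = width_mode),
    class = "osc_drive_spec")
}

#' Generate a seeded synaptic event train
#'
#' Draws the excitatory packages and uniform inhibition defined by an
#' [oscillatory_drive_spec()] and assigns each event to a compartment of the
#' target cell, uniformly by membrane area (synapses are distributed
#' uniformly over soma and dendrites). The same spec and seed always yield
#' the identical train, which is what allows paired phenotype comparisons on
#' bit-identical inputs.
#'
#' @param spec an `osc_drive_spec`.
#' @param cell the target `cck_cell` (for compartment areas).
#' @return object of class `event_train` with `events` (data.frame: `time`
#'   ms, `amp` nS, `kind` "exc"/"inh", `comp` 1-based compartment) sorted by
#'   time, and the synaptic kinetics.
#' @export
generate_drive <- function(spec, cell) {
  stopifnot(inherits(spec, "osc_drive_spec"), inherits(cell, "cck_cell"))
  cab <- build_cable(cell)
  dur <- spec$duration
  period <- if (spec$width_mode == "width") 1000 / spec$freq else
    eq1_onset(spec$freq)
  sdw <- if (spec$width_mode == "width") .package_sd(spec$freq) else
    period / 6
  centers <- seq(period / 2, dur, by = period)
  n_exc <- length(centers) * spec$events_per_package
  n_inh <- max(1L, round(spec$inh_rate_hz * dur / 1000))
  ev <- .with_seed(spec$seed, {
    t_exc <- rep(centers, each = spec$events_per_package) +
      rnorm(n_exc, 0, sdw)
    a_exc <- pmax(0, rnorm(n_exc, spec$exc[["mean"]], sqrt(spec$exc[["var"]])))
    t_inh <- runif(n_inh, 0, dur)
    a_inh <- pmax(0, rnorm(n_inh, spec$inh[["mean"]], sqrt(spec$inh[["var"]])))
    comp <- sample.int(cab$ncomp, n_exc + n_inh, replace = TRUE,
                       prob = cab$area)
    data.frame(
      time = c(t_exc, t_inh),
      amp = c(a_exc, a_inh),
      kind = rep(c("exc", "inh"), c(n_exc, n_inh)),
      comp = comp)
  })
  # events drawn beyond the simulated window wrap around (periodic
  # continuation of the oscillation), so the event count is exact
  ev$time <- ev$time %% dur
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  structure(
    list(events = ev, duration = dur, spec = spec,
         kinetics = list(
           exc = c(tau_rise = 0.5, tau_decay = 3, e_rev = 0),
           inh = c(tau_rise = 1, tau_decay = 8, e_rev = -70))),
    class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events (%d exc / %d inh), %.0f ms, freq %g Hz, seed %d\n",
              nrow(x$events), sum(x$events$kind == "exc"),
              sum(x$events$kind == "inh"), x$duration, x$spec$freq,
              x$spec$seed))
  invisible(x)
}

#' Biexponential synaptic conductance waveform
#'
#' Conductance time course of a single synaptic event, normalised so the
#' peak equals the event amplitude:
#' `g(t) = amp * f * (exp(-(t-t0)/tau_d) - exp(-(t-t0)/tau_r))` for
#' `t >= t0`, zero before.
#'
#' @param amp peak conductance (nS).
#' @param t0 event onset (ms).
#' @param t evaluation times (ms).
#' @param tau_rise,tau_decay kinetics (ms), `tau_decay > tau_rise`.
#' @return conductance (nS) at `t`.
#' @export
synapse_waveform <- function(amp, t0, t, tau_rise = 0.5, tau_decay = 3) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  fnorm <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  dtv <- t - t0
  ifelse(dtv < 0, 0,
         amp * fnorm * (exp(-dtv / tau_decay) - exp(-dtv / tau_rise)))
}
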