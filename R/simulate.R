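# Cable assembly and the R-side wrapper around the compiled integrator.

.VGRID <- list(v0 = -150, dv = 0.25, n = 1001L)  # -150..100 mV

#' Build the compartmental cable of a cell
#'
#' Expands the morphology stand-in into compartments: the soma (compartment
#' 1) and each dendrite as a chain of equal segments attached to the soma.
#' Axial coupling conductances use the 120 Ohm cm axial resistivity and
#' half-segment series resistances.
#'
#' @param cell a `cck_cell`.
#' @return list with `parent` (0-based, -1 at the root), `area` (cm2), `cm`
#'   (uF/cm2), `g_axial` (uS), `ncomp`.
#' @keywords internal
#' @export
build_cable <- function(cell) {
  m <- cell$morphology
  ra <- cell$passive$ra
  um2cm <- 1e-4
  soma_area <- pi * m$soma[["diam"]] * m$soma[["len"]] * um2cm^2
  # axial resistance of half the soma cylinder (Ohm)
  r_half_soma <- ra * (m$soma[["len"]] / 2 * um2cm) /
    (pi * (m$soma[["diam"]] * um2cm)^2 / 4)
  parent <- -1L
  area <- soma_area
  g_ax <- 0
  comp_class <- "soma"
  idx <- 1L
  for (d in seq_len(nrow(m$dendrites))) {
    len <- m$dendrites$len[d]
    diam <- m$dendrites$diam[d]
    nseg <- m$dendrites$nseg[d]
    seg_l <- len / nseg * um2cm
    seg_area <- pi * diam * um2cm * seg_l
    r_half_seg <- ra * (seg_l / 2) / (pi * (diam * um2cm)^2 / 4)
    prev <- 0L  # soma, 0-based
    for (s in seq_len(nseg)) {
      idx <- idx + 1L
      parent <- c(parent, prev)
      area <- c(area, seg_area)
      r <- if (s == 1) r_half_soma + r_half_seg else 2 * r_half_seg
      g_ax <- c(g_ax, 1e6 / r)
      comp_class <- c(comp_class, "dend")
      prev <- idx - 1L
    }
  }
  list(parent = as.integer(parent), area = area,
       cm = rep(cell$passive$cm, length(area)),
       g_axial = g_ax, comp_class = comp_class, ncomp = length(area))
}

# per-compartment density vectors (S/cm2) for a list of channels
.expand_densities <- function(channels, morphology) {
  nseg <- sum(morphology$dendrites$nseg)
  cls <- c("soma", rep("dend", nseg))
  lapply(channels, function(ch) {
    ifelse(cls == "soma", ch$density[["soma"]], ch$density[["dend"]])
  })
}

# sample gate functions onto the shared voltage grid
.channel_tables <- function(channels, morphology, record_channels) {
  v <- .VGRID$v0 + .VGRID$dv * (seq_len(.VGRID$n) - 1)
  dens <- .expand_densities(channels, morphology)
  lapply(seq_along(channels), function(j) {
    ch <- channels[[j]]
    gates <- lapply(ch$gates, function(g) {
      inf <- pmin(pmax(g$inf(v), 0), 1)
      tau <- pmax(g$tau(v), 1e-4)
      list(power = as.integer(g$power), inf = inf, tau = tau)
    })
    list(erev = ch$erev, record = ch$name %in% record_channels,
         gbar = dens[[j]], gates = gates)
  })
}

#' Current-clamp stimulus
#'
#' Piecewise-constant somatic current injection.
#'
#' @param amplitude_pA,duration_ms equal-length vectors of epoch amplitudes
#'   (pA) and durations (ms).
#' @return object of class `stimulus`.
#' @export
iclamp_stim <- function(amplitude_pA, duration_ms) {
  stopifnot(length(amplitude_pA) == length(duration_ms), all(duration_ms > 0))
  structure(list(mode = "iclamp",
                 epochs = cbind(value = amplitude_pA, duration = duration_ms)),
            class = "stimulus")
}

#' Voltage-clamp stimulus
#'
#' Piecewise-constant command potential applied at the soma through an
#' uncompensated series resistance.
#'
#' @param level_mV,duration_ms equal-length vectors of command levels (mV)
#'   and epoch durations (ms).
#' @param rs_mohm series resistance (MOhm); the whole-cell default is the
#'   measured 2.76 MOhm, the nucleated configuration uses a near-ideal
#'   0.05 MOhm.
#' @return object of class `stimulus`.
#' @export
vclamp_stim <- function(level_mV, duration_ms, rs_mohm = .series_resistance) {
  stopifnot(length(level_mV) == length(duration_ms), all(duration_ms > 0),
            rs_mohm > 0)
  structure(list(mode = "vclamp",
                 epochs = cbind(value = level_mV, duration = duration_ms),
                 g_series = 1 / rs_mohm),
            class = "stimulus")
}

#' Simulate a model cell
#'
#' Integrates the compartmental cable with an implicit (Crank-Nicolson class)
#' scheme; gating variables advance by their exact exponential relaxation
#' between steps. Deterministic given `(cell, stim, events, dt)`.
#'
#' @param cell a `cck_cell`.
#' @param stim a `stimulus` ([iclamp_stim()] / [vclamp_stim()]).
#' @param dt time step (ms), must be <= 0.025.
#' @param duration total simulated time (ms); defaults to the stimulus
#'   length.
#' @param v_init initial membrane potential (mV); gates start at steady
#'   state for it.
#' @param events optional `event_train` of synaptic inputs (see
#'   [generate_drive()]).
#' @param record_channels channel names whose total ohmic current (nA,
#'   outward positive) is recorded.
#' @param record_dt recording interval (ms); default records every step.
#' @param record_comps compartment indices (1-based) to record; default
#'   soma only.
#' @param theta implicitness of the voltage update (0.5 = Crank-Nicolson,
#'   1 = backward Euler). Defaults to Crank-Nicolson in current clamp and to
#'   backward Euler in voltage clamp, where the stiff electrode conductance
#'   would otherwise ring.
#' @return object of class `trace_set`: `time` (ms), `v` (mV, matrix with one
#'   column per recorded compartment), `i_clamp` (nA, voltage clamp only),
#'   `i_channel` (nA, one column per recorded channel), plus metadata.
#' @export
integrate_cell <- function(cell, stim, dt = 0.025, duration = NULL,
                           v_init = NULL, events = NULL,
                           record_channels = character(),
                           record_dt = NULL, record_comps = 1L,
                           theta = NULL) {
  stopifnot(inherits(cell, "cck_cell"), inherits(stim, "stimulus"))
  if (dt > 0.025 + 1e-12) stop("dt must be <= 0.025 ms")
  if (is.null(duration)) duration <- sum(stim$epochs[, "duration"])
  if (duration <= 0) stop("duration must be positive")
  if (is.null(v_init)) v_init <- cell$v_rest
  if (is.null(theta)) theta <- if (stim$mode == "vclamp") 1 else 0.5

  cab <- build_cable(cell)
  chans <- .channel_tables(cell$channels, cell$morphology, record_channels)

  syn <- NULL
  if (!is.null(events)) {
    stopifnot(inherits(events, "event_train"))
    ev <- events$events
    kin <- events$kinetics
    syn <- list(time = ev$time, amp = ev$amp,
                kind = as.integer(ev$kind == "inh"),
                comp = as.integer(ev$comp - 1L),
                tau_rise = c(kin$exc["tau_rise"], kin$inh["tau_rise"]),
                tau_decay = c(kin$exc["tau_decay"], kin$inh["tau_decay"]),
                e_rev = c(kin$exc["e_rev"], kin$inh["e_rev"]))
  }

  cstim <- list(mode = stim$mode, epochs = stim$epochs, comp = 0L)
  if (stim$mode == "vclamp") cstim$g_series <- stim$g_series

  res <- .simulate_cpp(
    cable = cab, channels = chans, grid = .VGRID, stim = cstim,
    syn_ = syn, dt = dt, duration = duration,
    v_init = as.numeric(v_init), theta = theta,
    record_dt = if (is.null(record_dt)) 0 else record_dt,
    record_comps = as.integer(record_comps - 1L), abort_v = 200
  )
  if (res$diverged)
    stop("numerical divergence (|V| > 200 mV); check stimulus and densities")

  ich <- res$i_channel
  rec_flag <- vapply(chans, `[[`, TRUE, "record")
  colnames(ich) <- vapply(cell$channels, `[[`, "", "name")[rec_flag]
  structure(
    list(time = res$time, v = res$v,
         i_clamp = if (stim$mode == "vclamp") res$i_clamp else NULL,
         i_channel = ich, dt = dt, stim = stim, phenotype = cell$phenotype,
         record_comps = record_comps),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d samples, %.1f ms, dt = %g ms, %s\n",
              length(x$time), max(x$time), x$dt, x$stim$mode))
  invisible(x)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  out <- data.frame(time = x$time)
  for (j in seq_len(ncol(x$v)))
    out[[paste0("v", x$record_comps[j])]] <- x$v[, j]
  if (!is.null(x$i_clamp) && length(x$i_clamp)) out$i_clamp <- x$i_clamp
  for (nm in colnames(x$i_channel)) out[[nm]] <- x$i_channel[, nm]
  out
}

#' @export
plot.trace_set <- function(x, what = c("v", "i"), ...) {
  what <- match.arg(what)
  if (what == "v") {
    graphics::plot(x$time, x$v[, 1], type = "l", xlab = "time (ms)",
                   ylab = "membrane potential (mV)", ...)
  } else {
    y <- if (!is.null(x$i_clamp) && length(x$i_clamp)) x$i_clamp else
      x$i_channel[, 1]
    graphics::plot(x$time, y, type = "l", xlab = "time (ms)",
                   ylab = "current (nA)", ...)
  }
  invisible(x)
}

# command potential at the recorded time points of a vclamp trace
.command_of <- function(trace) {
  ep <- trace$stim$epochs
  ends <- cumsum(ep[, "duration"])
  idx <- findInterval(trace$time, c(0, ends[-length(ends)]),
                      rightmost.closed = FALSE)
  ep[pmin(idx, nrow(ep)), "value"]
}
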