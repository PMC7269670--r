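#' Voltage-dependent inactivation time constant from anchors
#'
#' Builds the inactivation/recovery time constant curve tau_h(V) by monotone
#' cubic (Fritsch-Carlson) interpolation through measured anchors: recovery
#' time constants on the hyperpolarized limb and the decay time constant of
#' the current on the depolarized limb. Outside the anchor range the curve is
#' clamped at the end anchor values, keeping it strictly positive everywhere.
#'
#' @param v voltage(s) (mV).
#' @param anchors two-column matrix or data.frame `(v, tau)` with at least two
#'   rows, distinct voltages and strictly positive time constants (ms).
#' @return tau (ms) at `v`; passes through every anchor exactly.
#' @examples
#' anchors <- cbind(v = c(-120, -85, -75, -65, -25),
#'                  tau = c(4.4, 29.8, 46.2, 58.2, 71.2))
#' tau_h(-85, anchors)  # 29.8
#' @export
tau_h <- function(v, anchors) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2) stop("need at least two tau anchors")
  if (anyDuplicated(anchors[, 1])) stop("anchor voltages must be distinct")
  if (any(anchors[, 2] <= 0)) stop("all tau anchors must be strictly positive")
  ord <- order(anchors[, 1])
  av <- anchors[ord, 1]
  at <- anchors[ord, 2]
  f <- splinefun(av, at, method = "monoH.FC")
  vc <- pmin(pmax(v, av[1]), av[length(av)])
  f(vc)
}

.const_fun <- function(value) {
  force(value)
  function(v) rep(value, length(v))
}

.gate <- function(power, inf, tau) list(power = power, inf = inf, tau = tau)

#' Construct a Hodgkin-Huxley channel model
#'
#' Low-level constructor. Gates are given as functions of voltage for the
#' steady state and time constant; the simulator samples them onto a lookup
#' grid. Most users will use the presets ([isa_channel()], [core_channels()]).
#'
#' @param name identifier.
#' @param erev reversal potential (mV).
#' @param gates list of gates, each `list(power, inf = function(v),
#'   tau = function(v))`.
#' @param density named numeric `c(soma = , dend = )` in S/cm2, both >= 0.
#' @param gating optional list of Boltzmann parameters retained as metadata
#'   (needed by [apply_hptx()] and [channel_current()]).
#' @return object of class `channel`.
#' @export
hh_channel <- function(name, erev, gates, density, gating = NULL) {
  stopifnot(is.character(name), is.finite(erev))
  density <- c(soma = unname(density["soma"]), dend = unname(density["dend"]))
  density[is.na(density)] <- 0
  if (any(density < 0)) stop("channel density must be >= 0")
  structure(list(name = name, erev = erev, gates = gates,
                 density = density, gating = gating),
            class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel %s> E = %g mV, density soma %.3g / dend %.3g S/cm2, %d gate(s)\n",
              x$name, x$erev, x$density["soma"], x$density["dend"],
              length(x$gates)))
  invisible(x)
}

#' I_SA channel variant presets
#'
#' The two kinetic variants of the subthreshold-activated A-type potassium
#' current. Steady-state activation/inactivation are single Boltzmann curves
#' (gate exponents 1), the activation time constant is fixed at 1 ms, and
#' tau_h(V) interpolates the measured recovery and inactivation time
#' constants (see [tau_h()]).
#'
#' Two calibration profiles are shipped. `"whole_cell"` uses the whole-cell
#' inactivation midpoints (-64.5 / -57.4 mV) and activation anchored to the
#' threshold-range whole-cell current amplitudes; `"nucleated"` uses the
#' nucleated-patch activation midpoints (-16.4 / -8.9 mV) and time constants.
#' Both share the whole-cell inactivation curves.
#'
#' @param variant `"tor"` or `"rs"`.
#' @param profile `"whole_cell"` or `"nucleated"`.
#' @param density named `c(soma=, dend=)` density in S/cm2; defaults to the
#'   phenotype-mix values (see [isa_preset()]).
#' @return `channel` object.
#' @export
isa_channel <- function(variant = c("tor", "rs"),
                        profile = c("whole_cell", "nucleated"),
                        density = NULL) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  act <- switch(profile,
                whole_cell = .isa_act_whole_cell[[variant]],
                nucleated = .isa_act_nucleated[[variant]])
  inact <- .isa_inact[[variant]]
  anchors <- .isa_tau_h[[profile]][[variant]]
  if (is.null(density)) {
    density <- switch(variant,
                      tor = .isa_density$tor$isa_tor,
                      rs = .isa_density$rs$isa_rs)
  }
  gating <- list(v_half_act = act$v_half, k_act = act$k, exponent_act = 1L,
                 tau_act = .isa_tau_m, v_half_inact = inact$v_half,
                 k_inact = inact$k, tau_inact_anchors = anchors,
                 has_inactivation = TRUE)
  .build_isa(paste0("isa_", variant), density, gating)
}

.build_isa <- function(name, density, gating) {
  g <- gating
  m_inf <- function(v) boltzmann(v, g$v_half_act, g$k_act, "act")
  h_inf <- function(v) boltzmann(v, g$v_half_inact, g$k_inact, "inact")
  h_tau <- function(v) tau_h(v, g$tau_inact_anchors)
  hh_channel(name, .E_K,
             gates = list(.gate(g$exponent_act, m_inf, .const_fun(g$tau_act)),
                          .gate(1L, h_inf, h_tau)),
             density = density, gating = g)
}

#' Shift activation voltage dependence (gating-modifier toxin effect)
#'
#' Heteropodatoxin (HpTX) inhibits Kv4-mediated I_SA by shifting the voltage
#' dependence of activation toward depolarized potentials. The measured
#' midpoint shifts are +12.4 mV (TOR) and +21.5 mV (RS).
#'
#' @param model a `channel` built by [isa_channel()] (or any channel carrying
#'   Boltzmann gating metadata).
#' @param shift depolarizing shift of the activation midpoint (mV).
#' @return a copy of `model` with `v_half_act` increased by `shift`; all
#'   other parameters unchanged.
#' @export
apply_hptx <- function(model, shift) {
  stopifnot(inherits(model, "channel"), is.finite(shift))
  if (is.null(model$gating))
    stop("channel '", model$name, "' carries no Boltzmann gating metadata")
  g <- model$gating
  g$v_half_act <- g$v_half_act + shift
  .build_isa(model$name, model$density, g)
}

#' Ohmic channel current at given gate states
#'
#' Standard Hodgkin-Huxley ohmic current, outward positive:
#' `I = density * m^a * h * (v - reversal)`.
#'
#' @param model a `channel` (somatic density is used).
#' @param v membrane voltage (mV).
#' @param m,h gate fractions in `[0, 1]` (`h` ignored for channels without
#'   inactivation).
#' @param area_um2 optional membrane area; if given, the absolute current is
#'   also returned.
#' @return list with `density_mA_cm2` and (if `area_um2` given) `pA`.
#' @export
channel_current <- function(model, v, m, h = 1, area_um2 = NULL) {
  stopifnot(inherits(model, "channel"))
  if (any(m < 0 | m > 1) || any(h < 0 | h > 1))
    stop("gate fractions must lie in [0, 1]")
  a <- if (!is.null(model$gating)) model$gating$exponent_act
  else if (length(model$gates)) model$gates[[1]]$power
  else 1L
  # S/cm2 * mV = mA/cm2
  dens <- model$density[["soma"]] * m^a * h * (v - model$erev)
  out <- list(density_mA_cm2 = dens)
  if (!is.null(area_um2)) {
    # mA/cm2 * cm2 -> mA; 1 mA = 1e9 pA; 1 um2 = 1e-8 cm2
    out$pA <- dens * area_um2 * 1e-8 * 1e9
  }
  out
}

#' I_SA channel set for a firing phenotype
#'
#' The RS phenotype carries a single I_SA_RS conductance; the TOR phenotype a
#' mixture of I_SA_RS and the left-shifted, slowly recovering I_SA_TOR in a
#' roughly 3:1 RS:TOR density ratio. All I_SA entries use a 2.96:1
#' somatic:dendritic density ratio.
#'
#' @param phenotype `"tor"` or `"rs"`.
#' @param profile calibration profile, see [isa_channel()].
#' @param scale multiplicative density scale (cell-to-cell variability).
#' @return list of `channel` objects.
#' @export
isa_preset <- function(phenotype = c("tor", "rs"),
                       profile = c("whole_cell", "nucleated"),
                       scale = 1) {
  phenotype <- match.arg(phenotype)
  profile <- match.arg(profile)
  dens <- .isa_density[[phenotype]]
  out <- lapply(names(dens), function(nm) {
    variant <- sub("isa_", "", nm)
    isa_channel(variant, profile, density = dens[[nm]] * scale)
  })
  names(out) <- names(dens)
  out
}

#' Core spiking conductances
#'
#' Minimal action-potential machinery shared by both phenotypes: transient
#' sodium (m^3 h, E_Na = +60 mV), delayed-rectifier potassium (n^2), a
#' spike-triggered adaptation potassium current, and ohmic leak. Densities
#' and gate midpoints were tuned once against the firing features of CCK+
#' interneurons (depolarized spike threshold, narrow spikes, accommodating
#' trains, short onset delay from hyperpolarized potentials in the RS
#' configuration) and are never varied between phenotypes.
#'
#' @param g_leak leak density (S/cm2).
#' @param e_leak leak reversal (mV); usually solved by [build_cell()] so the
#'   cell rests at -64.7 mV.
#' @param density_scale named list overriding core densities.
#' @return list of `channel` objects: `core_na`, `core_kdr`, `core_adapt`,
#'   `leak`.
#' @export
core_channels <- function(g_leak = .passive_defaults$g_leak, e_leak = -65,
                          density_scale = NULL) {
  dn <- .core_density
  if (!is.null(density_scale))
    for (nm in names(density_scale)) dn[[nm]] <- dn[[nm]] * density_scale[[nm]]
  na <- hh_channel(
    "core_na", .E_NA,
    gates = list(
      .gate(3L, function(v) 1 / (1 + exp(-(v + 30) / 6)), .const_fun(0.1)),
      .gate(1L, function(v) 1 / (1 + exp((v + 45) / 6)),
            function(v) 1 + 35 / (1 + exp((v + 40) / 6)))
    ),
    density = dn$na)
  kdr <- hh_channel(
    "core_kdr", .E_K,
    gates = list(
      .gate(2L, function(v) 1 / (1 + exp(-(v + 12) / 8)),
            function(v) 0.5 + 1.5 / (1 + exp((v + 20) / 8)))
    ),
    density = dn$kdr)
  # adaptation gate opens only during spikes (midpoint -25 mV), so the
  # after-spike K+ load accumulates with firing but is insensitive to the
  # subthreshold holding potential
  adapt <- hh_channel(
    "core_adapt", .E_K,
    gates = list(
      .gate(1L, function(v) 1 / (1 + exp(-(v + 25) / 4)), .const_fun(150))
    ),
    density = dn$adapt)
  lk <- hh_channel("leak", e_leak, gates = list(),
                   density = c(soma = g_leak, dend = g_leak))
  list(core_na = na, core_kdr = kdr, core_adapt = adapt, leak = lk)
}
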