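#' Passive membrane parameters
#'
#' @param cm specific capacitance (uF/cm2), within the measured 0.82-1.05
#'   range.
#' @param g_leak leak density (S/cm2), within 5e-5 to 5.8e-5.
#' @param e_leak leak reversal (mV).
#' @param ra axial resistivity (Ohm cm), fixed at 120.
#' @return list of class `passive_params`.
#' @export
passive_params <- function(cm = .passive_defaults$cm,
                           g_leak = .passive_defaults$g_leak,
                           e_leak = -65,
                           ra = .passive_defaults$ra) {
  rng <- .passive_defaults
  if (cm < rng$cm_range[1] - 1e-9 || cm > rng$cm_range[2] + 1e-9)
    stop("cm outside the measured range [0.82, 1.05] uF/cm2")
  if (g_leak < rng$g_leak_range[1] - 1e-12 || g_leak > rng$g_leak_range[2] + 1e-12)
    stop("g_leak outside the measured range [5e-5, 5.8e-5] S/cm2")
  structure(list(cm = cm, g_leak = g_leak, e_leak = e_leak, ra = ra),
            class = "passive_params")
}

#' Assemble a model CCK+ interneuron
#'
#' Builds a reduced compartmental cell in either firing configuration. The
#' two phenotypes differ *only* in their I_SA channel entries: the RS
#' configuration carries I_SA_RS alone (2.97 mS/cm2 somatic), the TOR
#' configuration the I_SA_TOR + I_SA_RS mixture (1.72 mS/cm2 somatic total).
#' Passive parameters and core spiking conductances are identical for the
#' same morphology/seed, so exchanging the phenotype isolates the effect of
#' the I_SA variant.
#'
#' The leak reversal is solved so that the two phenotypes' steady-state
#' resting potentials straddle the -64.7 mV target symmetrically; it is
#' phenotype-independent and each configuration rests within ~2.5 mV of the
#' target with zero holding current (the larger TOR I_SA window current
#' sits below, the RS one above).
#'
#' @param phenotype `"tor"` or `"rs"`.
#' @param morphology a [morph_standin()]; default is the calibrated template
#'   (jittered when `seed` is given).
#' @param seed integer; when non-NULL, draws per-cell passive parameters and
#'   an I_SA density scale factor (CV 0.159) reproducibly. `NULL` gives the
#'   population-mean cell.
#' @param profile I_SA calibration profile, see [isa_channel()].
#' @return object of class `cck_cell`.
#' @examples
#' cell <- build_cell("tor")
#' cell$channels$isa_tor$density["soma"] +
#'   cell$channels$isa_rs$density["soma"]   # 1.72e-3 S/cm2
#' @export
build_cell <- function(phenotype = c("tor", "rs"), morphology = NULL,
                       seed = NULL, profile = c("whole_cell", "nucleated")) {
  phenotype <- match.arg(phenotype)
  profile <- match.arg(profile)
  if (is.null(morphology)) {
    morphology <- if (is.null(seed)) template_morphology() else
      make_morphologies(1, seed = seed)[[1]]
  }
  stopifnot(inherits(morphology, "morph_standin"))
  if (any(morphology$dendrites$len / morphology$dendrites$nseg > 20 + 1e-9))
    stop("morphology violates the <= 20 um segment discretisation")

  rng <- .passive_defaults
  if (is.null(seed)) {
    cm <- rng$cm
    g_leak <- rng$g_leak
    isa_scale <- 1
  } else {
    draws <- .with_seed(seed + 1000003L, {
      c(runif(1, rng$cm_range[1], rng$cm_range[2]),
        runif(1, rng$g_leak_range[1], rng$g_leak_range[2]),
        max(0.5, 1 + rnorm(1, 0, .isa_density_cv)))
    })
    cm <- draws[1]; g_leak <- draws[2]; isa_scale <- draws[3]
  }

  core <- core_channels(g_leak = g_leak, e_leak = -65)
  isa <- isa_preset(phenotype, profile, scale = isa_scale)
  channels <- c(core, isa)

  cell <- structure(
    list(morphology = morphology,
         passive = passive_params(cm = cm, g_leak = g_leak, e_leak = -65),
         channels = channels, phenotype = phenotype, profile = profile,
         isa_scale = isa_scale, seed = seed,
         v_rest = rng$v_rest),
    class = "cck_cell")

  # shared leak reversal (phenotype-independent by design)
  e_leak <- .solve_e_leak(cell)
  cell$passive$e_leak <- e_leak
  cell$channels$leak$erev <- e_leak
  cell
}

# leak reversal such that total steady-state membrane current vanishes at
# the target resting potential. The I_SA window current is evaluated as the
# mean of the RS and TOR channel sets, so the solved reversal is identical
# for both phenotypes of a cell (phenotype purity) and each configuration
# rests within ~2 mV of the target.
.solve_e_leak <- function(cell) {
  cab <- build_cable(cell)
  core <- core_channels(g_leak = cell$passive$g_leak, e_leak = 0)[
    c("core_na", "core_kdr", "core_adapt")]
  current_of <- function(chans, v) {
    dens <- .expand_densities(chans, cell$morphology)
    tot <- 0
    for (j in seq_along(chans)) {
      ch <- chans[[j]]
      gp <- 1
      for (g in ch$gates) gp <- gp * g$inf(v)^g$power
      tot <- tot + sum(dens[[j]] * cab$area) * gp * (v - ch$erev)
    }
    tot
  }
  isa_rs <- isa_preset("rs", cell$profile, scale = cell$isa_scale)
  isa_tor <- isa_preset("tor", cell$profile, scale = cell$isa_scale)
  g_leak_tot <- cell$passive$g_leak * sum(cab$area)
  # steady-state (uniform-V) resting potential of one phenotype for a given
  # leak reversal
  rest_of <- function(e_leak, isa) {
    uniroot(function(v) {
      current_of(core, v) + current_of(isa, v) + g_leak_tot * (v - e_leak)
    }, c(-90, -48), tol = 1e-4)$root
  }
  # choose e_leak so the two phenotypes' rests straddle the target equally
  uniroot(function(e) {
    (rest_of(e, isa_rs) + rest_of(e, isa_tor)) / 2 - cell$v_rest
  }, c(-85, -52), tol = 1e-4)$root
}

#' @export
print.cck_cell <- function(x, ...) {
  isa <- grep("^isa_", names(x$channels), value = TRUE)
  tot <- sum(vapply(x$channels[isa], function(ch) ch$density[["soma"]],
                    numeric(1)))
  cat(sprintf("<cck_cell> phenotype %s (%s profile), %d compartments, area %.0f um^2\n",
              toupper(x$phenotype), x$profile,
              sum(x$morphology$dendrites$nseg) + 1L,
              x$morphology$total_area_um2))
  cat(sprintf("  somatic I_SA density %.3g mS/cm2 (%s), rest %.1f mV\n",
              tot * 1e3, paste(isa, collapse = " + "), x$v_rest))
  invisible(x)
}

#' Cell carrying a single calibrated I_SA variant
#'
#' For channel-level protocol round-trips (availability, recovery,
#' inactivation time constants) the printed curves describe one calibrated
#' I_SA variant in isolation; the TOR firing phenotype, in contrast, carries
#' a 3:1 RS:TOR density mixture whose compound protocol curves are slightly
#' right-shifted and faster than the pure TOR component. This builder
#' returns a cell carrying the single named variant at its own component
#' density (somatic 0.44 mS/cm2 for I_SA_TOR, 2.97 mS/cm2 for I_SA_RS), on
#' top of the usual core set; keeping the component's density also keeps the
#' clamp currents near the measured scale, so series-resistance errors stay
#' realistic.
#'
#' @inheritParams build_cell
#' @param variant `"tor"` or `"rs"`.
#' @return `cck_cell`.
#' @export
build_channel_cell <- function(variant = c("tor", "rs"), morphology = NULL,
                               seed = NULL,
                               profile = c("whole_cell", "nucleated")) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  cell <- build_cell(variant, morphology, seed, profile)
  isa <- .isa_names(cell)
  dens <- switch(variant,
                 tor = .isa_density$tor$isa_tor,
                 rs = .isa_density$rs$isa_rs) * cell$isa_scale
  cell$channels[isa] <- NULL
  cell$channels[[paste0("isa_", variant)]] <-
    isa_channel(variant, profile, density = dens)
  cell
}

#' Total I_SA conductance ratio between two configurations
#'
#' Area-weighted total I_SA conductance of the first cell divided by that of
#' the second. For the population-mean TOR and RS configurations this ratio
#' is 1.72/2.97 = 0.579: TOR firing requires less I_SA conductance.
#'
#' @param cell_a,cell_b `cck_cell` objects built on the same morphology.
#' @return dimensionless fraction.
#' @export
total_conductance_ratio <- function(cell_a, cell_b) {
  stopifnot(inherits(cell_a, "cck_cell"), inherits(cell_b, "cck_cell"))
  if (!isTRUE(all.equal(cell_a$morphology, cell_b$morphology)))
    stop("cells must share the same morphology")
  tot <- function(cell) {
    cab <- build_cable(cell)
    isa <- grep("^isa_", names(cell$channels), value = TRUE)
    dens <- .expand_densities(cell$channels[isa], cell$morphology)
    sum(vapply(seq_along(isa), function(j) sum(dens[[j]] * cab$area),
               numeric(1)))
  }
  ta <- tot(cell_a); tb <- tot(cell_b)
  if (tb == 0) stop("reference cell has zero I_SA conductance")
  ta / tb
}
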