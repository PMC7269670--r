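# Synthetic-data fixtures: noisy protocol measurements with recorded ground
# truth, for exercising the fitting pipeline without recordings.

#' Clean protocol base for noisy fixtures
#'
#' Simulates the steady-state inactivation or recovery protocol once on a
#' single-variant cell and keeps the clean test-pulse traces, so that many
#' noisy fixtures can be drawn from one simulation.
#'
#' @param variant `"tor"` or `"rs"`.
#' @param protocol `"inactivation"` or `"recovery"`.
#' @param recovery_v recovery voltage for the recovery protocol (mV).
#' @return object of class `fixture_base` with the clean traces, the grid,
#'   and the generating (model) parameters.
#' @export
fixture_base <- function(variant = c("tor", "rs"),
                         protocol = c("inactivation", "recovery"),
                         recovery_v = -85) {
  variant <- match.arg(variant)
  protocol <- match.arg(protocol)
  cell <- build_channel_cell(variant)
  g <- cell$channels[[paste0("isa_", variant)]]$gating
  if (protocol == "inactivation") {
    grid <- seq(-100, -35, by = 5)
    traces <- lapply(grid, function(pv) {
      r <- .isa_clamp_trace(cell, c(pv, -30), c(1000, 300),
                            .series_resistance, pv)
      sel <- r$time > 1000
      list(time = r$time[sel] - 1000, i_nA = r$i_sub[sel])
    })
    truth <- list(v_half = g$v_half_inact, k = g$k_inact)
  } else {
    grid <- exp(seq(log(1), log(233), length.out = 12))
    traces <- lapply(grid, function(dtv) {
      r <- .isa_clamp_trace(cell, c(-120, -30, recovery_v, -30),
                            c(345, 500, dtv, 150),
                            .series_resistance, -120)
      tot <- 345 + 500 + dtv + 150
      sel <- r$time > tot - 150
      list(time = r$time[sel], i_nA = r$i_sub[sel])
    })
    truth <- list(tau = tau_h(recovery_v, g$tau_inact_anchors),
                  recovery_v = recovery_v)
  }
  structure(list(variant = variant, protocol = protocol, grid = grid,
                 traces = traces, truth = truth),
            class = "fixture_base")
}

#' Noisy current fixture with recorded ground truth
#'
#' Adds seeded white (Gaussian) current noise to the clean protocol traces
#' of a [fixture_base()] and extracts the measured curve the way the
#' analysis pipeline would: smoothed-peak currents for the inactivation
#' protocol, test-pulse areas for the recovery protocol. The generating
#' parameters (both the model values and the noiseless-pipeline fit) ride
#' along as ground truth.
#'
#' @param base a `fixture_base` (built if a variant name is given instead).
#' @param noise_sd noise standard deviation (pA).
#' @param seed integer seed.
#' @return object of class `trace_fixture` with `curve` (x, y), `truth`,
#'   `noise_sd`, `seed`.
#' @export
make_noisy_current_fixture <- function(base, noise_sd = 10, seed = 1) {
  if (is.character(base)) base <- fixture_base(base)
  stopifnot(inherits(base, "fixture_base"), noise_sd >= 0)
  smooth_peak <- function(tr, n = 20) {
    i <- tr$i_nA
    if (length(i) > n) i <- stats::filter(i, rep(1 / n, n), sides = 2)
    max(i, na.rm = TRUE)
  }
  y <- .with_seed(seed, {
    vapply(base$traces, function(tr) {
      dt <- tr$time[2] - tr$time[1]
      noisy <- tr
      noisy$i_nA <- tr$i_nA + rnorm(length(tr$i_nA), 0, noise_sd * 1e-3)
      if (base$protocol == "inactivation") smooth_peak(noisy) * 1e3  # pA
      else sum(noisy$i_nA) * dt                                      # pC
    }, numeric(1))
  })
  curve <- data.frame(x = base$grid, y = y)
  # noiseless pipeline value as the measurement-level ground truth
  y0 <- vapply(base$traces, function(tr) {
    dt <- tr$time[2] - tr$time[1]
    if (base$protocol == "inactivation") smooth_peak(tr) * 1e3
    else sum(tr$i_nA) * dt
  }, numeric(1))
  truth <- base$truth
  truth$noiseless_fit <- .fit_fixture_curve(base$protocol, base$grid, y0)
  structure(list(variant = base$variant, protocol = base$protocol,
                 curve = curve, truth = truth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_fixture")
}

.fit_fixture_curve <- function(protocol, x, y) {
  if (protocol == "inactivation") {
    fit <- fit_boltzmann(x, y / max(y), direction = "inact")
    c(v_half = fit$v_half, k = fit$k)
  } else {
    fit <- fit_exponential(x, y, n_components = 1)
    c(tau = fit$tau)
  }
}

#' Fit a noisy fixture with the analysis pipeline
#'
#' @param fx a `trace_fixture`.
#' @return named vector of fitted parameters (`v_half`, `k` for
#'   inactivation; `tau` for recovery).
#' @export
fit_fixture <- function(fx) {
  stopifnot(inherits(fx, "trace_fixture"))
  .fit_fixture_curve(fx$protocol, fx$curve$x, fx$curve$y)
}

#' Write / read a fixture as CSV (lossless round-trip)
#'
#' @param fx a `trace_fixture`.
#' @param path file path.
#' @export
write_fixture_csv <- function(fx, path) {
  con <- file(path, "w")
  truth <- fx$truth[setdiff(names(fx$truth), "noiseless_fit")]
  writeLines(sprintf("# torsim fixture: variant=%s protocol=%s noise_sd=%.17g seed=%d %s",
                     fx$variant, fx$protocol, fx$noise_sd, fx$seed,
                     paste(names(truth), vapply(truth, function(v)
                       sprintf("%.17g", v), ""), sep = "=", collapse = " ")),
             con)
  write.csv(fx$curve, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_fixture_csv
#' @export
read_fixture_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  curve <- read.csv(path, comment.char = "#")
  meta <- sub("^# torsim fixture: ", "", hdr)
  kv <- strsplit(strsplit(meta, " ")[[1]], "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- setNames(suppressWarnings(as.numeric(vals)), names(vals))
  truth <- as.list(num[!is.na(num) & !names(num) %in%
                         c("noise_sd", "seed")])
  structure(list(variant = vals[["variant"]], protocol = vals[["protocol"]],
                 curve = curve, truth = truth,
                 noise_sd = as.numeric(vals[["noise_sd"]]),
                 seed = as.integer(vals[["seed"]])),
            class = "trace_fixture")
}
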