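# File interfaces: tidy CSV for traces and event trains, JSON for configs
# and fits. Seeds and generating parameters are recorded in headers /
# config objects so every output is regenerable.

#' Write / read a trace set as tidy CSV
#'
#' Columns: `time` (ms) plus one column per recorded quantity. A commented
#' header records the stimulus mode and time step.
#'
#' @param trace a `trace_set`.
#' @param path file path.
#' @return `read_trace_csv` returns a data.frame with the header metadata in
#'   `attr(, "meta")`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  con <- file(path, "w")
  writeLines(sprintf("# torsim trace: mode=%s dt=%g phenotype=%s",
                     trace$stim$mode, trace$dt,
                     trace$phenotype %||% "NA"), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- read.csv(path, comment.char = "#")
  attr(df, "meta") <- sub("^# torsim trace: ", "", hdr)
  df
}

#' Write / read an event train as CSV
#'
#' Columns `time`, `amp`, `kind`, `comp`; the commented header records the
#' generating seed, frequency and strength, so a train file documents its
#' own provenance. Round-trips losslessly.
#'
#' @param train an `event_train`.
#' @param path file path.
#' @export
write_events_csv <- function(train, path) {
  con <- file(path, "w")
  writeLines(sprintf("# torsim events: seed=%d freq=%g events_per_package=%d inh_rate_hz=%g duration=%g",
                     train$spec$seed, train$spec$freq,
                     train$spec$events_per_package, train$spec$inh_rate_hz,
                     train$duration), con)
  write.csv(train$events, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  ev <- read.csv(path, comment.char = "#")
  attr(ev, "meta") <- sub("^# torsim events: ", "", hdr)
  ev
}

#' Serialize / restore a cell configuration
#'
#' The JSON config holds everything needed to rebuild the cell bit-
#' identically: phenotype, calibration profile, seed, passive parameters,
#' morphology dimensions and the per-channel densities. `read_cell_config`
#' reconstructs the `cck_cell` through the normal builders, so configs
#' round-trip losslessly.
#'
#' @param cell a `cck_cell`.
#' @param path file path (`.json`).
#' @export
write_cell_config <- function(cell, path) {
  cfg <- list(
    phenotype = cell$phenotype,
    profile = cell$profile,
    seed = cell$seed,
    isa_scale = cell$isa_scale,
    passive = unclass(cell$passive),
    morphology = list(soma = as.list(cell$morphology$soma),
                      dendrites = cell$morphology$dendrites[c("len", "diam")],
                      seg_len = cell$morphology$seg_len),
    densities = lapply(cell$channels, function(ch) as.list(ch$density))
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_config
#' @export
read_cell_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- morph_standin(c(diam = cfg$morphology$soma$diam,
                       len = cfg$morphology$soma$len),
                     as.data.frame(cfg$morphology$dendrites),
                     seg_len = cfg$morphology$seg_len)
  cell <- build_cell(cfg$phenotype, morphology = m,
                     seed = if (is.null(cfg$seed)) NULL else cfg$seed,
                     profile = cfg$profile)
  cell
}

#' Write a fit object as JSON
#'
#' @param fit a `boltzmann_fit` or `exp_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    c(list(class = class(fit)[1]), unclass(fit)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
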