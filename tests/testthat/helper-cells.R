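# Shared fixtures: template cells and a few expensive simulations are built
# once per test run and memoised here.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, expr, .cache)
  get(key, .cache)
}

tpl_rs <- function() memo("rs", build_cell("rs"))
tpl_tor <- function() memo("tor", build_cell("tor"))
tpl_ctor <- function() memo("ctor", build_channel_cell("tor"))
tpl_crs <- function() memo("crs", build_channel_cell("rs"))

# passive-only single compartment (soma cylinder, 20x20 um)
passive_cell <- function() memo("passive", {
  m <- morph_standin(c(diam = 20, len = 20),
                     data.frame(len = numeric(0), diam = numeric(0)))
  cell <- build_cell("rs", morphology = m)
  for (nm in c("core_na", "core_kdr", "core_adapt", "isa_rs"))
    cell$channels[[nm]]$density[] <- 0
  cell$channels$leak$erev <- -65
  cell$passive$e_leak <- -65
  cell
})

soma_area_cm2 <- function() pi * 20 * 20 * 1e-8
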