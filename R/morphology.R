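#' Reduced morphology stand-in
#'
#' A soma plus unbranched dendrites, standing in for full anatomical
#' reconstructions. Sections are cylinders; dendrites are discretised into
#' segments no longer than `seg_len` micrometres.
#'
#' @param soma numeric `c(diam =, len =)` in um.
#' @param dendrites data.frame with columns `len`, `diam` (um), one row per
#'   dendrite.
#' @param seg_len maximum segment length (um), <= 20.
#' @return object of class `morph_standin` with the total membrane area
#'   (um^2) attached.
#' @export
morph_standin <- function(soma, dendrites, seg_len = 20) {
  stopifnot(all(soma > 0), all(dendrites$len > 0), all(dendrites$diam > 0),
            seg_len > 0, seg_len <= 20)
  dendrites$nseg <- pmax(1L, as.integer(ceiling(dendrites$len / seg_len)))
  area <- pi * soma[["diam"]] * soma[["len"]] +
    sum(pi * dendrites$diam * dendrites$len)
  structure(list(soma = c(diam = soma[["diam"]], len = soma[["len"]]),
                 dendrites = dendrites, seg_len = seg_len,
                 total_area_um2 = area),
            class = "morph_standin")
}

#' @export
print.morph_standin <- function(x, ...) {
  cat(sprintf("<morphology> soma %g x %g um, %d dendrite(s), total area %.0f um^2\n",
              x$soma["diam"], x$soma["len"], nrow(x$dendrites),
              x$total_area_um2))
  invisible(x)
}

#' Default template morphology
#'
#' The template dimensions are calibrated so that the TOR whole-cell
#' voltage-clamp simulation yields an I_SA peak of roughly 683 pA at the
#' -40 mV step (the measured whole-cell amplitude).
#' @return `morph_standin`.
#' @export
template_morphology <- function() {
  tpl <- .morph_template
  morph_standin(
    soma = tpl$soma,
    dendrites = data.frame(len = rep(tpl$dend[["len"]], tpl$n_dend),
                           diam = rep(tpl$dend[["diam"]], tpl$n_dend)),
    seg_len = tpl$seg_len
  )
}

#' Generate a population of morphology stand-ins
#'
#' Draws `n` stand-ins whose soma and dendrite dimensions are jittered
#' uniformly within +/-20% of the template, emulating cell-to-cell size
#' variability of the reconstructed population.
#'
#' @param n number of morphologies (>= 1).
#' @param seed integer seed; the set is fully reproducible.
#' @return list of `morph_standin`.
#' @export
make_morphologies <- function(n, seed = 1) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tpl <- .morph_template
      j <- function(x) x * runif(length(x), 0.8, 1.2)
      morph_standin(
        soma = c(diam = j(tpl$soma[["diam"]]), len = j(tpl$soma[["len"]])),
        dendrites = data.frame(len = j(rep(tpl$dend[["len"]], tpl$n_dend)),
                               diam = j(rep(tpl$dend[["diam"]], tpl$n_dend))),
        seg_len = tpl$seg_len
      )
    })
  })
}

#' Read an SWC morphology file onto the stand-in representation
#'
#' Minimal SWC reader: soma samples (type 1) are collapsed into an equivalent
#' cylinder of the same surface area; each dendritic subtree (types 3/4) is
#' collapsed into one unbranched dendrite with its total path length and
#' mean diameter. Axon samples (type 2) are ignored.
#'
#' @param path SWC file path.
#' @return `morph_standin`.
#' @export
read_swc <- function(path) {
  sw <- read.table(path, comment.char = "#",
                   col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  soma <- sw[sw$type == 1, , drop = FALSE]
  if (nrow(soma) == 0) stop("no soma samples (type 1) in ", path)
  rs <- mean(soma$r)
  # equivalent cylinder with diam = len preserving a sphere's surface area
  deq <- sqrt(4 * rs^2)  # pi d L = 4 pi r^2 with L = d
  dend <- sw[sw$type %in% c(3, 4), , drop = FALSE]
  if (nrow(dend) == 0) stop("no dendrite samples (type 3/4) in ", path)
  idx <- setNames(seq_len(nrow(sw)), sw$id)
  seglen <- vapply(seq_len(nrow(dend)), function(i) {
    p <- dend$parent[i]
    if (p < 0 || !as.character(p) %in% names(idx)) return(0)
    pp <- sw[idx[[as.character(p)]], ]
    sqrt((dend$x[i] - pp$x)^2 + (dend$y[i] - pp$y)^2 + (dend$z[i] - pp$z)^2)
  }, numeric(1))
  # root dendritic samples (children of soma) define subtrees
  roots <- dend$id[sw$type[idx[as.character(dend$parent)]] == 1]
  nsub <- max(1L, length(roots))
  total_len <- sum(seglen)
  morph_standin(
    soma = c(diam = deq, len = deq),
    dendrites = data.frame(len = rep(total_len / nsub, nsub),
                           diam = rep(2 * mean(dend$r), nsub))
  )
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
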