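#' Boltzmann voltage dependence
#'
#' Two-state Boltzmann function used throughout voltage-clamp
#' electrophysiology for steady-state activation and inactivation curves.
#' For `direction = "act"` the returned fraction increases with voltage,
#' for `direction = "inact"` it decreases:
#' \deqn{f(V) = \frac{1}{1 + e^{\mp (V - V_{1/2})/k}}}
#'
#' @param v membrane voltage (mV); vectorised.
#' @param v_half half-activation (or half-inactivation) voltage (mV).
#' @param k slope factor (mV), strictly positive.
#' @param direction `"act"` (increasing) or `"inact"` (decreasing).
#' @return fraction in `[0, 1]`, same length as `v`.
#' @examples
#' boltzmann(-64.5, -64.5, 6.6, "inact")   # 0.5 at the midpoint
#' boltzmann(-80, -64.5, 6.594, "inact")   # ~0.913 available at -80 mV
#' @export
boltzmann <- function(v, v_half, k, direction = c("act", "inact")) {
  direction <- match.arg(direction)
  if (!all(is.finite(v))) stop("non-finite voltage in `v`")
  if (!is.finite(v_half) || !is.finite(k)) stop("non-finite Boltzmann parameter")
  if (k <= 0) stop("slope factor `k` must be > 0")
  s <- if (direction == "act") -1 else 1
  1 / (1 + exp(s * (v - v_half) / k))
}

#' Solve a Boltzmann slope factor from one anchor point
#'
#' Given a midpoint voltage and one additional (voltage, fraction) point on
#' the curve, inverts the Boltzmann to obtain the slope factor `k`. This is
#' how slope factors are recovered when only a midpoint and a single
#' availability/activation percentage are reported.
#'
#' @param v_half midpoint voltage (mV).
#' @param anchor_v voltage of the anchor point (mV).
#' @param anchor_f fraction at the anchor, strictly in (0, 1) and != 0.5
#'   (unless `anchor_v == v_half`, which leaves `k` undetermined).
#' @param direction `"act"` or `"inact"` (see [boltzmann()]).
#' @param default_k returned when the anchor sits exactly at the midpoint.
#' @return slope factor `k` (mV, > 0) such that
#'   `boltzmann(anchor_v, v_half, k, direction)` equals `anchor_f`.
#' @examples
#' calibrate_from_anchors(-64.5, -80, 0.913, "inact")  # ~6.59 mV
#' @export
calibrate_from_anchors <- function(v_half, anchor_v, anchor_f,
                                   direction = c("act", "inact"),
                                   default_k = 6.6) {
  direction <- match.arg(direction)
  if (!is.finite(anchor_f) || anchor_f <= 0 || anchor_f >= 1)
    stop("anchor fraction must lie strictly in (0, 1)")
  if (abs(anchor_v - v_half) < 1e-12) {
    if (abs(anchor_f - 0.5) > 1e-9)
      stop("anchor at the midpoint must have fraction 0.5")
    return(default_k)
  }
  if (abs(anchor_f - 0.5) < 1e-12)
    stop("fraction 0.5 away from the midpoint has no Boltzmann solution")
  s <- if (direction == "act") -1 else 1
  k <- s * (anchor_v - v_half) / log(1 / anchor_f - 1)
  if (k <= 0)
    stop("anchor is on the wrong side of the midpoint for direction '",
         direction, "'")
  k
}

#' Fit a Boltzmann curve to points
#'
#' Least-squares fit of `amp / (1 + exp(s (v - v_half)/k))` with
#' Levenberg-Marquardt. Used for simulated steady-state inactivation /
#' activation curves and for membrane-potential dependence of firing.
#'
#' @param v voltages (mV).
#' @param y observed fractions (need not be normalised).
#' @param direction `"act"` or `"inact"`.
#' @param fix_amp if `TRUE`, amplitude fixed at 1.
#' @return object of class `boltzmann_fit` with elements `v_half`, `k`,
#'   `amplitude`, `r_squared`, `direction`.
#' @export
fit_boltzmann <- function(v, y, direction = c("act", "inact"),
                          fix_amp = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(v) == length(y), length(v) >= 4)
  s <- if (direction == "act") -1 else 1
  amp0 <- max(abs(y))
  if (amp0 <= 0) amp0 <- 1
  # crude midpoint/slope start from the half-amplitude crossing
  yn <- y / amp0
  ord <- order(v)
  vh0 <- tryCatch(approx(yn[ord], v[ord], xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(vh0)) vh0 <- stats::median(v)
  k0 <- max(diff(range(v)) / 10, 1)
  fn <- if (fix_amp) {
    function(p) p[3] * 0 + 1 / (1 + exp(s * (v - p[1]) / p[2])) - y
  } else {
    function(p) p[3] / (1 + exp(s * (v - p[1]) / p[2])) - y
  }
  fit <- minpack.lm::nls.lm(
    par = c(vh0, k0, amp0), fn = fn,
    lower = c(-150, 1e-3, 1e-6), upper = c(100, 100, 10 * amp0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  res <- fn(p)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(
    list(v_half = p[1], k = p[2], amplitude = if (fix_amp) 1 else p[3],
         r_squared = max(0, min(1, r2)), direction = direction),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit (%s): V1/2 = %.2f mV, k = %.2f mV, amp = %.3f, R^2 = %.4f\n",
              x$direction, x$v_half, x$k, x$amplitude, x$r_squared))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(v_half = object$v_half, k = object$k, amplitude = object$amplitude)
}

#' @export
predict.boltzmann_fit <- function(object, newdata, ...) {
  v <- if (is.list(newdata)) newdata$v else newdata
  object$amplitude * boltzmann(v, object$v_half, object$k, object$direction)
}

#' Fit one- or two-component exponential decay/recovery
#'
#' Fits `y = c0 + a1 exp(-x/tau1) (+ a2 exp(-x/tau2))` by
#' Levenberg-Marquardt least squares, with log-linear initialisation.
#' Amplitudes may be negative (recovery time courses rise).
#'
#' @param x ordinate (ms), length >= 5.
#' @param y observed values.
#' @param n_components 1 or 2.
#' @return object of class `exp_fit` with `tau` (ms, sorted ascending for two
#'   components), `amplitude`, `offset`, `r_squared`, `converged`.
#' @examples
#' x <- seq(0, 200, by = 5)
#' fit_exponential(x, 3 * exp(-x / 30))$tau  # 30
#' @export
fit_exponential <- function(x, y, n_components = 1) {
  stopifnot(length(x) == length(y), length(x) >= 5,
            n_components %in% c(1, 2))
  rng <- diff(range(x))
  c0 <- y[which.max(x)]
  a0 <- y[which.min(x)] - c0
  # log-linear slope estimate for the dominant component
  z <- y - c0
  usable <- which(sign(z) == sign(a0) & abs(z) > 1e-12 * max(abs(z), 1e-300))
  tau0 <- if (length(usable) >= 3) {
    sl <- stats::coef(lm(log(abs(z[usable])) ~ x[usable]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else rng / 3
  } else rng / 3
  tau0 <- min(max(tau0, rng / 50), rng * 3)

  if (n_components == 1) {
    fn <- function(p) p[1] + p[2] * exp(-x / p[3]) - y
    fit <- minpack.lm::nls.lm(par = c(c0, a0, tau0), fn = fn,
                              lower = c(-Inf, -Inf, 1e-6),
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- fit$par
    tau <- p[3]; amp <- p[2]; off <- p[1]
  } else {
    fn <- function(p) p[1] + p[2] * exp(-x / p[3]) + p[4] * exp(-x / p[5]) - y
    fit <- minpack.lm::nls.lm(par = c(c0, a0 * 0.6, tau0 / 5, a0 * 0.4, tau0 * 2),
                              fn = fn,
                              lower = c(-Inf, -Inf, 1e-6, -Inf, 1e-6),
                              control = minpack.lm::nls.lm.control(maxiter = 500))
    p <- fit$par
    ord <- order(c(p[3], p[5]))
    tau <- c(p[3], p[5])[ord]; amp <- c(p[2], p[4])[ord]; off <- p[1]
  }
  res <- fn(p)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(
    list(tau = unname(tau), amplitude = unname(amp), offset = unname(off),
         r_squared = max(0, min(1, r2)),
         converged = fit$info %in% 1:4),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: tau = %s ms, R^2 = %.4f%s\n",
              paste(sprintf("%.3g", x$tau), collapse = ", "), x$r_squared,
              if (x$converged) "" else " (did not converge)"))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(setNames(object$tau, paste0("tau", seq_along(object$tau))),
    setNames(object$amplitude, paste0("a", seq_along(object$amplitude))),
    offset = object$offset)
}
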