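#' Canonical pupil response waveform
#'
#' The pupillary light reflex trace is modelled as the sum of two logistic
#' sigmoids: a downward constriction step and an upward re-dilation step,
#'
#' \deqn{D(t) = b - a_1 \sigma((t - t_1)/s_1) + a_2 \sigma((t - t_2)/s_2)}
#'
#' with \eqn{\sigma(x) = 1/(1 + e^{-x})}. `b` is the pre-flash asymptotic
#' diameter, `a1`/`t1`/`s1` the constriction amplitude, midpoint and time
#' scale, and `a2`/`t2`/`s2` the re-dilation counterparts. Physiological
#' constraints: `s1, s2 > 0`, `t2 > t1`, `0 <= a2 <= a1`, `b > 0` and
#' `b - a1 > 0` (the pupil never closes or overshoots its baseline). The
#' limits are \eqn{D(-\infty) = b} and \eqn{D(+\infty) = b - a_1 + a_2},
#' the final asymptotic size after re-dilation.
#'
#' @param b pre-flash asymptotic diameter (mm).
#' @param a1 constriction sigmoid amplitude (mm).
#' @param t1 constriction midpoint time (s).
#' @param s1 constriction time scale (s).
#' @param a2 re-dilation sigmoid amplitude (mm).
#' @param t2 re-dilation midpoint time (s).
#' @param s2 re-dilation time scale (s).
#' @param rmse optional residual RMSE of a fit that produced the parameters.
#' @return An object of class `"plr_waveform"`: a named list of the seven
#'   parameters (plus `rmse`), validated against the constraints above.
#' @export
plr_waveform <- function(b, a1, t1, s1, a2, t2, s2, rmse = NA_real_) {
  p <- c(b = b, a1 = a1, t1 = t1, s1 = s1, a2 = a2, t2 = t2, s2 = s2)
  if (any(!is.finite(p)))
    stop("plr_waveform: non-finite parameter", call. = FALSE)
  if (s1 <= 0 || s2 <= 0)
    stop("plr_waveform: time scales s1, s2 must be > 0", call. = FALSE)
  if (t2 <= t1)
    stop("plr_waveform: re-dilation midpoint t2 must exceed t1", call. = FALSE)
  if (a1 < 0 || a2 < 0 || a2 > a1 + 1e-12)
    stop("plr_waveform: amplitudes must satisfy 0 <= a2 <= a1", call. = FALSE)
  if (b <= 0 || b - a1 <= 0)
    stop("plr_waveform: b and b - a1 must be > 0 (pupil cannot close)",
         call. = FALSE)
  structure(as.list(c(p, rmse = rmse)), class = "plr_waveform")
}

wf_pars <- function(fit) {
  if (inherits(fit, "plr_fit")) fit <- fit$waveform
  unlist(fit[c("b", "a1", "t1", "s1", "a2", "t2", "s2")])
}

#' Evaluate the canonical waveform
#'
#' @param fit a [plr_waveform()] or [plr_fit()] object.
#' @param times numeric vector of time points (s).
#' @return Pupil diameters (mm) at `times`.
#' @export
plr_eval <- function(fit, times) {
  p <- wf_pars(fit)
  if (any(!is.finite(p))) stop("plr_eval: invalid model", call. = FALSE)
  p[["b"]] -
    p[["a1"]] * stats::plogis((times - p[["t1"]]) / p[["s1"]]) +
    p[["a2"]] * stats::plogis((times - p[["t2"]]) / p[["s2"]])
}

#' Analytic first derivative of the canonical waveform
#'
#' The derivative of each logistic term \eqn{a\,\sigma((t-t_0)/s)} is
#' \eqn{(a/s)\,\sigma'((t-t_0)/s)} with \eqn{\sigma' = \sigma(1-\sigma)},
#' so for well-separated sigmoids the extreme velocities are approximately
#' \eqn{-a_1/(4 s_1)} (maximum constriction velocity, at `t1`) and
#' \eqn{a_2/(4 s_2)} (peak dilation velocity, at `t2`).
#'
#' @inheritParams plr_eval
#' @return Rate of diameter change (mm/s) at `times`.
#' @export
plr_deriv <- function(fit, times) {
  p <- wf_pars(fit)
  if (any(!is.finite(p))) stop("plr_deriv: invalid model", call. = FALSE)
  s1 <- stats::plogis((times - p[["t1"]]) / p[["s1"]])
  s2 <- stats::plogis((times - p[["t2"]]) / p[["s2"]])
  -p[["a1"]] / p[["s1"]] * s1 * (1 - s1) +
    p[["a2"]] / p[["s2"]] * s2 * (1 - s2)
}

## Objective: penalised SSE. The linear constraint b - a1 > 0 cannot be
## expressed as a box bound, so it enters as a quadratic penalty.
wf_sse <- function(theta, t, d) {
  b <- theta[1]; a1 <- theta[2]; t1 <- theta[3]; s1 <- theta[4]
  dt <- theta[5]; r <- theta[6]; s2 <- theta[7]
  a2 <- r * a1
  pred <- b - a1 * stats::plogis((t - t1) / s1) +
    a2 * stats::plogis((t - (t1 + dt)) / s2)
  sse <- sum((d - pred)^2)
  gap <- 0.05 - (b - a1)
  if (gap > 0) sse <- sse + 1e6 * gap^2
  sse
}

wf_sse_grad <- function(theta, t, d) {
  b <- theta[1]; a1 <- theta[2]; t1 <- theta[3]; s1 <- theta[4]
  dt <- theta[5]; r <- theta[6]; s2 <- theta[7]
  a2 <- r * a1
  u1 <- (t - t1) / s1; u2 <- (t - (t1 + dt)) / s2
  sg1 <- stats::plogis(u1); sg2 <- stats::plogis(u2)
  d1 <- sg1 * (1 - sg1); d2 <- sg2 * (1 - sg2)
  pred <- b - a1 * sg1 + a2 * sg2
  res <- d - pred
  dp <- cbind(b = 1,
              a1 = -sg1 + r * sg2,
              t1 = a1 * d1 / s1 - a2 * d2 / s2,
              s1 = a1 * d1 * u1 / s1,
              dt = -a2 * d2 / s2,
              r = a1 * sg2,
              s2 = -a2 * d2 * u2 / s2)
  g <- -2 * colSums(res * dp)
  gap <- 0.05 - (b - a1)
  if (gap > 0) {
    g[1] <- g[1] - 2e6 * gap
    g[2] <- g[2] + 2e6 * gap
  }
  g
}

#' Fit the canonical waveform to a pupillogram
#'
#' Constrained nonlinear least squares by box-bounded quasi-Newton
#' (`optim`, L-BFGS-B) from a deterministic multistart grid over the
#' constriction midpoint and time scale, so identical input always yields
#' an identical fit. Amplitude constraints (`0 <= a2 <= a1`,
#' `b - a1 > 0`) are honoured via the parameterisation `a2 = r * a1`,
#' `r` in `[0, 1]`, and a penalty on pupil closure. Fits that finish on a
#' parameter bound are flagged (`boundary = TRUE`) but not rejected.
#'
#' @param rec a [pupillogram()]. Must have at least 30 samples, cover some
#'   pre-flash baseline and extend at least 2 s past flash onset.
#' @param t1_grid,s1_grid multistart grids for the constriction midpoint
#'   (relative to flash onset, s) and time scale (s).
#' @return An object of class `"plr_fit"` with components `waveform`
#'   (a [plr_waveform()]), `rmse`, `fitted`, `data`, `boundary` and
#'   `convergence`.
#' @examples
#' truth <- plr_waveform(b = 6, a1 = 2, t1 = 1.5, s1 = 0.1,
#'                       a2 = 1, t2 = 3, s2 = 0.3)
#' tt <- seq(0, 5, by = 1 / 60)
#' rec <- pupillogram(tt, plr_eval(truth, tt), flash_onset = 1)
#' coef(plr_fit(rec))
#' @export
plr_fit <- function(rec, t1_grid = c(0.2, 0.5, 0.9), s1_grid = c(0.08, 0.25)) {
  stopifnot(inherits(rec, "pupillogram"))
  t <- rec$t; d <- rec$d; onset <- rec$flash_onset
  if (length(t) < 30)
    stop("plr_fit: need at least 30 samples", call. = FALSE)
  if (t[1] >= onset || t[length(t)] - onset < 2)
    stop("plr_fit: recording must span pre-flash baseline and >= 2 s post-flash",
         call. = FALSE)

  b0 <- mean(d[t <= onset])
  a10 <- max(b0 - min(d), 0)
  dspan <- max(max(d) - min(d), 0.05)

  lower <- c(b = 0.3, a1 = 0, t1 = onset, s1 = 0.02, dt = 0.05, r = 0,
             s2 = 0.05)
  upper <- c(b = 12, a1 = 11, t1 = onset + 1.5, s1 = 0.5, dt = 4, r = 1,
             s2 = 1.5)

  best <- NULL
  for (dt1 in t1_grid) for (s1s in s1_grid) {
    start <- c(b = min(max(b0, lower[["b"]]), upper[["b"]]),
               a1 = min(a10, upper[["a1"]]),
               t1 = onset + dt1, s1 = s1s, dt = 1.5, r = 0.5, s2 = 0.3)
    opt <- try(stats::optim(start, wf_sse, wf_sse_grad, t = t, d = d,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 400)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("plr_fit: optimisation failed for all starts (fit-failure)",
         call. = FALSE)

  th <- best$par
  ## A degenerate flat fit can park t1 anywhere; normalise a1 ~ 0 fits.
  a1 <- th[["a1"]]; a2 <- th[["r"]] * th[["a1"]]
  wf <- plr_waveform(b = th[["b"]], a1 = a1, t1 = th[["t1"]], s1 = th[["s1"]],
                     a2 = a2, t2 = th[["t1"]] + th[["dt"]], s2 = th[["s2"]])
  fitted <- plr_eval(wf, t)
  rmse <- sqrt(mean((d - fitted)^2))
  wf$rmse <- rmse

  at_bound <- any(abs(th - lower) < 1e-8 & names(th) != "r" & names(th) != "a1") ||
    any(abs(th - upper) < 1e-8)
  structure(list(waveform = wf, rmse = rmse, fitted = fitted, data = rec,
                 boundary = at_bound, convergence = best$convergence,
                 sse = best$value),
            class = "plr_fit")
}

#' @export
coef.plr_fit <- function(object, ...) wf_pars(object)

#' @export
print.plr_fit <- function(x, ...) {
  cat("Canonical PLR waveform fit\n")
  print(round(wf_pars(x), 4))
  cat(sprintf("RMSE %.4f mm%s\n", x$rmse,
              if (isTRUE(x$boundary)) " (parameter at bound)" else ""))
  invisible(x)
}

#' @export
predict.plr_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  plr_eval(object, times)
}

#' @export
residuals.plr_fit <- function(object, ...) object$data$d - object$fitted

#' @export
fitted.plr_fit <- function(object, ...) object$fitted

#' @export
summary.plr_fit <- function(object, ...) {
  pars <- plr_parameters(object$data, object)
  out <- list(fit = object, parameters = pars)
  class(out) <- "summary.plr_fit"
  out
}

#' @export
print.summary.plr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nExtracted PLR parameters:\n")
  print(x$parameters)
  invisible(x)
}

#' @export
plot.plr_fit <- function(x, ...) {
  plot(x$data, ...)
  graphics::lines(x$data$t, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}

#' Simulate traces from a fitted waveform
#'
#' Draws `nsim` noisy replicates of the fitted curve at the original time
#' points, with i.i.d. Gaussian measurement noise.
#'
#' @param object a `"plr_fit"`.
#' @param nsim number of replicate traces.
#' @param seed optional RNG seed.
#' @param noise_sd measurement noise standard deviation (mm); defaults to
#'   the fit RMSE.
#' @param ... unused.
#' @return A matrix with one column per replicate.
#' @export
simulate.plr_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = object$rmse, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  matrix(object$fitted + stats::rnorm(n * nsim, sd = noise_sd), ncol = nsim)
}
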