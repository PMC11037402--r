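#' Extract the standard PLR parameters from a fitted recording
#'
#' Computes the eight standard pupillary-light-reflex metrics:
#' \describe{
#'   \item{INIT}{baseline diameter: mean of samples over the first 250 ms
#'     of the recording (mm).}
#'   \item{END}{minimum diameter: median of the samples inside a 130 ms
#'     window centred on the post-flash minimum, searched within the first
#'     1.5 s after flash onset (mm).}
#'   \item{FIN}{asymptotic final size after re-dilation,
#'     `b - a1 + a2` (mm).}
#'   \item{CAMP}{constriction amplitude, `INIT - END` (mm).}
#'   \item{MCV}{maximum constriction velocity: minimum of the first
#'     derivative during the constriction phase (mm/s, signed, <= 0).}
#'   \item{PDV}{peak dilation velocity: maximum of the first derivative
#'     during re-dilation (mm/s, >= 0).}
#'   \item{LAT}{constriction latency: interval from flash onset to the
#'     commencement of constriction, operationalised as the time at which
#'     the constriction sigmoid has covered `latency_threshold` (default
#'     1%) of its amplitude, i.e. `t1 + s1 * log(p/(1-p)) - flash_onset`.}
#'   \item{T75}{recovery time: time after the trough for the diameter to
#'     regain 75% of CAMP; flagged unreached when the fitted asymptote
#'     never attains the threshold.}
#' }
#' INIT and END come from the raw samples; velocities and recovery use the
#' fitted model's analytic derivative for noise robustness (set
#' `velocity = "raw"` for finite differences of the raw trace).
#'
#' @param rec the [pupillogram()] the fit was obtained from.
#' @param fit the corresponding [plr_fit()] (or [plr_waveform()]).
#' @param latency_threshold fraction of `a1` defining constriction onset.
#' @param velocity `"model"` (analytic derivative of the fit) or `"raw"`
#'   (finite differences of the measured trace).
#' @return An object of class `"plr_params"`: the eight parameters plus
#'   `trough_time` and the flags `non_constricting` and `t75_unreached`.
#' @export
plr_parameters <- function(rec, fit, latency_threshold = 0.01,
                           velocity = c("model", "raw")) {
  stopifnot(inherits(rec, "pupillogram"))
  velocity <- match.arg(velocity)
  p <- wf_pars(fit)
  t <- rec$t; d <- rec$d; onset <- rec$flash_onset
  t0 <- t[1]

  init <- mean(d[t <= t0 + 0.25])

  ## trough search: raw minimum within 1.5 s post flash onset
  in_win <- t > onset & t <= onset + 1.5
  non_constricting <- FALSE
  if (!any(in_win)) {
    non_constricting <- TRUE
    end <- init
    trough_t <- onset
  } else {
    i_min <- which(in_win)[which.min(d[in_win])]
    trough_t <- t[i_min]
    end <- stats::median(d[abs(t - trough_t) <= 0.065])
    if (end >= init) {
      non_constricting <- TRUE
      end <- init
    }
  }
  camp <- init - end

  fin <- p[["b"]] - p[["a1"]] + p[["a2"]]

  ## model trough: zero crossing of the analytic derivative in (t1, t2)
  trough_m <- model_trough(p, t)

  if (velocity == "model") {
    if (p[["a1"]] <= 1e-12 && p[["a2"]] <= 1e-12) {
      mcv <- 0; pdv <- 0
    } else {
      mcv <- min(0, stats::optimize(function(u) plr_deriv(fit, u),
                                    c(t[1], trough_m))$objective)
      pdv <- if (p[["a2"]] <= 1e-12) 0 else
        max(0, stats::optimize(function(u) plr_deriv(fit, u),
                               c(trough_m, t[length(t)]),
                               maximum = TRUE)$objective)
    }
  } else {
    dd <- diff(d) / diff(t)
    tm <- (t[-1] + t[-length(t)]) / 2
    mcv <- min(0, dd[tm <= trough_m])
    pdv <- max(0, dd[tm > trough_m], na.rm = TRUE)
  }

  lat <- (p[["t1"]] + p[["s1"]] *
            log(latency_threshold / (1 - latency_threshold))) - onset

  ## T75 recovery from the fitted curve
  t75 <- NA_real_
  t75_unreached <- TRUE
  thr <- end + 0.75 * camp
  if (!non_constricting && camp > 0 && fin >= thr) {
    hi <- max(t[length(t)], p[["t2"]] + 60 * p[["s2"]])
    f <- function(u) plr_eval(fit, u) - thr
    if (f(trough_m) <= 0 && f(hi) >= 0) {
      t_cross <- stats::uniroot(f, c(trough_m, hi), tol = 1e-9)$root
      t75 <- t_cross - trough_m
      t75_unreached <- FALSE
    } else if (f(trough_m) > 0) {
      ## fitted curve already above threshold at the trough
      t75 <- 0
      t75_unreached <- FALSE
    }
  }

  structure(list(init = init, end = end, fin = fin, camp = camp,
                 mcv = mcv, pdv = pdv, lat = lat, t75 = t75,
                 trough_time = trough_m,
                 non_constricting = non_constricting,
                 t75_unreached = t75_unreached),
            class = "plr_params")
}

## Location of the fitted-model minimum between the two sigmoid midpoints.
model_trough <- function(p, t) {
  if (p[["a1"]] <= 1e-12) return(p[["t1"]])
  if (p[["a2"]] <= 1e-12) return(t[length(t)])
  f <- function(u) {
    s1 <- stats::plogis((u - p[["t1"]]) / p[["s1"]])
    s2 <- stats::plogis((u - p[["t2"]]) / p[["s2"]])
    -p[["a1"]] / p[["s1"]] * s1 * (1 - s1) +
      p[["a2"]] / p[["s2"]] * s2 * (1 - s2)
  }
  lo <- p[["t1"]]; hi <- p[["t2"]]
  if (f(lo) < 0 && f(hi) > 0)
    return(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
  ## overlapping sigmoids: fall back to a dense grid minimum of the curve
  grid <- seq(t[1], max(t[length(t)], hi), length.out = 2000)
  wf <- structure(as.list(p), class = "plr_waveform")
  grid[which.min(plr_eval(wf, grid))]
}

#' @export
print.plr_params <- function(x, ...) {
  v <- unlist(x[c("init", "end", "fin", "camp", "mcv", "pdv", "lat", "t75")])
  names(v) <- toupper(names(v))
  print(round(v, 4))
  if (x$non_constricting) cat("flag: non-constricting recording\n")
  if (x$t75_unreached) cat("flag: 75% recovery not reached\n")
  invisible(x)
}

#' @export
as.data.frame.plr_params <- function(x, ...) {
  data.frame(init = x$init, end = x$end, fin = x$fin, camp = x$camp,
             mcv = x$mcv, pdv = x$pdv, lat = x$lat, t75 = x$t75,
             non_constricting = x$non_constricting,
             t75_unreached = x$t75_unreached)
}

#' Absolute-velocity accessors
#'
#' Velocities are stored signed (MCV <= 0 <= PDV); these return magnitudes.
#' @param x a `"plr_params"` object.
#' @return Absolute velocity in mm/s.
#' @export
abs_mcv <- function(x) abs(x$mcv)

#' @rdname abs_mcv
#' @export
abs_pdv <- function(x) abs(x$pdv)
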