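#' Construct a pupillogram
#'
#' A pupillogram is a single pupil-diameter trace recorded around a light
#' flash: time points in seconds, diameters in millimetres, and the flash
#' timing. The standard recording protocol is 5 s at a nominal 60 Hz with
#' 1 s of pre-stimulus baseline, a 1 s flash, and 3 s of recovery.
#'
#' @param t numeric vector of time points (s), strictly increasing.
#' @param d numeric vector of pupil diameters (mm), finite and positive,
#'   same length as `t`.
#' @param recording_id identifier for the recording.
#' @param flash_onset flash onset time (s); must lie within `range(t)`.
#' @param flash_duration flash duration (s), default 1.
#' @param sample_rate_nominal nominal sampling rate (Hz), default 60.
#' @param subject_id optional subject identifier.
#' @return An object of class `"pupillogram"`.
#' @export
pupillogram <- function(t, d, recording_id = "rec", flash_onset = 1,
                        flash_duration = 1, sample_rate_nominal = 60,
                        subject_id = NA_character_) {
  t <- as.numeric(t)
  d <- as.numeric(d)
  if (length(t) != length(d))
    stop("pupillogram: t and d must have the same length", call. = FALSE)
  if (any(!is.finite(t)))
    stop("pupillogram: non-finite time points", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("pupillogram: t must be strictly increasing", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("pupillogram: all diameters must be finite and > 0", call. = FALSE)
  if (flash_onset < t[1] || flash_onset > t[length(t)])
    stop("pupillogram: flash_onset outside the recorded time range",
         call. = FALSE)
  structure(
    list(recording_id = as.character(recording_id),
         subject_id = as.character(subject_id),
         t = t, d = d,
         flash_onset = as.numeric(flash_onset),
         flash_duration = as.numeric(flash_duration),
         sample_rate_nominal = as.numeric(sample_rate_nominal)),
    class = "pupillogram")
}

#' @export
print.pupillogram <- function(x, ...) {
  cat(sprintf("Pupillogram '%s': %d samples, %.2f-%.2f s, flash at %.2f s (%.0f ms)\n",
              x$recording_id, length(x$t), x$t[1], x$t[length(x$t)],
              x$flash_onset, 1000 * x$flash_duration))
  cat(sprintf("  diameter range %.2f-%.2f mm\n", min(x$d), max(x$d)))
  invisible(x)
}

#' @export
as.data.frame.pupillogram <- function(x, ...) {
  data.frame(recording_id = x$recording_id, subject_id = x$subject_id,
             t_s = x$t, diameter_mm = x$d, stringsAsFactors = FALSE)
}

#' @export
plot.pupillogram <- function(x, ...) {
  graphics::plot(x$t, x$d, type = "l", xlab = "time (s)",
                 ylab = "pupil diameter (mm)",
                 main = x$recording_id, ...)
  graphics::rect(x$flash_onset, graphics::par("usr")[3],
                 x$flash_onset + x$flash_duration, graphics::par("usr")[4],
                 col = grDevices::adjustcolor("gold", 0.2), border = NA)
  invisible(x)
}
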