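## Deterministic substream seeding: every random draw in a simulated study
## flows from the master seed through a named substream, so identical
## configurations always reproduce identical datasets.
substream_seed <- function(master, ...) {
  label <- paste(c(...), collapse = "/")
  m <- 2147483563
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer(h) + 1L
}

#' Synthetic subject profile
#'
#' Describes one simulated subject's pupil physiology: the dark-adapted
#' diameter `d_max`, bright-light floor `d_min`, the half-constriction
#' illuminance `L_half` and sensitivity exponent `h` of the
#' luminance-response curve, the flash-response gain `amp_gain`, sigmoid
#' time scales `s1`/`s2`, latency offset, and measurement noise.
#'
#' @param d_max dark-adapted diameter (mm).
#' @param d_min bright-light floor (mm).
#' @param L_half illuminance of half-maximal constriction (lx).
#' @param h luminance sensitivity exponent.
#' @param amp_gain flash-response gain in (0, 1].
#' @param s1,s2 constriction / re-dilation time scales (s).
#' @param latency_offset constriction midpoint delay after flash onset (s).
#' @param noise_sd per-frame measurement noise (mm).
#' @return Object of class `"subject_profile"`.
#' @export
subject_profile <- function(d_max = 7, d_min = 2.5, L_half = 60, h = 0.7,
                            amp_gain = 0.45, s1 = 0.09, s2 = 0.32,
                            latency_offset = 0.55, noise_sd = 0.05) {
  stopifnot(d_max > d_min, d_min > 0, L_half > 0, h > 0,
            amp_gain > 0, amp_gain <= 1, s1 > 0, s2 > 0, noise_sd >= 0)
  structure(list(d_max = d_max, d_min = d_min, L_half = L_half, h = h,
                 amp_gain = amp_gain, s1 = s1, s2 = s2,
                 latency_offset = latency_offset, noise_sd = noise_sd),
            class = "subject_profile")
}

## Draw a subject from the population spread (used per cohort substream).
random_profile <- function(noise_sd = 0.05) {
  subject_profile(
    d_max = stats::runif(1, 6.2, 7.8),
    d_min = stats::runif(1, 2.1, 2.9),
    L_half = exp(stats::runif(1, log(30), log(120))),
    h = stats::runif(1, 0.5, 0.9),
    amp_gain = stats::runif(1, 0.35, 0.55),
    s1 = stats::runif(1, 0.07, 0.12),
    s2 = stats::runif(1, 0.26, 0.38),
    latency_offset = stats::runif(1, 0.5, 0.65),
    noise_sd = noise_sd)
}

#' Steady-state pupil diameter under ambient light
#'
#' Hill-type sigmoid in illuminance:
#' `d_min + (d_max - d_min) / (1 + (lux / L_half)^h)`, strictly decreasing
#' from `d_max` in darkness to `d_min` under very bright light.
#'
#' @param profile a [subject_profile()].
#' @param lux ambient illuminance (lx), `>= 0`.
#' @return Baseline diameter (mm).
#' @export
baseline_diameter <- function(profile, lux) {
  stopifnot(all(lux >= 0))
  profile$d_min + (profile$d_max - profile$d_min) /
    (1 + (lux / profile$L_half)^profile$h)
}

#' Camera exposure as a function of ambient light
#'
#' Firmware exposure is modelled as a saturating decreasing function of
#' illuminance, `E_max / (1 + lux / L_E)`, with optional multiplicative
#' log-normal jitter. Exposure units are opaque positive scalars.
#'
#' @param lux ambient illuminance (lx).
#' @param E_max exposure in darkness.
#' @param L_E illuminance halving the exposure (lx).
#' @param jitter_sd sd of the log-normal jitter (0 = deterministic).
#' @return Exposure value(s), > 0.
#' @export
exposure_from_lux <- function(lux, E_max = 1000, L_E = 50, jitter_sd = 0) {
  stopifnot(all(lux >= 0))
  e <- E_max / (1 + lux / L_E)
  if (jitter_sd > 0) e <- e * exp(stats::rnorm(length(e), 0, jitter_sd))
  e
}

#' Simulate a single pupillogram
#'
#' Builds the ground-truth canonical waveform for a subject under given
#' ambient light, evaluates it over the standard 5 s / 60 Hz recording
#' (1 s pre-flash, 1 s flash, 3 s recovery) and adds Gaussian frame noise.
#' The constriction amplitude is `amp_gain * (b - d_min)` scaled by the
#' drug multiplier `delta` (1 for an untreated eye, a small value such as
#' 0.02 for pharmacological mydriasis, which also pins the baseline near
#' the dark-adapted diameter — the "fixed dilated pupil"). Re-dilation
#' amplitude is 80% of the constriction amplitude. Kinetic parameters
#' (latency, time scales) drift mildly with the baseline diameter, so
#' every extracted parameter carries some lighting dependence.
#'
#' @param profile a [subject_profile()].
#' @param lux ambient illuminance (lx).
#' @param drug `"none"` or `"mydriatic"`.
#' @param seed RNG seed for the noise draw (`NULL` = current RNG state).
#' @param delta drug amplitude multiplier for the mydriatic state.
#' @param recording_id,subject_id identifiers stamped on the recording.
#' @param flash_onset flash onset (s); recordings run 0-5 s.
#' @param noise_sd overrides the profile's noise (mm) when non-`NULL`.
#' @return List with `rec` (a [pupillogram()]) and `truth`
#'   (the generating [plr_waveform()]).
#' @export
simulate_recording <- function(profile, lux, drug = c("none", "mydriatic"),
                               seed = NULL, delta = 0.02,
                               recording_id = "sim", subject_id = "S1",
                               flash_onset = 1, noise_sd = NULL) {
  drug <- match.arg(drug)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- profile$noise_sd

  b <- baseline_diameter(profile, lux)
  d_drug <- 1
  if (drug == "mydriatic") {
    ## fixed dilated pupil: baseline pinned near the dark-adapted size
    b <- profile$d_max - 0.02 * (profile$d_max - profile$d_min)
    d_drug <- delta
  }
  a1 <- profile$amp_gain * (b - profile$d_min) * d_drug
  a2 <- 0.8 * a1
  s1 <- profile$s1 * (1 + 0.05 * (b - 5))
  s2 <- profile$s2 * (1 + 0.05 * (b - 5))
  t1 <- flash_onset + profile$latency_offset + 0.06 * (b - 5)
  t2 <- t1 + 1.4 + 0.04 * (b - 5)
  truth <- plr_waveform(b = b, a1 = a1, t1 = t1, s1 = s1,
                        a2 = a2, t2 = t2, s2 = s2)
  tt <- seq(0, 5, by = 1 / 60)
  d <- plr_eval(truth, tt)
  if (noise_sd > 0) d <- d + stats::rnorm(length(d), 0, noise_sd)
  d <- pmax(d, 0.2)
  rec <- pupillogram(tt, d, recording_id = recording_id,
                     subject_id = subject_id, flash_onset = flash_onset,
                     flash_duration = 1, sample_rate_nominal = 60)
  list(rec = rec, truth = truth)
}

#' Cohort configuration for the synthetic studies
#'
#' Defaults mirror the laboratory lighting study (9 subjects, 8
#' illumination levels spanning darkness to ~10,000 lx, 5 repeats per
#' level) and the outpatient mydriasis study (15 patients, both eyes,
#' pre/post tropicamide under 12-120 lx clinic lighting).
#'
#' @param n_subjects number of subjects.
#' @param levels illuminance levels (lx), positive.
#' @param repeats recordings per subject per level, `>= 1`.
#' @param delta drug amplitude multiplier for mydriasis.
#' @param noise_sd per-frame measurement noise (mm).
#' @param dropout fraction of recordings randomly dropped (default 0).
#' @param seed master seed; all substreams derive from it.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 9,
                          levels = c(5, 16, 45, 112, 400, 1343, 4000, 10000),
                          repeats = 5, delta = 0.02, noise_sd = 0.05,
                          dropout = 0, seed = 1) {
  stopifnot(all(levels > 0), repeats >= 1, n_subjects >= 1,
            delta >= 0, delta <= 1, dropout >= 0, dropout < 1)
  structure(list(n_subjects = n_subjects, levels = levels,
                 repeats = repeats, delta = delta, noise_sd = noise_sd,
                 dropout = dropout, seed = seed),
            class = "cohort_config")
}

study_skeleton <- function() {
  structure(list(recordings = list(), truth = list(), meta = NULL),
            class = "plr_study")
}

#' Simulate the laboratory lighting study
#'
#' Generates `n_subjects x length(levels) x repeats` recordings (default
#' 360) with subject-level random physiology, lighting-dependent baselines
#' and amplitudes, exposure metadata, and ground-truth waveforms for
#' oracle scoring.
#'
#' @param config a [cohort_config()].
#' @return Object of class `"plr_study"`: `recordings` (named list of
#'   [pupillogram()]s), `truth` (data frame of generating parameters) and
#'   `meta` (recording metadata: subject, illuminance, exposure, drug
#'   state, eye, flash timing).
#' @export
simulate_lighting_study <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  study <- study_skeleton()
  meta <- list(); truth <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    set.seed(substream_seed(config$seed, "profile", sid))
    prof <- random_profile(noise_sd = config$noise_sd)
    for (lux in config$levels) for (r in seq_len(config$repeats)) {
      rid <- sprintf("%s_L%g_r%d", sid, lux, r)
      set.seed(substream_seed(config$seed, "exposure", rid))
      expo <- exposure_from_lux(lux, jitter_sd = 0.05)
      if (config$dropout > 0) {
        set.seed(substream_seed(config$seed, "dropout", rid))
        if (stats::runif(1) < config$dropout) next
      }
      sim <- simulate_recording(prof, lux, drug = "none",
                                seed = substream_seed(config$seed, "rec", rid),
                                recording_id = rid, subject_id = sid)
      study$recordings[[rid]] <- sim$rec
      truth[[rid]] <- data.frame(recording_id = rid,
                                 as.data.frame(unclass(sim$truth)[1:7]))
      meta[[rid]] <- data.frame(recording_id = rid, subject_id = sid,
                                illuminance_lux = lux, exposure = expo,
                                drug_state = "none", eye = "L",
                                flash_onset_s = 1, flash_duration_s = 1,
                                stringsAsFactors = FALSE)
    }
  }
  study$meta <- do.call(rbind, meta)
  study$truth <- do.call(rbind, truth)
  rownames(study$meta) <- rownames(study$truth) <- NULL
  study
}

#' Simulate the outpatient mydriasis study
#'
#' Each of `n_subjects` patients (default 15) contributes both eyes in a
#' reactive pre-drug state and an unreactive post-tropicamide state
#' (amplitude multiplier `delta`, baseline pinned near the dark-adapted
#' diameter), under clinic lighting drawn uniformly from 12-120 lx.
#'
#' @param config a [cohort_config()]; the relevant fields are
#'   `n_subjects`, `delta`, `noise_sd` and `seed`.
#' @param lux_range clinic illuminance range (lx).
#' @return A `"plr_study"` (see [simulate_lighting_study()]); `meta`
#'   carries `drug_state` `"pre"`/`"post"` and `eye` `"L"`/`"R"`.
#' @export
simulate_mydriasis_study <- function(config = cohort_config(n_subjects = 15),
                                     lux_range = c(12, 120)) {
  stopifnot(inherits(config, "cohort_config"))
  study <- study_skeleton()
  meta <- list(); truth <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("P%02d", i)
    set.seed(substream_seed(config$seed, "myd-profile", sid))
    prof <- random_profile(noise_sd = config$noise_sd)
    for (eye in c("L", "R")) for (state in c("pre", "post")) {
      rid <- sprintf("%s_%s_%s", sid, eye, state)
      set.seed(substream_seed(config$seed, "myd-lux", rid))
      lux <- stats::runif(1, lux_range[1], lux_range[2])
      expo <- exposure_from_lux(lux, jitter_sd = 0.05)
      sim <- simulate_recording(
        prof, lux, drug = if (state == "post") "mydriatic" else "none",
        seed = substream_seed(config$seed, "myd-rec", rid),
        delta = config$delta, recording_id = rid, subject_id = sid)
      study$recordings[[rid]] <- sim$rec
      truth[[rid]] <- data.frame(recording_id = rid,
                                 as.data.frame(unclass(sim$truth)[1:7]))
      meta[[rid]] <- data.frame(recording_id = rid, subject_id = sid,
                                illuminance_lux = lux, exposure = expo,
                                drug_state = state, eye = eye,
                                flash_onset_s = 1, flash_duration_s = 1,
                                stringsAsFactors = FALSE)
    }
  }
  study$meta <- do.call(rbind, meta)
  study$truth <- do.call(rbind, truth)
  rownames(study$meta) <- rownames(study$truth) <- NULL
  study
}

#' @export
print.plr_study <- function(x, ...) {
  cat(sprintf("Synthetic PLR study: %d recordings, %d subjects, %d lighting levels\n",
              length(x$recordings), length(unique(x$meta$subject_id)),
              length(unique(x$meta$illuminance_lux))))
  print(utils::head(x$meta, 4))
  invisible(x)
}

#' Fit and extract PLR parameters for every recording in a study
#'
#' Runs [plr_fit()] and [plr_parameters()] on each recording and joins the
#' results with the study metadata, yielding the analysis-ready parameter
#' table (one row per recording).
#'
#' @param study a `"plr_study"` or a list with `recordings` and `meta`.
#' @param ... passed to [plr_parameters()].
#' @return Data frame: metadata columns, the eight parameters, `rmse` and
#'   the extraction flags.
#' @export
study_parameters <- function(study, ...) {
  rows <- lapply(study$meta$recording_id, function(rid) {
    rec <- study$recordings[[rid]]
    fit <- plr_fit(rec)
    cbind(data.frame(recording_id = rid, stringsAsFactors = FALSE),
          as.data.frame(plr_parameters(rec, fit, ...)),
          rmse = fit$rmse)
  })
  params <- do.call(rbind, rows)
  merge(study$meta, params, by = "recording_id", sort = FALSE)
}
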