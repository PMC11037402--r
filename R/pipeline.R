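#' End-to-end reactivity pipeline on synthetic cohorts
#'
#' Runs the full analysis chain: simulate the laboratory lighting study,
#' fit the per-parameter lighting-correction models on it, simulate the
#' outpatient mydriasis cohort (subjects disjoint from the lighting
#' cohort, so the correction models never see the data they correct),
#' correct its parameters, compute raw PuRe scores with the published
#' coefficients, calibrate the piecewise 0-5 scaler on the cohort's
#' pre/post raw scores, and classify every recording at the scaled 3.0
#' (normal/abnormal) boundary.
#'
#' @param seed master seed driving both simulations.
#' @param alpha L1 penalty for the correction models.
#' @param lighting_config,mydriasis_config optional [cohort_config()]s
#'   overriding the defaults (which follow the two study designs).
#' @return List with `scores` (per-recording data frame: raw, scaled,
#'   class, drug state), `accuracy` (fraction correct at the 3.0
#'   boundary), `auc`, `scaler`, `correction_models` and the two parameter
#'   tables.
#' @export
pure_pipeline <- function(seed = 1, alpha = 0.006,
                          lighting_config = cohort_config(seed = seed),
                          mydriasis_config = cohort_config(n_subjects = 15,
                                                           seed = seed)) {
  light <- simulate_lighting_study(lighting_config)
  light_params <- study_parameters(light)
  models <- fit_plr_corrections(light_params, alpha = alpha)

  myd <- simulate_mydriasis_study(mydriasis_config)
  myd_params <- study_parameters(myd)
  corrected <- correct_plr(myd_params, models)

  model <- pure_model()
  raw <- pure_score(model, corrected)
  pre <- raw[corrected$drug_state == "pre"]
  post <- raw[corrected$drug_state == "post"]
  scaler <- fit_pure_scaler(pre, post)
  scaled <- scale_pure(scaler, raw)

  reactive <- corrected$drug_state == "pre"
  accuracy <- mean((scaled > 3) == reactive)
  auc <- evaluate_discrimination(raw[reactive], raw[!reactive])$auc

  list(scores = data.frame(recording_id = corrected$recording_id,
                           subject_id = corrected$subject_id,
                           drug_state = corrected$drug_state,
                           raw_score = raw, pure_score = scaled,
                           class = as.character(pure_class(scaled)),
                           stringsAsFactors = FALSE),
       accuracy = accuracy, auc = auc, scaler = scaler,
       correction_models = models,
       lighting_parameters = light_params,
       mydriasis_parameters = corrected)
}
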