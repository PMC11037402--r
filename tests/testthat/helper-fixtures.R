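# Shared fixtures, built in code. Expensive end-to-end objects are
# computed once per test run and memoised.

REF_WF <- function() plr_waveform(b = 6, a1 = 2, t1 = 1.5, s1 = 0.1,
                                  a2 = 1, t2 = 3, s2 = 0.3)

noiseless_rec <- function(wf = REF_WF(), flash_onset = 1,
                          t = seq(0, 5, by = 1 / 60), id = "ref") {
  pupillogram(t, plr_eval(wf, t), recording_id = id,
              flash_onset = flash_onset)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Full end-to-end pipeline at the default study conditions (shared by the
# score-stability and discrimination tests).
pipeline_fixture <- function(seed = 1) {
  cached(paste0("pipeline", seed), pure_pipeline(seed = seed))
}

# Lighting-study parameter table (shared by correction tests).
lighting_params_fixture <- function(seed = 1) {
  cached(paste0("lp", seed), {
    pipe <- pipeline_fixture(seed)
    pipe$lighting_parameters
  })
}

loso_fixture <- function(seed = 1) {
  cached(paste0("loso", seed),
         correct_plr_loso(lighting_params_fixture(seed)))
}

# Small deterministic parameter table where the response is a known
# function of baseline and exposure plus subject offsets.
toy_correction_data <- function(n_subj = 4, n_per = 30, seed = 99,
                                fun = function(B, E) 2 + 0.5 * log(E),
                                noise = 0.05, subj_sd = 0) {
  set.seed(seed)
  subj <- rep(sprintf("s%d", seq_len(n_subj)), each = n_per)
  B <- runif(n_subj * n_per, 2.5, 7.5)
  E <- exp(runif(n_subj * n_per, log(5), log(900)))
  offs <- rep(rnorm(n_subj, 0, subj_sd), each = n_per)
  y <- fun(B, E) + offs + rnorm(n_subj * n_per, 0, noise)
  data.frame(subject_id = subj, init = B, exposure = E, y = y)
}
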