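test_that("feature matrix columns equal their defining functions", {
  ## closed-form spot checks
  m1 <- build_feature_matrix(1, 1)
  expect_equal(unname(drop(m1)), c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 1, 0))
  m2 <- build_feature_matrix(exp(1), 1)
  expect_equal(unname(m2[, c("log(B)", "log(B)^2", "log(B)*log(E)")]),
               c(1, 1, 0))

  ## random inputs: element-wise recomputation per term
  set.seed(3)
  B <- runif(25, 0.5, 8); E <- exp(runif(25, 0, 7))
  X <- build_feature_matrix(B, E)
  oracle <- cbind(B, E, B^2, E^2, 1 / B, 1 / E, log(B), log(E),
                  log(B)^2, log(E)^2, B * E, log(B) * log(E))
  expect_equal(unname(X), unname(oracle))

  expect_error(build_feature_matrix(-1, 2), "baseline")
  expect_error(build_feature_matrix(2, 0), "exposure")
  expect_error(build_feature_matrix(2, 2, terms = "B^3"), "unknown")
})

test_that("BIC subset ranking matches brute-force enumeration on a 4-term pool", {
  pool <- c("log(E)", "B", "E^-1", "B*E")
  dat <- toy_correction_data(fun = function(B, E) 1 + 0.8 * log(E) - 0.3 * B)
  rank <- stepwise_bic_select(dat$init, dat$exposure, dat$y, terms = pool)
  expect_equal(length(rank$candidates), 16)

  ## independent oracle: lm() over all subsets with the BIC formula
  X <- build_feature_matrix(dat$init, dat$exposure, pool)
  n <- nrow(X)
  oracle <- lapply(0:15, function(mask) {
    sel <- pool[bitwAnd(mask, 2^(0:3)) > 0]
    rss <- if (length(sel))
      sum(residuals(lm(dat$y ~ X[, sel, drop = FALSE]))^2)
    else sum(residuals(lm(dat$y ~ 1))^2)
    list(terms = sel, bic = n * log(rss / n) + (length(sel) + 1) * log(n))
  })
  oracle <- oracle[order(vapply(oracle, `[[`, numeric(1), "bic"))]
  for (i in seq_len(16)) {
    expect_setequal(rank$candidates[[i]]$terms, oracle[[i]]$terms)
    expect_equal(rank$candidates[[i]]$bic, oracle[[i]]$bic, tolerance = 1e-9)
  }
  ## the data-generating term tops the ranking
  expect_true("log(E)" %in% rank$candidates[[1]]$terms)
})

test_that("stepwise search on the full pool finds a planted log(E) signal", {
  dat <- toy_correction_data(n_subj = 5, n_per = 40, seed = 21,
                             fun = function(B, E) 2 + 0.5 * log(E))
  rank <- stepwise_bic_select(dat$init, dat$exposure, dat$y)
  expect_gt(length(rank$candidates), 10)
  expect_true("log(E)" %in% rank$candidates[[1]]$terms)
  ## ranking is sorted by BIC
  bics <- vapply(rank$candidates, `[[`, numeric(1), "bic")
  expect_false(is.unsorted(bics))
})

test_that("constant response collapses to an intercept-only model", {
  dat <- toy_correction_data()
  expect_warning(rank <- stepwise_bic_select(dat$init, dat$exposure,
                                             rep(1.8, nrow(dat))),
                 "constant")
  expect_equal(rank$candidates[[1]]$terms, character(0))
  m <- suppressWarnings(
    lasso_finetune(rank, dat$init, dat$exposure, rep(1.8, nrow(dat)),
                   dat$subject_id, parameter = "const"))
  expect_length(m$coefficients, 0)
  expect_equal(predict(m, data.frame(init = 4, exposure = 10)), 1.8)
})

test_that("LASSO fine-tuning: zero penalty reduces to OLS; winner finds the truth", {
  dat <- toy_correction_data(n_subj = 5, n_per = 30, seed = 7,
                             fun = function(B, E) 2 + 0.5 * log(E))
  rank <- stepwise_bic_select(dat$init, dat$exposure, dat$y,
                              terms = c("log(E)", "B", "E^-1", "B*E"))
  m0 <- lasso_finetune(rank, dat$init, dat$exposure, dat$y, dat$subject_id,
                       alpha = 0, parameter = "y")
  ## alpha = 0: coefficients equal the OLS refit of the winning subset
  X <- build_feature_matrix(dat$init, dat$exposure, m0$terms)
  ols <- coef(lm(dat$y ~ X))
  expect_equal(unname(m0$intercept), unname(ols[1]), tolerance = 1e-8)
  expect_equal(unname(m0$coefficients), unname(ols[-1]), tolerance = 1e-8)

  ## with the default penalty, the winner contains the generative term in
  ## at least 18 of 20 seeded replicates
  hits <- 0
  for (s in 1:20) {
    d2 <- toy_correction_data(n_subj = 4, n_per = 25, seed = 100 + s,
                              fun = function(B, E) 2 + 0.5 * log(E))
    r2 <- stepwise_bic_select(d2$init, d2$exposure, d2$y,
                              terms = c("log(E)", "B", "E^-1", "B*E"))
    w <- lasso_finetune(r2, d2$init, d2$exposure, d2$y, d2$subject_id,
                        alpha = 0.006, parameter = "y")
    if ("log(E)" %in% names(w$coefficients)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("L1 sparsity keeps at most one of two duplicated columns", {
  set.seed(11)
  n <- 120
  x <- runif(n, 1, 5)
  y <- 1 + x + rnorm(n, 0, 0.1)
  X <- cbind(a = x, b = x)
  fit <- purescore:::lasso_refit(X, y, alpha = 0.01)
  expect_lte(sum(abs(fit$coefficients) > 1e-8), 1)
})

test_that("prediction is the dot product of stored coefficients and terms", {
  m <- structure(list(parameter = "camp",
                      terms = c("log(E)", "B"),
                      coefficients = c("log(E)" = 0.5, "B" = -0.2),
                      intercept = 1.0, average = 2.0, alpha = 0.006,
                      diagnostics = list(r2 = NA)),
                 class = "plr_correction")
  nd <- data.frame(init = c(4, 2), exposure = c(exp(2), exp(4)))
  expect_equal(predict(m, nd),
               1.0 + 0.5 * c(2, 4) - 0.2 * c(4, 2))
  ## intercept-only
  m$terms <- character(0); m$coefficients <- numeric(0); m$intercept <- 1.8
  expect_equal(predict(m, nd), c(1.8, 1.8))
})

test_that("the correction formula is exact, shift-equivariant arithmetic", {
  expect_equal(apply_correction(3.0, 3.0, 4.0), 4.0)
  expect_equal(apply_correction(3.5, 3.0, 4.0), 4.5)
  d <- 0.37
  expect_equal(apply_correction(3.5 + d, 3.0, 4.0) -
                 apply_correction(3.5, 3.0, 4.0), d)
  ## between-subject differences at identical lighting are preserved
  expect_equal(apply_correction(5.1, 2.2, 4.0) -
                 apply_correction(4.4, 2.2, 4.0), 5.1 - 4.4)
})

test_that("LOSO correction flattens a deterministic lighting dependence", {
  ## response is an exact function of (B, E) within the model class:
  ## corrected values must collapse to the fold grand mean
  dat <- toy_correction_data(n_subj = 4, n_per = 25, seed = 13,
                             fun = function(B, E) 1 + 0.4 * log(E),
                             noise = 0)
  dat$end <- dat$y
  out <- correct_plr_loso(dat, alpha = 0, parameters = "end",
                          terms = c("log(E)", "B"))
  for (s in unique(out$subject_id)) {
    rows <- out$subject_id == s
    fold_mean <- mean(dat$end[!rows])
    expect_equal(out$end_c[rows], rep(fold_mean, sum(rows)),
                 tolerance = 1e-6)
  }

  ## permuting row order leaves the corrected values unchanged
  perm <- sample(nrow(dat))
  out2 <- correct_plr_loso(dat[perm, ], alpha = 0, parameters = "end",
                           terms = c("log(E)", "B"))
  expect_equal(out2$end_c, out$end_c[perm], tolerance = 1e-12)
})

test_that("held-out predictions differ from full-data fits for an outlying subject", {
  dat <- toy_correction_data(n_subj = 3, n_per = 25, seed = 17,
                             fun = function(B, E) 1 + 0.4 * log(E),
                             noise = 0.01)
  ## make subject 3 a different regime
  shift <- dat$subject_id == "s3"
  dat$y[shift] <- dat$y[shift] + 3
  dat$end <- dat$y
  loso <- correct_plr_loso(dat, alpha = 0, parameters = "end",
                           terms = c("log(E)", "B"))
  full_m <- fit_plr_corrections(transform(dat, end = y), alpha = 0,
                                parameters = "end")
  full <- correct_plr(transform(dat, end = y), full_m)
  expect_gt(mean(abs(loso$end_c[shift] - full$end_c[shift])), 0.1)
})

test_that("illumination F statistic matches a manual ANOVA decomposition", {
  ## hand-built balanced table: 2 subjects x 2 levels x 3 reps
  df <- expand.grid(rep = 1:3, level = c("lo", "hi"), subj = c("A", "B"))
  set.seed(2)
  df$y <- 5 - 1 * (df$level == "hi") + 0.5 * (df$subj == "B") +
    rnorm(nrow(df), 0, 0.2)
  a <- light_anova(df$y, df$level, df$subj)

  ## brute-force residual sums of squares
  fit_rss <- function(form) sum(residuals(lm(form, data = df))^2)
  rss1 <- fit_rss(y ~ factor(subj) + factor(level))
  rss0 <- fit_rss(y ~ factor(subj))
  df1 <- 1; df2 <- nrow(df) - 3
  expect_equal(a$f, ((rss0 - rss1) / df1) / (rss1 / df2), tolerance = 1e-10)
  expect_equal(a$df1, df1)
  expect_equal(a$df2, df2)

  ## per-subject constants are absorbed by the subject intercepts
  df$y2 <- df$y + 10 * (df$subj == "B")
  expect_equal(light_anova(df$y2, df$level, df$subj)$f, a$f,
               tolerance = 1e-8)

  ## no illumination effect at all: F = 0
  df$y3 <- rep(c(1, 2), each = 6)[order(order(df$subj))]
  df$y3 <- ifelse(df$subj == "A", 1, 2)
  expect_equal(light_anova(df$y3, df$level, df$subj)$f, 0)
})

test_that("correction models serialize to full double precision", {
  lp <- head(lighting_params_fixture(), 200)
  models <- fit_plr_corrections(lp, parameters = c("camp", "end"))
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_models(models, path)
  back <- read_correction_models(path)
  probe <- data.frame(init = seq(2.5, 7.5, length.out = 11),
                      exposure = exp(seq(0, 6, length.out = 11)))
  ## JSON carries 15 significant digits, so predictions agree to ~1e-15
  ## relative error but not bit-exactly
  for (pn in names(models))
    expect_equal(predict(models[[pn]], probe),
                 predict(back[[pn]], probe), tolerance = 1e-12)
  ## strict mode rejects unknown fields
  txt <- jsonlite::read_json(path)
  txt$models[[1]]$mystery <- 1
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(txt, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_correction_models(path2), "unknown field")
})
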