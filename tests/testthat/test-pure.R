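test_that("published linear score reproduces its coefficients on unit inputs", {
  m <- pure_model()
  expect_equal(pure_score(m, 0, 0, 0, 0, 0, 0), 0)
  expect_equal(pure_score(m, 0, 1, 0, 0, 0, 0), -2.438)
  expect_equal(pure_score(m, 0, 0, 0, 0, 0, 1), 2.604)
  expect_equal(pure_score(m, 1, 0, 0, 0, 0, 0), 0.007)
  expect_equal(pure_score(m, 0, 0, 1, 0, 0, 0), 2.773)
  expect_equal(pure_score(m, 0, 0, 0, 1, 0, 0), 0.838)
  expect_equal(pure_score(m, 0, 0, 0, 0, 1, 0), 1.239)
  ## general dot product
  expect_equal(pure_score(m, 5, 3.5, 4.5, -3, 1, 1.5),
               0.007 * 5 - 2.438 * 3.5 + 2.773 * 4.5 + 0.838 * (-3) +
                 1.239 * 1 + 2.604 * 1.5)
  ## data-frame interface and missing-field error
  df <- data.frame(init = 5, end_c = 3.5, fin_c = 4.5, mcv_c = -3,
                   pdv_c = 1, camp_c = 1.5)
  expect_equal(pure_score(m, df), pure_score(m, 5, 3.5, 4.5, -3, 1, 1.5))
  expect_error(pure_score(m, df[, -2]), "end_c")
  expect_error(pure_model(coefficients = c(init = 1)), "missing coefficient")
})

test_that("piecewise scaler anchors follow the calibration recipe exactly", {
  ## worked example: post median -2 sd 1, pre median 4.5 sd 0.5
  sc <- fit_pure_scaler(pre_scores = c(4, 4.5, 5),
                        post_scores = c(-3, -2, -1))
  expect_equal(sc$raw, c(-5, -3, -2, -1, 0, 3, 4.5))
  expect_equal(sc$scaled, c(-0.5, 0.2, 0.8, 1.0, 3, 4.0, 4.5))

  ## fixed mapped points
  expect_equal(scale_pure(sc, 0), 3.0)
  expect_equal(scale_pure(sc, 4.5), 4.5)   # median(pre)
  expect_equal(scale_pure(sc, -2), 0.8)    # median(post)
  expect_equal(scale_pure(sc, -1), 1.0)    # median(post) + sd(post)
  expect_equal(scale_pure(sc, 3), 4.0)     # median(pre) - 3 sd(pre)
  ## interpolation inside a segment
  expect_equal(scale_pure(sc, -1.5), 0.9)
  ## clamping
  expect_equal(scale_pure(sc, -1e6), 0)
  expect_equal(scale_pure(sc, 1e6), 5)

  ## overlapping calibration distributions are rejected
  expect_error(fit_pure_scaler(c(4, 4.5, 5), c(-0.1, 0.5, 1.2)),
               "anchors not increasing")
  expect_error(fit_pure_scaler(c(4, 4.5), c(-3, -2, -1)), ">= 3 scores")
})

test_that("scaler is scale-equivariant in raw units and monotone onto [0, 5]", {
  pre <- c(3.2, 4.1, 4.4, 5.0, 4.6)
  post <- c(-2.5, -1.7, -2.2, -3.1, -1.9)
  sc <- fit_pure_scaler(pre, post)
  cc <- 3.7
  sc2 <- fit_pure_scaler(cc * pre, cc * post)
  expect_equal(sc2$raw, cc * sc$raw, tolerance = 1e-12)
  expect_equal(sc2$scaled, sc$scaled)

  ## monotone non-decreasing over a wide grid, surjective onto [0, 5]
  grid <- seq(-50, 50, length.out = 5001)
  vals <- scale_pure(sc, grid)
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(range(vals), c(0, 5))
})

test_that("AUC equals the brute-force pairwise comparison count", {
  set.seed(8)
  for (rep in 1:5) {
    pos <- round(rnorm(13, 1), 1)   # rounding forces some ties
    neg <- round(rnorm(9, 0), 1)
    res <- evaluate_discrimination(pos, neg)
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(res$auc, mean(pairs))
  }
  ## degenerate cases
  expect_equal(evaluate_discrimination(c(2, 3), c(-1, 0))$auc, 1)
  expect_equal(evaluate_discrimination(c(2, 3), c(-1, 0))$accuracy, 1)
  expect_equal(evaluate_discrimination(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
})

test_that("score training with no penalties agrees with plain logistic regression", {
  set.seed(4)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x1 - 0.7 * x2))
  fit <- train_pure_model(cbind(a = x1, b = x2), y, alpha = 0, gamma = 0,
                          expand = FALSE)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$intercept), unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[c("a", "b")]),
               unname(coef(ref)[2:3]), tolerance = 1e-4)
})

test_that("trained score separates classes and respects sign conventions", {
  set.seed(9)
  x <- c(rnorm(40, 2, 0.3), rnorm(40, -2, 0.3))
  y <- rep(c(1, 0), each = 40)
  fit <- train_pure_model(cbind(f = x), y, alpha = 0.006, gamma = 0,
                          expand = FALSE)
  expect_gt(fit$coefficients[["f"]], 0)
  expect_error(train_pure_model(cbind(f = x), rep(1, 80)), "both classes")

  ## on the synthetic mydriasis cohort the trained score separates
  ## pre from post perfectly
  pipe <- pipeline_fixture()
  cp <- pipe$mydriasis_parameters
  feats <- cp[, c("end_c", "fin_c", "camp_c", "mcv_c", "pdv_c")]
  lab <- as.numeric(cp$drug_state == "pre")
  tr <- train_pure_model(feats, lab, illumination = round(log10(cp$illuminance_lux), 1),
                         alpha = 0.006, gamma = 1)
  auc <- evaluate_discrimination(tr$raw_scores[lab == 1],
                                 tr$raw_scores[lab == 0])$auc
  expect_equal(auc, 1.0)
})

test_that("scaled scores are stable across lighting yet separate drug states", {
  pipe <- pipeline_fixture()
  ## lighting study (all reactive), corrected with the trained models and
  ## scored with the published formula + the cohort-calibrated scaler
  lp <- correct_plr(pipe$lighting_parameters, pipe$correction_models)
  raw <- pure_score(pure_model(), lp)
  scaled <- scale_pure(pipe$scaler, raw)
  level_means <- tapply(scaled, lp$illuminance_lux, mean)
  expect_lt(sd(level_means), 0.25)

  sc <- pipe$scores
  gap <- mean(sc$pure_score[sc$drug_state == "pre"]) -
    mean(sc$pure_score[sc$drug_state == "post"])
  expect_gt(gap, 2.5)
})

test_that("PuRe model JSON round trip preserves coefficients and scaler", {
  m <- pure_model()
  m$scaler <- fit_pure_scaler(c(4, 4.5, 5), c(-3, -2, -1))
  path <- withr::local_tempfile(fileext = ".json")
  write_pure_model(m, path)
  back <- read_pure_model(path)
  expect_equal(coef(back), coef(m), tolerance = 1e-12)
  expect_equal(round(unname(coef(back)[c("end_c", "camp_c")]), 3),
               c(-2.438, 2.604))
  grid <- seq(-6, 6, by = 0.25)
  expect_identical(scale_pure(back$scaler, grid), scale_pure(m$scaler, grid))
  ## truncated file: parse error, no partial model
  txt <- readLines(path)
  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], path2)
  expect_error(read_pure_model(path2))
})
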