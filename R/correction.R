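#' The lighting-correction feature library
#'
#' Each PLR parameter is predicted from two lighting proxies: the measured
#' baseline pupil diameter (`B`, the INIT parameter, mm) and the camera
#' exposure reported by the phone firmware (`E`, opaque positive units).
#' The candidate terms are the linear, squared, inverse, log and squared-log
#' transforms of each predictor plus the interactions `B*E` and
#' `log(B)*log(E)`.
#'
#' @return Character vector of the 12 term names, in canonical order.
#' @export
plr_terms <- function() {
  c("B", "E", "B^2", "E^2", "B^-1", "E^-1",
    "log(B)", "log(E)", "log(B)^2", "log(E)^2",
    "B*E", "log(B)*log(E)")
}

eval_term <- function(term, B, E) {
  switch(term,
         "B" = B, "E" = E,
         "B^2" = B^2, "E^2" = E^2,
         "B^-1" = 1 / B, "E^-1" = 1 / E,
         "log(B)" = log(B), "log(E)" = log(E),
         "log(B)^2" = log(B)^2, "log(E)^2" = log(E)^2,
         "B*E" = B * E,
         "log(B)*log(E)" = log(B) * log(E),
         stop("unknown feature term: ", term, call. = FALSE))
}

#' Build the lighting feature matrix
#'
#' @param baseline vector of baseline pupil diameters (mm), > 0.
#' @param exposure vector of camera exposure values, > 0.
#' @param terms subset of [plr_terms()] to evaluate, in column order.
#' @return Numeric matrix, one column per term.
#' @export
build_feature_matrix <- function(baseline, exposure, terms = plr_terms()) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("build_feature_matrix: baseline must be finite and > 0", call. = FALSE)
  if (any(!is.finite(exposure)) || any(exposure <= 0))
    stop("build_feature_matrix: exposure must be finite and > 0", call. = FALSE)
  bad <- setdiff(terms, plr_terms())
  if (length(bad)) stop("unknown feature term: ", bad[1], call. = FALSE)
  X <- vapply(terms, eval_term, numeric(length(baseline)),
              B = baseline, E = exposure)
  X <- matrix(X, nrow = length(baseline),
              dimnames = list(NULL, terms))
  X
}

ols_bic <- function(X, y) {
  n <- length(y)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  rss <- sum(fit$residuals^2)
  k <- fit$rank
  bic <- if (rss < 1e-12) -Inf else n * log(rss / n) + k * log(n)
  list(bic = bic, rss = rss)
}

subset_key <- function(terms) paste0("k:", paste(sort(terms), collapse = "|"))

#' Rank feature subsets by BIC
#'
#' Searches subsets of the candidate feature terms for an ordinary
#' least-squares prediction of a PLR parameter, scoring each visited subset
#' by the Bayes information criterion
#' `BIC = n log(RSS/n) + k log(n)`. Small pools (up to
#' `exhaustive_limit` terms) are enumerated exhaustively; larger pools are
#' searched by forward selection with backward pruning at every step, with
#' every evaluated candidate recorded. The ranked list feeds the LASSO
#' fine-tuning stage.
#'
#' @inheritParams build_feature_matrix
#' @param y numeric response (one PLR parameter), `n >= 10`.
#' @param max_models retain at most this many top-ranked subsets.
#' @param exhaustive_limit enumerate all subsets when
#'   `length(terms) <= exhaustive_limit`.
#' @return Object of class `"plr_bic_ranking"`: list with `candidates`
#'   (each a list of `terms` and `bic`, ascending BIC) and `terms` (the
#'   pool searched).
#' @export
stepwise_bic_select <- function(baseline, exposure, y, terms = plr_terms(),
                                max_models = 250, exhaustive_limit = 8) {
  keep <- is.finite(y)
  y <- y[keep]; baseline <- baseline[keep]; exposure <- exposure[keep]
  n <- length(y)
  if (n < 10) stop("stepwise_bic_select: need at least 10 observations",
                   call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    warning("constant response: returning intercept-only model")
    return(structure(list(candidates = list(list(terms = character(0),
                                                 bic = -Inf)),
                          terms = terms),
                     class = "plr_bic_ranking"))
  }
  X <- build_feature_matrix(baseline, exposure, terms)
  registry <- new.env(parent = emptyenv())
  score <- function(sub) {
    key <- subset_key(sub)
    if (!is.null(registry[[key]])) return(registry[[key]]$bic)
    b <- ols_bic(X[, sub, drop = FALSE], y)$bic
    registry[[key]] <- list(terms = sub, bic = b)
    b
  }

  if (length(terms) <= exhaustive_limit) {
    p <- length(terms)
    for (mask in 0:(2^p - 1))
      score(terms[bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) > 0])
  } else {
    current <- character(0)
    cur_bic <- score(current)
    repeat {
      moves <- c(lapply(setdiff(terms, current),
                        function(tm) c(current, tm)),
                 lapply(seq_along(current),
                        function(i) current[-i]))
      if (!length(moves)) break
      bics <- vapply(moves, score, numeric(1))
      if (min(bics) < cur_bic - 1e-10) {
        current <- moves[[which.min(bics)]]
        cur_bic <- min(bics)
      } else break
    }
  }

  cand <- as.list(registry)
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "bic"))]
  names(cand) <- NULL
  if (length(cand) > max_models) cand <- cand[seq_len(max_models)]
  structure(list(candidates = cand, terms = terms),
            class = "plr_bic_ranking")
}

#' @export
print.plr_bic_ranking <- function(x, n = 5, ...) {
  cat(sprintf("BIC ranking over %d candidate subsets (pool of %d terms)\n",
              length(x$candidates), length(x$terms)))
  for (i in seq_len(min(n, length(x$candidates)))) {
    c_i <- x$candidates[[i]]
    cat(sprintf("  %2d. BIC %9.2f  {%s}\n", i, c_i$bic,
                paste(c_i$terms, collapse = ", ")))
  }
  invisible(x)
}

## L1 refit of one candidate subset; coefficients on the original scale.
## glmnet needs >= 2 columns, so the single-feature case uses the
## closed-form soft-threshold solution on the standardized column.
lasso_refit <- function(X, y, alpha) {
  p <- ncol(X)
  n <- length(y)
  if (p == 0 || alpha < 0) stop("lasso_refit: invalid input", call. = FALSE)
  if (alpha == 0) {
    fit <- stats::lm.fit(cbind(1, X), y)
    cf <- fit$coefficients
    return(list(intercept = cf[1],
                coefficients = stats::setNames(cf[-1], colnames(X))))
  }
  if (p == 1) {
    x <- X[, 1]
    sdx <- sqrt(mean((x - mean(x))^2))
    if (sdx < 1e-12) return(list(intercept = mean(y),
                                 coefficients = stats::setNames(0, colnames(X))))
    xs <- (x - mean(x)) / sdx
    rho <- mean(xs * (y - mean(y)))
    bs <- sign(rho) * max(abs(rho) - alpha, 0)
    b <- bs / sdx
    return(list(intercept = mean(y) - b * mean(x),
                coefficients = stats::setNames(b, colnames(X))))
  }
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = alpha, standardize = TRUE)
  cf <- as.numeric(stats::coef(fit))
  list(intercept = cf[1],
       coefficients = stats::setNames(cf[-1], colnames(X)))
}

#' Fine-tune BIC-ranked models with LASSO and pick a winner
#'
#' Each candidate subset from [stepwise_bic_select()] is refitted with an
#' L1 penalty (`alpha`, applied on internally standardized features), terms
#' shrunk exactly to zero are dropped, and the winning model is the one
#' with the smallest leave-one-subject-out cross-validated mean squared
#' prediction error. The returned model stores the training grand mean of
#' the parameter (pooled over all lighting conditions), which the
#' correction formula adds back.
#'
#' @param candidates a `"plr_bic_ranking"`.
#' @inheritParams stepwise_bic_select
#' @param subject subject identifiers, used for the cross-validation folds.
#' @param alpha L1 penalty weight (default 0.006).
#' @param parameter name of the parameter being modelled (for labelling).
#' @return Object of class `"plr_correction"`: `parameter`, `terms`,
#'   `coefficients`, `intercept`, `average`, `alpha` and `diagnostics`
#'   (in-sample `r2`, CV MSE).
#' @export
lasso_finetune <- function(candidates, baseline, exposure, y, subject,
                           alpha = 0.006, parameter = "parameter") {
  stopifnot(inherits(candidates, "plr_bic_ranking"))
  keep <- is.finite(y)
  y <- y[keep]; baseline <- baseline[keep]; exposure <- exposure[keep]
  subject <- as.character(subject[keep])
  if (!length(candidates$candidates))
    stop("lasso_finetune: empty candidate list", call. = FALSE)
  subjects <- unique(subject)

  fit_one <- function(terms, idx) {
    if (!length(terms))
      return(list(intercept = mean(y[idx]),
                  coefficients = stats::setNames(numeric(0), character(0))))
    X <- build_feature_matrix(baseline[idx], exposure[idx], terms)
    lasso_refit(X, y[idx], alpha)
  }
  predict_one <- function(model, idx) {
    pred <- rep(model$intercept, length(idx))
    terms <- names(model$coefficients)
    nz <- terms[model$coefficients != 0]
    if (length(nz)) {
      X <- build_feature_matrix(baseline[idx], exposure[idx], nz)
      pred <- pred + drop(X %*% model$coefficients[nz])
    }
    pred
  }

  all_idx <- seq_along(y)
  cv_mse <- vapply(candidates$candidates, function(cand) {
    err <- 0
    for (s in subjects) {
      hold <- which(subject == s)
      if (length(hold) == length(y)) next
      m <- fit_one(cand$terms, setdiff(all_idx, hold))
      err <- err + sum((y[hold] - predict_one(m, hold))^2)
    }
    err / length(y)
  }, numeric(1))

  win <- candidates$candidates[[which.min(cv_mse)]]
  final <- fit_one(win$terms, all_idx)
  nz <- final$coefficients[final$coefficients != 0]
  if (length(win$terms) && !length(nz))
    warning("all coefficients shrunk to zero: intercept-only model for ",
            parameter)
  pred <- predict_one(final, all_idx)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

  structure(list(parameter = parameter,
                 terms = names(nz),
                 coefficients = nz,
                 intercept = unname(final$intercept),
                 average = mean(y),
                 alpha = alpha,
                 diagnostics = list(r2 = r2, cv_mse = min(cv_mse),
                                    f_raw = NA_real_,
                                    f_corrected = NA_real_)),
            class = "plr_correction")
}

#' @export
print.plr_correction <- function(x, ...) {
  cat(sprintf("Lighting-correction model for %s\n", toupper(x$parameter)))
  if (length(x$coefficients)) {
    cat("  terms:", paste(sprintf("%s (%.4g)", names(x$coefficients),
                                  x$coefficients), collapse = " + "), "\n")
  } else cat("  intercept-only\n")
  cat(sprintf("  intercept %.4g, training mean %.4g, in-sample R^2 %.3f\n",
              x$intercept, x$average, x$diagnostics$r2))
  invisible(x)
}

#' Predict a PLR parameter from lighting
#'
#' @param object a `"plr_correction"` model.
#' @param newdata data frame with columns `init` (baseline, mm) and
#'   `exposure`, or the vectors `baseline`/`exposure` via `...`.
#' @param ... unused.
#' @return Predicted parameter values.
#' @export
predict.plr_correction <- function(object, newdata, ...) {
  B <- if (!is.null(newdata$baseline)) newdata$baseline else newdata$init
  E <- newdata$exposure
  pred <- rep(object$intercept, length(B))
  if (length(object$coefficients)) {
    X <- build_feature_matrix(B, E, names(object$coefficients))
    pred <- pred + drop(X %*% object$coefficients)
  }
  pred
}

#' The lighting-correction formula
#'
#' `corrected = average + measured - predicted`: the deviation of the
#' measurement from its lighting-predicted value, added to the parameter's
#' training grand mean. A perfectly average response returns exactly the
#' grand mean under any lighting, and the correction is shift-equivariant
#' in the measurement.
#'
#' @param measured measured parameter value(s).
#' @param predicted lighting-model prediction(s).
#' @param average training grand mean of the parameter.
#' @return Corrected value(s).
#' @export
apply_correction <- function(measured, predicted, average) {
  average + measured - predicted
}

CORRECTED_PARAMS <- c("end", "fin", "camp", "mcv", "pdv", "lat", "t75")

#' Fit lighting-correction models for all PLR parameters
#'
#' Runs the full two-stage selection (stepwise BIC ranking, then LASSO
#' fine-tuning with leave-one-subject-out CV) for each parameter except
#' INIT, which serves as the Baseline predictor and is never corrected.
#'
#' @param data data frame with columns `subject_id`, `init`, `exposure`
#'   and the parameter columns `end`, `fin`, `camp`, `mcv`, `pdv`, `lat`,
#'   `t75`.
#' @param alpha L1 penalty weight.
#' @param parameters which parameters to model.
#' @param terms candidate feature pool.
#' @param max_models retained BIC-ranked candidates per parameter.
#' @return Object of class `"plr_correction_set"`: a named list of
#'   `"plr_correction"` models.
#' @export
fit_plr_corrections <- function(data, alpha = 0.006,
                                parameters = CORRECTED_PARAMS,
                                terms = plr_terms(), max_models = 250) {
  models <- lapply(parameters, function(pn) {
    y <- data[[pn]]
    rank <- stepwise_bic_select(data$init, data$exposure, y, terms = terms,
                                max_models = max_models)
    lasso_finetune(rank, data$init, data$exposure, y, data$subject_id,
                   alpha = alpha, parameter = pn)
  })
  names(models) <- parameters
  structure(models, class = "plr_correction_set", alpha = alpha)
}

#' @export
print.plr_correction_set <- function(x, ...) {
  cat(sprintf("Lighting-correction model set (%d parameters, alpha = %g)\n",
              length(x), attr(x, "alpha")))
  for (m in x) print(m)
  invisible(x)
}

#' Apply lighting corrections to a parameter table
#'
#' @param data parameter table as in [fit_plr_corrections()].
#' @param models a `"plr_correction_set"`.
#' @return `data` with one added column per corrected parameter
#'   (`end_c`, `fin_c`, ... , `t75_c`).
#' @export
correct_plr <- function(data, models) {
  stopifnot(inherits(models, "plr_correction_set"))
  for (pn in names(models)) {
    m <- models[[pn]]
    data[[paste0(pn, "_c")]] <-
      apply_correction(data[[pn]], predict(m, data), m$average)
  }
  data
}

#' Leave-one-subject-out corrected parameter table
#'
#' For each subject, correction models are trained on all remaining
#' subjects only, so no model ever sees the data it corrects. The grand
#' mean (`average`) is likewise recomputed per training fold.
#'
#' @inheritParams fit_plr_corrections
#' @return `data` with the corrected parameter columns appended; row order
#'   is preserved.
#' @export
correct_plr_loso <- function(data, alpha = 0.006,
                             parameters = CORRECTED_PARAMS,
                             terms = plr_terms(), max_models = 250) {
  subjects <- sort(unique(as.character(data$subject_id)))
  if (length(subjects) < 3)
    stop("correct_plr_loso: need at least 3 subjects", call. = FALSE)
  for (pn in parameters) data[[paste0(pn, "_c")]] <- NA_real_
  for (s in subjects) {
    hold <- data$subject_id == s
    if (!any(hold)) next
    train <- data[!hold, , drop = FALSE]
    models <- fit_plr_corrections(train, alpha = alpha,
                                  parameters = parameters, terms = terms,
                                  max_models = max_models)
    corr <- correct_plr(data[hold, , drop = FALSE], models)
    for (pn in parameters)
      data[[paste0(pn, "_c")]][hold] <- corr[[paste0(pn, "_c")]]
  }
  data
}

#' F-test for illumination dependence of a parameter
#'
#' Tests the categorical illumination factor in a linear model with
#' per-subject intercepts (a fixed-effect stand-in for the random subject
#' intercept, exact for balanced designs): the F statistic compares the
#' subject-only model against the subject + illumination model.
#'
#' @param values parameter values (NAs dropped).
#' @param illumination illumination level, treated categorically.
#' @param subject subject identifiers.
#' @return List with `f`, `df1`, `df2` and `p`.
#' @export
light_anova <- function(values, illumination, subject) {
  keep <- is.finite(values)
  values <- values[keep]
  illumination <- factor(illumination[keep])
  subject <- factor(subject[keep])
  if (nlevels(illumination) < 2 || nlevels(subject) < 2)
    stop("light_anova: need >= 2 illumination levels and >= 2 subjects",
         call. = FALSE)
  if (any(table(illumination) < 1))
    stop("light_anova: empty illumination level", call. = FALSE)
  full <- stats::lm(values ~ subject + illumination)
  red <- stats::lm(values ~ subject)
  rss1 <- sum(stats::residuals(full)^2)
  rss0 <- sum(stats::residuals(red)^2)
  df1 <- red$df.residual - full$df.residual
  df2 <- full$df.residual
  num <- max(rss0 - rss1, 0)
  f <- if (num < 1e-12) 0 else (num / df1) / (rss1 / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
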