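#' The Pupil Reactivity (PuRe) model
#'
#' The published PuRe score is a linear combination of the raw baseline
#' diameter and five lighting-corrected PLR parameters:
#'
#' \deqn{PuRe = 0.007\,INIT - 2.438\,END_c + 2.773\,FIN_c + 0.838\,MCV_c
#'   + 1.239\,PDV_c + 2.604\,CAMP_c}
#'
#' with no intercept. INIT enters uncorrected (it is the Baseline
#' predictor of the lighting models); MCV is signed. The raw score is
#' mapped to the 0-5 clinical scale by a [fit_pure_scaler()] object.
#'
#' @param coefficients named numeric vector over
#'   `init, end_c, fin_c, mcv_c, pdv_c, camp_c`.
#' @param intercept intercept of the linear score (0 for the published
#'   model).
#' @param scaler optional [fit_pure_scaler()] object attached to the model.
#' @return Object of class `"pure_model"`.
#' @export
pure_model <- function(coefficients = c(init = 0.007, end_c = -2.438,
                                        fin_c = 2.773, mcv_c = 0.838,
                                        pdv_c = 1.239, camp_c = 2.604),
                       intercept = 0, scaler = NULL) {
  required <- c("init", "end_c", "fin_c", "mcv_c", "pdv_c", "camp_c")
  missing <- setdiff(required, names(coefficients))
  if (length(missing))
    stop("pure_model: missing coefficient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(coefficients = coefficients[required],
                 intercept = intercept, scaler = scaler),
            class = "pure_model")
}

#' @export
coef.pure_model <- function(object, ...) object$coefficients

#' @export
print.pure_model <- function(x, ...) {
  cat("Pupil Reactivity (PuRe) score model\n")
  cf <- x$coefficients
  cat("  PuRe =", paste(sprintf("%+.3f*%s", cf, toupper(names(cf))),
                        collapse = " "), "\n")
  if (x$intercept != 0) cat(sprintf("  intercept %.4g\n", x$intercept))
  cat(if (is.null(x$scaler)) "  no scaler attached\n"
      else "  piecewise 0-5 scaler attached\n")
  invisible(x)
}

#' Raw PuRe linear score
#'
#' @param model a [pure_model()].
#' @param init raw baseline diameter (mm), or a data frame / list holding
#'   all six inputs as columns `init, end_c, fin_c, mcv_c, pdv_c, camp_c`.
#' @param end_c,fin_c,mcv_c,pdv_c,camp_c lighting-corrected parameters
#'   (ignored when `init` is a data frame).
#' @return Raw (unscaled) score value(s).
#' @export
pure_score <- function(model, init, end_c, fin_c, mcv_c, pdv_c, camp_c) {
  if (is.list(init)) {
    d <- init
    for (f in names(model$coefficients))
      if (is.null(d[[f]]))
        stop("pure_score: missing input '", f, "'", call. = FALSE)
    vals <- vapply(names(model$coefficients), function(f) as.numeric(d[[f]]),
                   numeric(length(d[["init"]])))
    vals <- matrix(vals, ncol = length(model$coefficients))
  } else {
    vals <- cbind(init, end_c, fin_c, mcv_c, pdv_c, camp_c)
  }
  if (any(!is.finite(vals)))
    stop("pure_score: non-finite input", call. = FALSE)
  model$intercept + drop(vals %*% model$coefficients)
}

#' @export
predict.pure_model <- function(object, newdata,
                               type = c("raw", "scaled"), ...) {
  type <- match.arg(type)
  raw <- pure_score(object, newdata)
  if (type == "raw") return(raw)
  if (is.null(object$scaler))
    stop("predict.pure_model: no scaler attached", call. = FALSE)
  scale_pure(object$scaler, raw)
}

#' Calibrate the piecewise 0-5 scaler
#'
#' The raw score is rescaled onto the clinical 0-5 range by a piecewise
#' linear function anchored on the calibration distributions of raw scores
#' before (`pre`, reactive) and after (`post`, unreactive) mydriatic
#' administration. With `m` the sample median and `s` the sample standard
#' deviation (n-1 denominator), the anchors are:
#' `m_post - 3 s_post -> -0.5`, `m_post - s_post -> 0.2`, `m_post -> 0.8`,
#' `m_post + s_post -> 1.0`, `0 -> 3`, `m_pre - 3 s_pre -> 4.0`,
#' `m_pre -> 4.5`. Beyond the outer anchors the adjacent segment is
#' extrapolated; results are clamped to `[0, 5]`.
#'
#' @param pre_scores raw scores of reactive (pre-drug) recordings,
#'   `length >= 3`.
#' @param post_scores raw scores of unreactive (post-drug) recordings,
#'   `length >= 3`.
#' @return Object of class `"pure_scaler"` with `raw` and `scaled` anchor
#'   vectors and the calibration summaries.
#' @export
fit_pure_scaler <- function(pre_scores, post_scores) {
  if (length(pre_scores) < 3 || length(post_scores) < 3)
    stop("fit_pure_scaler: need >= 3 scores per sample", call. = FALSE)
  m_pre <- stats::median(pre_scores); s_pre <- stats::sd(pre_scores)
  m_post <- stats::median(post_scores); s_post <- stats::sd(post_scores)
  if (s_pre <= 0 || s_post <= 0)
    stop("fit_pure_scaler: calibration samples must have positive spread",
         call. = FALSE)
  raw <- c(m_post - 3 * s_post, m_post - s_post, m_post, m_post + s_post,
           0, m_pre - 3 * s_pre, m_pre)
  scaled <- c(-0.5, 0.2, 0.8, 1.0, 3, 4.0, 4.5)
  if (any(diff(raw) <= 0))
    stop(sprintf(paste0("fit_pure_scaler: calibration distributions overlap",
                        " zero; raw anchors not increasing (%s)"),
                 paste(sprintf("%.3g", raw), collapse = ", ")),
         call. = FALSE)
  structure(list(raw = raw, scaled = scaled, lower = 0, upper = 5,
                 calibration = list(median_pre = m_pre, sd_pre = s_pre,
                                    median_post = m_post, sd_post = s_post)),
            class = "pure_scaler")
}

#' Map raw PuRe scores onto the 0-5 scale
#'
#' Piecewise-linear interpolation between the calibrated anchors, linear
#' extrapolation with the end-segment slopes beyond them, clamped to
#' `[0, 5]`. Raw 0 always maps to 3.0, the reactive/unreactive midpoint;
#' 0 means a non-reactive pupil, 0-3 an abnormal ("sluggish") response and
#' 3-5 a normal brisk response.
#'
#' @param scaler a [fit_pure_scaler()] object.
#' @param raw raw score value(s).
#' @return Scaled score(s) in `[0, 5]`.
#' @export
scale_pure <- function(scaler, raw) {
  x <- scaler$raw; y <- scaler$scaled
  k <- length(x)
  out <- stats::approx(x, y, xout = raw, rule = 1)$y
  lo_slope <- (y[2] - y[1]) / (x[2] - x[1])
  hi_slope <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
  below <- raw < x[1]; above <- raw > x[k]
  out[below] <- y[1] + lo_slope * (raw[below] - x[1])
  out[above] <- y[k] + hi_slope * (raw[above] - x[k])
  pmin(pmax(out, scaler$lower), scaler$upper)
}

#' @export
print.pure_scaler <- function(x, ...) {
  cat("PuRe piecewise 0-5 scaler\n")
  print(data.frame(raw = round(x$raw, 4), scaled = x$scaled))
  invisible(x)
}

#' Classify a scaled PuRe score
#'
#' @param scaled scaled score(s) in `[0, 5]`.
#' @return Factor with levels `non-reactive` (0), `abnormal` (0-3) and
#'   `normal` (3-5).
#' @export
pure_class <- function(scaled) {
  cut(scaled, breaks = c(-Inf, 0, 3, Inf),
      labels = c("non-reactive", "abnormal", "normal"), right = TRUE)
}

## ---- score training -------------------------------------------------

expand_score_features <- function(X, powers = TRUE, products = TRUE) {
  nm <- colnames(X)
  out <- X
  if (powers) {
    sq <- X^2; colnames(sq) <- paste0(nm, "^2")
    inv <- 1 / X; colnames(inv) <- paste0(nm, "^-1")
    inv[!is.finite(inv)] <- 0
    out <- cbind(out, sq, inv)
  }
  if (products && ncol(X) > 1) {
    pr <- utils::combn(seq_len(ncol(X)), 2)
    prod_mat <- X[, pr[1, ], drop = FALSE] * X[, pr[2, ], drop = FALSE]
    colnames(prod_mat) <- paste0(nm[pr[1, ]], "*", nm[pr[2, ]])
    out <- cbind(out, prod_mat)
  }
  out
}

#' Train a PuRe-style score by penalised logistic regression
#'
#' Re-derives a reactivity score from labelled corrected parameters: the
#' separating hyperplane between reactive and unreactive recordings is
#' estimated by logistic regression with an L1 penalty (`alpha`) plus a
#' light-invariance penalty `gamma * V`, where `V` is the variance across
#' illumination levels of the mean raw score of reactive recordings.
#' Features are standardized internally; coefficients are returned on the
#' original scale. The optimisation uses FISTA proximal gradient descent
#' (the smooth part is the logistic deviance plus the quadratic invariance
#' penalty; the L1 part is handled by soft thresholding), or BFGS when
#' `alpha = 0`. Training never touches the shipped published model.
#'
#' @param features numeric matrix or data frame of candidate inputs (e.g.
#'   the corrected parameters), one row per recording.
#' @param reactive logical or 0/1 labels (1 = reactive).
#' @param illumination illumination level per recording (for the
#'   invariance penalty); ignored when `gamma = 0`.
#' @param alpha L1 weight (default 0.006).
#' @param gamma light-invariance penalty weight (default 1).
#' @param expand add squared, inverse and pairwise-product features.
#' @param max_iter,tol optimiser controls.
#' @return List with `coefficients` (nonzero, original scale),
#'   `intercept`, and the fitted raw scores.
#' @export
train_pure_model <- function(features, reactive, illumination = NULL,
                             alpha = 0.006, gamma = 1, expand = TRUE,
                             max_iter = 5000, tol = 1e-9) {
  X <- as.matrix(as.data.frame(features))
  y <- as.numeric(reactive)
  if (any(!is.finite(X))) stop("train_pure_model: non-finite features",
                               call. = FALSE)
  if (length(unique(y)) < 2)
    stop("train_pure_model: both classes must be present", call. = FALSE)
  if (expand) X <- expand_score_features(X)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  ## invariance penalty: V = var over illumination levels of the mean
  ## standardized-score of reactive rows => quadratic form beta' Q beta
  Q <- matrix(0, ncol(Z), ncol(Z))
  if (gamma > 0 && !is.null(illumination)) {
    lev <- factor(illumination[y == 1])
    Zr <- Z[y == 1, , drop = FALSE]
    M <- rowsum(Zr, lev) / as.vector(table(lev))
    if (nrow(M) > 1) {
      Mc <- sweep(M, 2, colMeans(M))
      Q <- crossprod(Mc) / (nrow(M) - 1)
    }
  }

  nll_grad <- function(b0, b) {
    eta <- b0 + drop(Z %*% b)
    p <- stats::plogis(eta)
    loss <- -mean(y * log(pmax(p, 1e-12)) +
                    (1 - y) * log(pmax(1 - p, 1e-12))) +
      gamma * drop(crossprod(b, Q %*% b))
    g0 <- mean(p - y)
    g <- drop(crossprod(Z, p - y)) / n + 2 * gamma * drop(Q %*% b)
    list(loss = loss, g0 = g0, g = g)
  }

  pfeat <- ncol(Z)
  if (alpha == 0) {
    obj <- function(th) nll_grad(th[1], th[-1])$loss
    grd <- function(th) { g <- nll_grad(th[1], th[-1]); c(g$g0, g$g) }
    ## the logistic loss is flat near its optimum, so the objective must
    ## converge far below `tol` for the coefficients to converge to ~tol
    opt <- stats::optim(rep(0, pfeat + 1), obj, grd, method = "BFGS",
                        control = list(maxit = max_iter,
                                       reltol = min(tol, 1e-13)))
    b0 <- opt$par[1]; b <- opt$par[-1]
  } else {
    ## FISTA with backtracking line search
    b <- numeric(pfeat); b0 <- 0
    vb <- b; vb0 <- b0; tk <- 1; L <- 1
    soft <- function(u, thr) sign(u) * pmax(abs(u) - thr, 0)
    prev_obj <- Inf
    for (it in seq_len(max_iter)) {
      g <- nll_grad(vb0, vb)
      repeat {
        nb <- soft(vb - g$g / L, alpha / L)
        nb0 <- vb0 - g$g0 / L
        new <- nll_grad(nb0, nb)
        quad <- g$loss + sum(g$g * (nb - vb)) + g$g0 * (nb0 - vb0) +
          L / 2 * (sum((nb - vb)^2) + (nb0 - vb0)^2)
        if (new$loss <= quad + 1e-12 || L > 1e8) break
        L <- L * 2
      }
      tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
      vb <- nb + (tk - 1) / tk1 * (nb - b)
      vb0 <- nb0 + (tk - 1) / tk1 * (nb0 - b0)
      b <- nb; b0 <- nb0; tk <- tk1
      obj_now <- new$loss + alpha * sum(abs(b))
      if (abs(prev_obj - obj_now) < tol * max(1, abs(obj_now))) break
      prev_obj <- obj_now
    }
  }

  beta <- b / sdv
  intercept <- b0 - sum(beta * mu)
  nz <- beta[abs(beta) > 1e-10]
  raw <- intercept + drop(X %*% beta)
  list(coefficients = nz, intercept = intercept, raw_scores = raw,
       alpha = alpha, gamma = gamma)
}

## ---- discrimination -------------------------------------------------

#' ROC discrimination of reactive vs unreactive scores
#'
#' AUC by the rank (Mann-Whitney) statistic with ties counted 0.5, plus
#' accuracy at a raw threshold (default 0, the scaled-3.0 boundary) and
#' ROC points over all distinct thresholds. Reactive scores are the
#' positive (higher-scoring) class.
#'
#' @param scores_reactive scores of reactive recordings.
#' @param scores_unreactive scores of unreactive recordings.
#' @param threshold classification threshold on the score scale supplied.
#' @return List with `accuracy`, `auc` and a data frame `roc` of
#'   (fpr, tpr) points.
#' @export
evaluate_discrimination <- function(scores_reactive, scores_unreactive,
                                    threshold = 0) {
  stopifnot(length(scores_reactive) > 0, length(scores_unreactive) > 0)
  n1 <- length(scores_reactive); n0 <- length(scores_unreactive)
  r <- rank(c(scores_reactive, scores_unreactive), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  acc <- (sum(scores_reactive > threshold) +
            sum(scores_unreactive <= threshold)) / (n1 + n0)
  thr <- sort(unique(c(-Inf, scores_reactive, scores_unreactive, Inf)))
  roc <- data.frame(
    fpr = vapply(thr, function(u) mean(scores_unreactive > u), numeric(1)),
    tpr = vapply(thr, function(u) mean(scores_reactive > u), numeric(1)))
  list(accuracy = acc, auc = auc, roc = roc)
}
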