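# QSAR model-evaluation statistics and a minimal PLS1 latent-variable
# regression engine (NIPALS), used to exercise the statistics end-to-end on
# arbitrary numeric descriptor matrices.

#' Relative prediction error, percent
#'
#' \eqn{100 (obs - pred) / obs}. Full precision is returned; round to two
#' decimals for display.
#'
#' @param observed,predicted numeric vectors, same units; observed nonzero.
#' @return signed percents.
#' @examples
#' round(relative_error(-32.347, -32.025), 2)  # 1.00
#' @export
relative_error <- function(observed, predicted) {
  if (any(observed == 0, na.rm = TRUE))
    stop_validation("relative error undefined for observed value 0")
  (observed - predicted) / observed * 100
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2}.
#'
#' @param observed,predicted equal-length numeric vectors, length \eqn{\ge} 3.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3)
    stop_validation("need equal-length vectors of at least 3 values")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop_validation("observed values are constant: R2 undefined")
  1 - sum((observed - predicted)^2) / tss
}

#' Fit a PLS1 latent-variable regression (NIPALS)
#'
#' Deterministic partial-least-squares regression of a single response on a
#' numeric descriptor matrix, the latent-variable engine behind the
#' validation statistics. Descriptors are centred (and optionally
#' unit-variance scaled); components are extracted by NIPALS. Collinear
#' descriptor columns are harmless — predictions depend only on the latent
#' directions.
#'
#' @param X numeric descriptor matrix, rows = molecules.
#' @param y numeric response (e.g., binding free energies, kJ/mol).
#' @param ncomp number of latent components; must not exceed the rank of the
#'   centred descriptor matrix.
#' @param scale. unit-variance scale the descriptors (constant columns are
#'   left unscaled).
#' @return object of class \code{pls_qsar} with \code{coefficients} (in the
#'   original descriptor space), \code{intercept}, weights/loadings/scores,
#'   \code{fitted.values} and \code{residuals}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X[, 1] - 2 * X[, 2] + rnorm(10, sd = 0.1)
#' fit <- pls_fit(X, y, ncomp = 2)
#' cor(predict(fit, X), y)
#' @export
pls_fit <- function(X, y, ncomp = 2, scale. = FALSE) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || anyNA(y) || any(!is.finite(X)) ||
      any(!is.finite(y)))
    stop_validation("X and y must be finite numeric with no missing values")
  if (nrow(X) != length(y)) stop_validation("nrow(X) must equal length(y)")
  x_center <- colMeans(X)
  x_scale <- if (scale.) apply(X, 2, stats::sd) else rep(1, ncol(X))
  x_scale[x_scale == 0] <- 1
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  f <- y - y_center

  rk <- qr(Xc)$rank
  if (ncomp > rk)
    stop_validation(sprintf(
      "ncomp = %d exceeds the rank of the centred descriptor matrix (%d)",
      ncomp, rk))

  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  E <- Xc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop_validation(sprintf(
        "response carries no covariance with the residual descriptors at component %d", a))
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
  }
  B <- W %*% solve(crossprod(P, W), q)          # scaled space
  beta <- drop(B) / x_scale
  intercept <- y_center - sum(beta * x_center)
  fitted <- drop(X %*% beta) + intercept
  structure(list(
    coefficients = beta, intercept = intercept, ncomp = ncomp,
    weights = W, loadings = P, scores = Tm, q = q,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    scaled = scale., fitted.values = fitted, residuals = y - fitted, y = y
  ), class = "pls_qsar")
}

#' @export
predict.pls_qsar <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
coef.pls_qsar <- function(object, ...) object$coefficients

#' @export
residuals.pls_qsar <- function(object, ...) object$residuals

#' @export
fitted.pls_qsar <- function(object, ...) object$fitted.values

#' @export
print.pls_qsar <- function(x, ...) {
  cat(sprintf("PLS1 regression (NIPALS): %d components, %d descriptors, %d molecules\n",
              x$ncomp, length(x$coefficients), length(x$y)))
  cat(sprintf("  R2 (fitted) = %.4f\n", r_squared(x$y, x$fitted.values)))
  invisible(x)
}

#' Leave-one-out cross-validated Q2
#'
#' For each molecule, the PLS model is refit on the remaining molecules and
#' the held-out response predicted;
#' \eqn{Q^2 = 1 - PRESS / \sum (obs - \bar{obs})^2}. A \eqn{Q^2 > 0.5} is
#' the conventional threshold for reliable internal predictivity; on the
#' same training data \eqn{Q^2 \le R^2}.
#'
#' @inheritParams pls_fit
#' @return the LOO cross-validated determination coefficient.
#' @export
loo_q2 <- function(X, y, ncomp = 2, scale. = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop_validation("LOO Q2 needs at least 4 molecules")
  if (ncomp >= n - 1)
    stop_validation("ncomp must be below n_molecules - 1 for LOO")
  press <- 0
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], ncomp = ncomp,
                   scale. = scale.)
    press <- press + (y[i] - predict(fit, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' External-validation determination coefficient
#'
#' Measures predictivity on an external test set. Three labelled variants
#' are provided because published values do not always state which
#' convention was used: \code{"standard"},
#' \eqn{1 - \sum (obs_t - pred_t)^2 / \sum (obs_t - \bar{obs}_{train})^2}
#' (test-set deviations measured about the training mean);
#' \code{"sd_testmean"}, the same with the test-set mean in the
#' denominator; \code{"pearson2"}, the squared Pearson correlation of
#' observed and predicted test values.
#'
#' @param train_observed observed responses of the training set.
#' @param test_observed,test_predicted observed and predicted responses of
#'   the external test set (\eqn{\ge} 3 pairs).
#' @param formula variant label.
#' @return the coefficient, with the variant in attribute \code{"formula"}.
#' @export
external_r2_pred <- function(train_observed, test_observed, test_predicted,
                             formula = c("standard", "sd_testmean",
                                         "pearson2")) {
  formula <- match.arg(formula)
  if (length(test_observed) < 3 ||
      length(test_observed) != length(test_predicted))
    stop_validation("need at least 3 matched test pairs")
  press <- sum((test_observed - test_predicted)^2)
  val <- switch(formula,
    standard = {
      den <- sum((test_observed - mean(train_observed))^2)
      if (den == 0)
        stop_validation("degenerate denominator: test responses all equal ",
                        "the training mean")
      1 - press / den
    },
    sd_testmean = {
      den <- sum((test_observed - mean(test_observed))^2)
      if (den == 0)
        stop_validation("degenerate denominator: constant test responses")
      1 - press / den
    },
    pearson2 = {
      if (stats::sd(test_observed) == 0 || stats::sd(test_predicted) == 0)
        stop_validation("degenerate variance for correlation")
      stats::cor(test_observed, test_predicted)^2
    })
  structure(val, formula = formula)
}

#' Standard error of prediction on an external test set
#' @param test_observed,test_predicted matched test-set responses.
#' @return \eqn{\sqrt{\sum (obs - pred)^2 / n}}.
#' @export
sep_external <- function(test_observed, test_predicted) {
  if (!length(test_observed) ||
      length(test_observed) != length(test_predicted))
    stop_validation("need matched test pairs")
  sqrt(mean((test_observed - test_predicted)^2))
}

#' Standard error of estimate and Fischer value
#'
#' Conventional QSAR definitions with the latent components as model degrees
#' of freedom: \eqn{SEE = \sqrt{RSS / (n - N - 1)}} and
#' \eqn{F = (R^2 / N) / ((1 - R^2)/(n - N - 1))}. A perfect fit reports
#' \code{F = Inf}.
#'
#' @param observed,predicted fitted training responses.
#' @param n_components number of latent components N.
#' @return \code{list(SEE, F)}.
#' @export
see_and_f <- function(observed, predicted, n_components) {
  n <- length(observed)
  df <- n - n_components - 1
  if (df <= 0) stop_validation("non-positive degrees of freedom")
  rss <- sum((observed - predicted)^2)
  r2 <- r_squared(observed, predicted)
  Fval <- if (r2 == 1) Inf else (r2 / n_components) / ((1 - r2) / df)
  list(SEE = sqrt(rss / df), F = Fval)
}

#' Recompute the published relative errors of the reference pairs
#'
#' Recomputes \code{relative_error} for every packaged reference
#' activity pair and compares with the published relative-error column.
#'
#' @param model \code{"all"} or one of the three model names.
#' @param tolerance allowed absolute deviation in percentage points
#'   (default 0.01).
#' @param error_on_mismatch abort with a discrepancy report naming molecule
#'   and model if any row deviates beyond tolerance.
#' @return data.frame of pairs with \code{rel_err_recomputed} (full
#'   precision), \code{rel_err_printed} and \code{deviation} columns.
#' @examples
#' v <- validate_qsar_reference()
#' max(v$deviation)
#' @export
validate_qsar_reference <- function(model = "all", tolerance = 0.01,
                                    error_on_mismatch = TRUE) {
  x <- qsar_reference_pairs(model)
  x$rel_err_recomputed <- relative_error(x$observed, x$predicted)
  x$deviation <- abs(x$rel_err_recomputed - x$rel_err_printed)
  bad <- x[x$deviation > tolerance, , drop = FALSE]
  if (nrow(bad) && error_on_mismatch)
    stop_validation("relative-error mismatch beyond ", tolerance,
                    " for: ", paste(sprintf("%s/%s", bad$model,
                                            bad$molecule), collapse = ", "))
  x
}

#' Full validation report for one descriptor/response model
#'
#' Fits PLS on the training molecules, then assembles the internal
#' (\eqn{Q^2}, \eqn{R^2}, SEE, F) and external (\eqn{R^2_{pred}} in all
#' three variants, SEP) validation statistics plus per-molecule relative
#' errors — the full evaluation battery for one QSAR endpoint model.
#'
#' @param X descriptor matrix for all molecules (rows named or ordered as
#'   \code{y}).
#' @param y response vector.
#' @param split character vector, \code{"training"}/\code{"test"} per row.
#' @param ncomp latent components.
#' @param scale. scale descriptors.
#' @return object of class \code{qsar_validation}: list with \code{Q2},
#'   \code{N}, \code{R2}, \code{SEE}, \code{F}, \code{R2_pred} (named
#'   3-vector), \code{SEP}, \code{relative_errors} and the fitted model.
#' @export
qsar_validation_report <- function(X, y, split, ncomp = 2, scale. = FALSE) {
  X <- as.matrix(X)
  if (!all(split %in% c("training", "test")))
    stop_validation("split must be 'training' or 'test'")
  tr <- split == "training"; te <- !tr
  if (sum(te) < 3) stop_validation("need at least 3 test molecules")
  fit <- pls_fit(X[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                 scale. = scale.)
  pred_all <- predict(fit, X)
  sf <- see_and_f(y[tr], pred_all[tr], ncomp)
  r2p <- vapply(c("standard", "sd_testmean", "pearson2"), function(fm)
    as.numeric(external_r2_pred(y[tr], y[te], pred_all[te], fm)),
    numeric(1))
  structure(list(
    Q2 = loo_q2(X[tr, , drop = FALSE], y[tr], ncomp = ncomp,
                scale. = scale.),
    N = ncomp,
    R2 = r_squared(y[tr], pred_all[tr]),
    SEE = sf$SEE, F = sf$F,
    R2_pred = r2p,
    SEP = sep_external(y[te], pred_all[te]),
    relative_errors = relative_error(y, pred_all),
    model = fit
  ), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat(sprintf(
    "QSAR validation: Q2 = %.3f, N = %d, R2 = %.3f, SEE = %.3f, F = %.1f\n",
    x$Q2, x$N, x$R2, x$SEE, x$F))
  cat(sprintf("  external: R2_pred = %.3f (standard) / %.3f (test-mean) / %.3f (pearson2), SEP = %.3f\n",
              x$R2_pred["standard"], x$R2_pred["sd_testmean"],
              x$R2_pred["pearson2"], x$SEP))
  invisible(x)
}
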