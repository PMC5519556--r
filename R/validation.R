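# Internal: OLS coefficients on an intercept-augmented design (fast path for
# the cross-validation loops).
.ols_coef <- function(X, y) {
  qr.coef(qr(cbind(1, X)), y)
}

#' Cross-validated predictive squared correlation (Q2)
#'
#' Internal validation by iterated held-out refitting:
#' \describe{
#'   \item{`loo`}{leave-one-out -- each row held out once.}
#'   \item{`lto`}{leave-two-out -- all `choose(n, 2)` unordered pairs are
#'     enumerated and both rows of each pair predicted from the remaining
#'     n - 2.}
#'   \item{`lmo`}{leave-many-out -- `repeats` random holdouts of
#'     `lmo_fraction` of the rows; predictions are pooled across repeats.}
#' }
#' In every scheme \eqn{Q^2 = 1 - \sum(y_i - \hat y_i)^2 / \sum(y_i -
#' \bar y)^2} with \eqn{\bar y} the mean of the *full* training response (not
#' the per-fold mean), and the sums run over all pooled held-out predictions.
#' `rmse_cv` is the root mean squared held-out error on the same pool.
#'
#' @param X Regressor data.frame/matrix (no intercept column).
#' @param y Numeric response.
#' @param scheme `"loo"`, `"lto"` or `"lmo"`.
#' @param lmo_fraction Fraction of rows held out per LMO repeat (default 0.2).
#' @param repeats Number of LMO repeats (default 1000).
#' @param seed Optional integer seed for the LMO holdout draws.
#' @return List with `q2`, `rmse_cv`, `scheme`, `n_models`.
#' @examples
#' d <- single_chemical_descriptors(antibiotic_toxicity(), "luc_litr")
#' cross_validate(d$X, d$y, "loo")$q2
#' @export
cross_validate <- function(X, y, scheme = c("loo", "lto", "lmo"),
                           lmo_fraction = 0.2, repeats = 1000, seed = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  holdouts <- switch(scheme,
    loo = as.list(seq_len(n)),
    lto = {
      prs <- utils::combn(n, 2)
      lapply(seq_len(ncol(prs)), function(k) prs[, k])
    },
    lmo = {
      k <- max(1L, round(lmo_fraction * n))
      draw <- function() sample.int(n, k)
      if (!is.null(seed)) {
        withr::with_seed(seed, replicate(repeats, draw(), simplify = FALSE))
      } else {
        replicate(repeats, draw(), simplify = FALSE)
      }
    }
  )
  min_train <- n - max(lengths(holdouts))
  if (min_train <= p + 1)
    stop(sprintf("held-out folds leave only %d rows to fit %d regressors",
                 min_train, p), call. = FALSE)
  obs <- numeric(0)
  pred <- numeric(0)
  for (idx in holdouts) {
    beta <- .ols_coef(X[-idx, , drop = FALSE], y[-idx])
    if (anyNA(beta))
      stop("singular design in a cross-validation fold", call. = FALSE)
    yhat <- drop(cbind(1, X[idx, , drop = FALSE]) %*% beta)
    obs <- c(obs, y[idx])
    pred <- c(pred, yhat)
  }
  press <- sum((obs - pred)^2)
  denom <- sum((obs - mean(y))^2)
  list(q2 = 1 - press / denom,
       rmse_cv = sqrt(press / length(obs)),
       scheme = scheme,
       n_models = length(holdouts))
}

#' Random train/test split
#'
#' Splits `n` rows into disjoint, exhaustive training and test index sets.
#' The training set receives `floor(fraction_train * n)` rows (an 81-row panel
#' at 0.8 gives the 64/17 split used for the mixture models). Deterministic
#' for a fixed seed.
#'
#' @param n Number of rows (>= 2), or a data.frame whose rows are split.
#' @param fraction_train Training fraction, default 0.8.
#' @param seed Optional integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, fraction_train = 0.8, seed = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  n_train <- max(1L, min(n - 1L, floor(fraction_train * n)))
  perm <- if (!is.null(seed)) withr::with_seed(seed, sample.int(n)) else
    sample.int(n)
  train <- sort(perm[seq_len(n_train)])
  list(train = train, test = sort(setdiff(seq_len(n), train)))
}

#' External validation: Q2F1 and RMSEP on a held-out test set
#'
#' \eqn{Q^2_{F1} = 1 - \sum(Y_i - \hat Y_i)^2 / \sum(Y_i - \bar y_{train})^2}
#' over the test rows, with the denominator centred on the *training* mean, so
#' a model that merely predicts the training mean scores 0. RMSEP is the plain
#' root mean squared prediction error (division by the test size, no
#' degrees-of-freedom correction).
#'
#' @param model A `qstr_fit` fitted on the training set.
#' @param test_X Test regressors (same columns as the model's design).
#' @param test_y Test responses.
#' @param train_mean Mean of the training responses; defaults to the mean of
#'   the model's own response vector.
#' @return List with `q2_f1`, `rmsep`, `n_test`.
#' @export
external_q2f1 <- function(model, test_X, test_y, train_mean = mean(model$y)) {
  if (length(test_y) < 1) stop("empty test set", call. = FALSE)
  denom <- sum((test_y - train_mean)^2)
  if (denom == 0)
    stop("degenerate test set: all responses equal the training mean",
         call. = FALSE)
  yhat <- predict(model, test_X)
  list(q2_f1 = 1 - sum((test_y - yhat)^2) / denom,
       rmsep = sqrt(mean((test_y - yhat)^2)),
       n_test = length(test_y))
}

#' Williams-plot applicability-domain diagnostics
#'
#' Computes, for each training row, the leverage (diagonal of the hat matrix
#' of the intercept-augmented training design) and, for each optional test
#' row, the same quadratic form evaluated at its descriptor vector.
#' Standardized residuals are raw residuals divided by the model RMSE (the
#' "3 delta" convention). Rows with leverage above the warning value
#' \eqn{h^* = 3(m + 1)/n} (m descriptors, n training rows) are flagged as
#' high-leverage; rows with |standardized residual| > 3 as response outliers.
#' Points inside both bounds lie in the model's applicability domain.
#'
#' @param train A `qstr_fit` (its design, residuals and RMSE are used), or a
#'   numeric matrix of training regressors if `train_resid` and `rmse` are
#'   supplied.
#' @param test_X,test_resid Optional test regressors and their raw prediction
#'   residuals.
#' @param train_resid,rmse Raw training residuals and model RMSE, required
#'   when `train` is a bare matrix.
#' @return Object of class `williams_ad`: a data.frame (`row_id`, `set`,
#'   `leverage`, `std_residual`, `high_leverage`, `outlier`) with attributes
#'   `h_star`, `m`, `n_train`.
#' @export
williams_ad <- function(train, test_X = NULL, test_resid = NULL,
                        train_resid = NULL, rmse = NULL) {
  if (inherits(train, "qstr_fit")) {
    train_X <- train$X
    train_resid <- train$residuals
    rmse <- train$rmse
  } else {
    train_X <- as.matrix(train)
    if (is.null(train_resid) || is.null(rmse))
      stop("train_resid and rmse are required when train is a matrix",
           call. = FALSE)
  }
  n <- nrow(train_X)
  m <- ncol(train_X)
  X1 <- cbind(1, train_X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1))
    stop("singular training design", call. = FALSE)
  xtx_inv <- chol2inv(qr.R(qrx))
  lev_train <- rowSums((X1 %*% xtx_inv) * X1)
  h_star <- 3 * (m + 1) / n
  out <- data.frame(
    row_id = if (!is.null(rownames(train_X))) rownames(train_X) else
      as.character(seq_len(n)),
    set = "train",
    leverage = lev_train,
    std_residual = train_resid / rmse,
    stringsAsFactors = FALSE
  )
  if (!is.null(test_X)) {
    test_X <- as.matrix(test_X)
    if (is.null(test_resid) || length(test_resid) != nrow(test_X))
      stop("test_resid must accompany test_X, one per row", call. = FALSE)
    T1 <- cbind(1, test_X)
    out <- rbind(out, data.frame(
      row_id = if (!is.null(rownames(test_X))) rownames(test_X) else
        paste0("test_", seq_len(nrow(test_X))),
      set = "test",
      leverage = rowSums((T1 %*% xtx_inv) * T1),
      std_residual = test_resid / rmse,
      stringsAsFactors = FALSE
    ))
  }
  out$high_leverage <- out$leverage > h_star
  out$outlier <- abs(out$std_residual) > 3
  rownames(out) <- NULL
  structure(out, h_star = h_star, m = m, n_train = n,
            class = c("williams_ad", "data.frame"))
}

#' @export
print.williams_ad <- function(x, ...) {
  cat(sprintf(
    "Williams applicability domain: %d train / %d test rows, h* = %.4g (m = %d)\n",
    sum(x$set == "train"), sum(x$set == "test"), attr(x, "h_star"),
    attr(x, "m")))
  flagged <- x[x$high_leverage | x$outlier, , drop = FALSE]
  if (nrow(flagged)) {
    cat("Flagged rows:\n")
    print.data.frame(flagged)
  } else {
    cat("All rows inside the applicability domain.\n")
  }
  invisible(x)
}

#' Plot a Williams applicability-domain diagram
#'
#' Leverage against standardized residual, with the warning leverage
#' \eqn{h^*} as a vertical line and the +/-3 residual bounds as horizontal
#' lines.
#'
#' @param x A `williams_ad` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.williams_ad <- function(x, ...) {
  graphics::plot(x$leverage, x$std_residual,
                 pch = ifelse(x$set == "train", 16, 1),
                 xlab = "Leverage h", ylab = "Standardized residual",
                 ylim = range(c(-3.5, 3.5, x$std_residual)),
                 xlim = range(c(0, attr(x, "h_star") * 1.2, x$leverage)), ...)
  graphics::abline(v = attr(x, "h_star"), lty = 2)
  graphics::abline(h = c(-3, 3), lty = 2)
  graphics::legend("topright", pch = c(16, 1), legend = c("train", "test"),
                   bty = "n")
  invisible(x)
}
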