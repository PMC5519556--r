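#' Descriptor matrix for the single-chemical QSTR schemes
#'
#' Builds the regressor matrix and the response \eqn{\lg(K_c/K_a)} for one of
#' the three single-chemical model forms:
#' \describe{
#'   \item{`luc_litr`}{luciferase and LitR interaction energies -- the
#'     mechanism pair (acute action on luciferase, chronic action on the
#'     quorum-sensing regulator).}
#'   \item{`luc_target`}{luciferase and the class-specific chronic target
#'     protein energy.}
#'   \item{`moving_average`}{target-class-centred deviations
#'     \eqn{\Delta E^{Luc}} and \eqn{\Delta E^{T}} (see
#'     [moving_average_descriptors()]).}
#' }
#'
#' @param chems A `toxicity_dataset`.
#' @param scheme One of `"luc_litr"`, `"luc_target"`, `"moving_average"`.
#' @return List with `X` (data.frame of named regressors, rownames = abbr)
#'   and `y` (numeric response \eqn{\lg(K_c/K_a)}).
#' @export
single_chemical_descriptors <- function(chems, scheme = c("luc_litr",
                                                          "luc_target",
                                                          "moving_average")) {
  scheme <- match.arg(scheme)
  y <- log_slope_ratio(chems)
  X <- switch(scheme,
    luc_litr   = data.frame(e_luc = chems$e_luc, e_litr = chems$e_litr),
    luc_target = data.frame(e_luc = chems$e_luc, e_target = chems$e_target),
    moving_average = data.frame(
      delta_e_luc    = moving_average_descriptors(chems$e_luc, chems$chem_class),
      delta_e_target = moving_average_descriptors(chems$e_target, chems$chem_class)
    )
  )
  rownames(X) <- chems$abbr
  list(X = X, y = y)
}

#' Moving-average (group-centred) energy descriptors
#'
#' \eqn{\Delta E_{ij} = E_i - \overline{E}_{j(i)}}: each chemical's interaction
#' energy minus the mean energy over all chemicals sharing its target class.
#' Centring removes the between-target offset so chemicals acting on different
#' proteins become comparable; the group-wise mean of the result is zero.
#'
#' @param e Numeric energies (kcal/mol), one per chemical.
#' @param groups Target-class labels, same length as `e`.
#' @return Numeric \eqn{\Delta E} deviations.
#' @export
moving_average_descriptors <- function(e, groups) {
  stopifnot(length(e) == length(groups))
  e - stats::ave(e, groups)
}

#' Ordinary least squares with QSTR reporting statistics
#'
#' Fits `y ~ intercept + X` and reports the statistics used throughout the
#' package: \eqn{R^2 = 1 - SS_{res}/SS_{tot}},
#' \eqn{RMSE = \sqrt{SS_{res}/(n - p - 1)}} (residual degrees of freedom),
#' \eqn{F = (SS_{reg}/p)/(SS_{res}/(n - p - 1))} and its p-value from the
#' F(p, n - p - 1) distribution.
#'
#' @param X Data.frame or matrix of named regressors (no intercept column).
#' @param y Numeric response.
#' @param response Name of the response used in reports.
#' @return An object of class `qstr_fit`: coefficients (intercept first), `n`,
#'   `p`, `r2`, `rmse`, `f_stat`, `p_value`, `residuals`, `fitted`, plus the
#'   training design for validation utilities.
#' @examples
#' d <- single_chemical_descriptors(antibiotic_toxicity(), "luc_litr")
#' fit_qstr(d$X, d$y)
#' @export
fit_qstr <- function(X, y, response = "lg(Kc/Ka)") {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))) || anyDuplicated(names(X)))
    stop("regressors must have unique nonempty names", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in the design", call. = FALSE)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("X and y sizes differ", call. = FALSE)
  if (n <= p + 1)
    stop(sprintf("insufficient data: n = %d rows for %d regressors (+ intercept)",
                 n, p), call. = FALSE)
  dat <- cbind(.response = y, X)
  fm <- stats::lm(.response ~ ., data = dat)
  if (any(is.na(stats::coef(fm))) || fm$rank < p + 1)
    stop("singular design: regressors are linearly dependent", call. = FALSE)
  res <- stats::resid(fm)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - ss_res
  f_stat <- (ss_reg / p) / (ss_res / (n - p - 1))
  structure(list(
    response = response,
    coefficients = stats::coef(fm),
    n = n, p = p,
    r2 = 1 - ss_res / ss_tot,
    rmse = sqrt(ss_res / (n - p - 1)),
    f_stat = f_stat,
    p_value = stats::pf(f_stat, p, n - p - 1, lower.tail = FALSE),
    residuals = unname(res),
    fitted = unname(stats::fitted(fm)),
    X = as.matrix(X), y = y
  ), class = "qstr_fit")
}

#' @export
print.qstr_fit <- function(x, digits = 4, ...) {
  co <- x$coefficients
  terms <- names(co)[-1]
  rhs <- paste0(format(co[1], digits = digits),
                paste0(vapply(seq_along(terms), function(i) {
                  sprintf(" %s %s %s",
                          if (co[i + 1] < 0) "-" else "+",
                          format(abs(co[i + 1]), digits = digits), terms[i])
                }, character(1)), collapse = ""))
  cat(sprintf("%s = %s\n", x$response, rhs))
  cat(sprintf("n = %d, R2 = %.3f, RMSE = %.3f, F = %.3f, P = %.3f\n",
              x$n, x$r2, x$rmse, x$f_stat, x$p_value))
  invisible(x)
}

#' @export
predict.qstr_fit <- function(object, newdata, ...) {
  nm <- names(object$coefficients)[-1]
  newdata <- as.data.frame(newdata)
  missing <- setdiff(nm, names(newdata))
  if (length(missing))
    stop("newdata lacks regressor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  drop(cbind(1, as.matrix(newdata[nm])) %*% object$coefficients)
}

#' Fit a single-chemical slope-ratio QSTR model
#'
#' Convenience wrapper: builds the descriptors for `scheme` with
#' [single_chemical_descriptors()] and fits \eqn{\lg(K_c/K_a)} on them by OLS.
#'
#' @inheritParams single_chemical_descriptors
#' @return A `qstr_fit`.
#' @examples
#' fit_slope_ratio_model(antibiotic_toxicity(), "luc_litr")
#' @export
fit_slope_ratio_model <- function(chems, scheme = c("luc_litr", "luc_target",
                                                    "moving_average")) {
  d <- single_chemical_descriptors(chems, scheme)
  fit_qstr(d$X, d$y)
}

#' Fit the mixture slope-ratio QSTR model
#'
#' OLS of \eqn{\lg(K_c^m/K_a^m)} on the four concentration-proportion-weighted
#' interaction energies (acute-weighted luciferase energies of both
#' components, chronic-weighted LitR energies of both components).
#'
#' @param desc Data.frame from [mixture_descriptor_table()] (columns
#'   `wa_e_luc_a`, `wa_e_luc_b`, `wc_e_litr_a`, `wc_e_litr_b`,
#'   `log_slope_ratio_mix`).
#' @return A `qstr_fit`.
#' @export
fit_mixture_model <- function(desc) {
  need <- c("wa_e_luc_a", "wa_e_luc_b", "wc_e_litr_a", "wc_e_litr_b",
            "log_slope_ratio_mix")
  missing <- setdiff(need, names(desc))
  if (length(missing))
    stop("descriptor table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  fit_qstr(desc[need[1:4]], desc$log_slope_ratio_mix,
           response = "lg(Kc_m/Ka_m)")
}

#' Link between LitR and target-protein interaction energies
#'
#' Simple OLS of the LitR energy on the class-specific target-protein energy
#' across the panel. A strong link justifies substituting the mechanism-
#' agnostic LitR energy for the target energy in the chronic descriptors, so
#' one model form can serve chemicals with different (or unknown) modes of
#' action.
#'
#' @param chems A `toxicity_dataset`.
#' @return A `qstr_fit` with response `e_litr` and regressor `e_target`.
#' @export
fit_litr_target_link <- function(chems) {
  fit_qstr(data.frame(e_target = chems$e_target), chems$e_litr,
           response = "E_LitR")
}
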