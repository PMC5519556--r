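#' Bioluminescence inhibition from light readings
#'
#' Inhibition is the fractional loss of light relative to the untreated
#' control, \eqn{100 (L_0 - L_i)/L_0}. Values are bounded above by 100%
#' (complete light extinction) and may be negative when the exposed culture
#' emits more light than the control (hormetic stimulation, common at low
#' doses in the chronic assay).
#'
#' @param light_control Light intensity of the control group (> 0).
#' @param light_exposed Light intensity of the exposed group (>= 0).
#' @return Inhibition in percent.
#' @examples
#' inhibition_percent(1000, 250)   # 75% inhibition
#' inhibition_percent(1000, 1500)  # -50%: stimulation
#' @export
inhibition_percent <- function(light_control, light_exposed) {
  if (any(!is.finite(light_control)) || any(light_control <= 0))
    stop("light_control must be > 0", call. = FALSE)
  if (any(!is.finite(light_exposed)) || any(light_exposed < 0))
    stop("light_exposed must be >= 0", call. = FALSE)
  100 * (light_control - light_exposed) / light_control
}

#' Fit the linear log-dose response model
#'
#' Fits `inhibition = K * log10(concentration) + b` by ordinary least squares
#' to the observations whose inhibition falls strictly inside `window`.
#' Hormetic (negative) and saturated (100%) points fall outside the default
#' window and are excluded from the fit rather than modelled.
#'
#' @param points Data.frame with columns `concentration_mol_per_l` (> 0) and
#'   `inhibition_percent`, as in the `dose_response` schema.
#' @param window Numeric length-2: open inhibition interval retained for
#'   fitting. Default `c(0, 100)`.
#' @return An object of class `dr_fit`: a list with `slope_K` (% per decade),
#'   `intercept_b` (%), `r2`, `n_used`, `n_excluded`.
#' @examples
#' pts <- data.frame(concentration_mol_per_l = 10^seq(-4, -3, length.out = 5),
#'                   inhibition_percent = 20 * seq(-4, -3, length.out = 5) + 120)
#' fit_dose_response(pts)
#' @export
fit_dose_response <- function(points, window = c(0, 100)) {
  stopifnot(is.data.frame(points),
            all(c("concentration_mol_per_l", "inhibition_percent") %in%
                  names(points)))
  if (any(points$concentration_mol_per_l <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  keep <- points$inhibition_percent > window[1] &
    points$inhibition_percent < window[2]
  used <- points[keep, , drop = FALSE]
  if (nrow(used) < 2)
    stop("fewer than 2 points inside the inhibition window (",
         window[1], ", ", window[2], ")", call. = FALSE)
  lgc <- log10(used$concentration_mol_per_l)
  if (max(lgc) - min(lgc) < .Machine$double.eps^0.5)
    stop("all usable concentrations are equal: design is singular",
         call. = FALSE)
  fm <- stats::lm(used$inhibition_percent ~ lgc)
  ss_res <- sum(stats::resid(fm)^2)
  ss_tot <- sum((used$inhibition_percent - mean(used$inhibition_percent))^2)
  K <- unname(stats::coef(fm)[2])
  if (K <= 0)
    stop("fitted slope K is not positive: inhibition does not increase with dose",
         call. = FALSE)
  structure(list(
    slope_K = K,
    intercept_b = unname(stats::coef(fm)[1]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n_used = nrow(used),
    n_excluded = nrow(points) - nrow(used)
  ), class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("Linear dose-response fit: Inhibition(%%) = %.4g * lgC + %.4g\n",
              x$slope_K, x$intercept_b))
  cat(sprintf("  r2 = %.4f, n = %d used (%d excluded), -lgEC50 = %.4g\n",
              x$r2, x$n_used, x$n_excluded, neg_log_ec50(x)))
  invisible(x)
}

#' Potency at 50% inhibition from a linear dose-response fit
#'
#' Solves `K * lgC + b = 50` for the log10 concentration of half-maximal
#' inhibition and returns its negative, \eqn{-\lg EC_{50} = (b - 50)/K}. With
#' K > 0 and test concentrations below 1 mol/L this is positive. (Written with
#' the numerator as 50 - b, the same relation gives the signed lgEC50; the
#' sign cancels in all downstream ratio identities.)
#'
#' @param fit A `dr_fit`, or any list with elements `slope_K` and
#'   `intercept_b`.
#' @return The dimensionless potency \eqn{-\lg EC_{50}} (mol/L basis).
#' @seealso [potency_intercept()] for the inverse relation.
#' @export
neg_log_ec50 <- function(fit) {
  K <- fit$slope_K
  b <- fit$intercept_b
  if (!is.finite(K) || K == 0) stop("slope K must be nonzero", call. = FALSE)
  (b - 50) / K
}

#' Intercept implied by a slope and a potency
#'
#' Inverse of [neg_log_ec50()]: `b = 50 + K * neg_log_ec50`, the intercept of
#' the dose-response line that crosses 50% inhibition at the stated potency.
#'
#' @param slope_K Slope in % per log10 concentration decade.
#' @param neg_log_ec50 Potency \eqn{-\lg EC_{50}}.
#' @return Intercept b in %.
#' @export
potency_intercept <- function(slope_K, neg_log_ec50) {
  50 + slope_K * neg_log_ec50
}

#' Log ratio of chronic to acute dose-response slopes
#'
#' \eqn{\lg(K_c/K_a)} quantifies how much steeper the chronic dose-response
#' curve is than the acute one; it is the response variable of all the QSTR
#' regressions in this package and is positive for every chemical in the
#' reference panel.
#'
#' @param x A `toxicity_dataset` row(s) or any data.frame with `slope_acute`
#'   and `slope_chronic`, or a numeric vector `slope_chronic` when `ka` is
#'   given.
#' @param ka Optional numeric acute slope(s) when `x` is the chronic slope.
#' @return Numeric \eqn{\log_{10}(K_c/K_a)}.
#' @examples
#' log_slope_ratio(antibiotic_toxicity())
#' @export
log_slope_ratio <- function(x, ka = NULL) {
  if (is.data.frame(x)) {
    kc <- x$slope_chronic
    ka <- x$slope_acute
  } else {
    kc <- x
  }
  if (any(!is.finite(ka)) || any(ka <= 0) || any(!is.finite(kc)) || any(kc <= 0))
    stop("slopes must be positive", call. = FALSE)
  log10(kc / ka)
}

#' Log ratio of the acute and chronic intercept terms
#'
#' Returns \eqn{\lg[(50 - b_a)/(50 - b_c)]}, the second term of the identity
#' linking acute and chronic potency:
#' \deqn{\lg(-\lg EC_{50}^a) - \lg(-\lg EC_{50}^c) = \lg(K_c/K_a) +
#'   \lg\frac{50 - b_a}{50 - b_c}.}
#' When only tabulated potencies and slopes are available (no raw fitted
#' intercepts) the same quantity is computed through that identity as
#' \eqn{\lg(-\lg EC_{50}^a) - \lg(-\lg EC_{50}^c) - \lg(K_c/K_a)}.
#'
#' @param x Either a data.frame with columns `neg_log_ec50_acute`,
#'   `neg_log_ec50_chronic`, `slope_acute`, `slope_chronic` (tabulated route),
#'   or a `dr_fit` for the acute assay (then `chronic_fit` is required).
#' @param chronic_fit Optional `dr_fit` for the chronic assay (direct route
#'   from raw intercepts).
#' @return Numeric \eqn{\lg[(50 - b_a)/(50 - b_c)]}.
#' @export
intercept_log_ratio <- function(x, chronic_fit = NULL) {
  if (inherits(x, "dr_fit") || (is.list(x) && !is.data.frame(x) &&
                                !is.null(x$intercept_b))) {
    stopifnot(!is.null(chronic_fit))
    num <- 50 - x$intercept_b
    den <- 50 - chronic_fit$intercept_b
    if (num == 0 || den == 0)
      stop("intercept equals 50%: log ratio undefined", call. = FALSE)
    if (num / den <= 0)
      stop("(50 - b_a)/(50 - b_c) must be positive", call. = FALSE)
    return(log10(num / den))
  }
  nla <- x$neg_log_ec50_acute
  nlc <- x$neg_log_ec50_chronic
  if (any(nla <= 0) || any(nlc <= 0))
    stop("potencies must be positive for the tabulated route", call. = FALSE)
  log10(nla) - log10(nlc) - log_slope_ratio(x)
}
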