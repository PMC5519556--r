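#' Intercept-ratio law as a fixed coefficient pair
#'
#' The link between the intercept-ratio term and the slope ratio,
#' \eqn{\lg[(50 - b_a)/(50 - b_c)] = \alpha + \beta \, \lg(K_c/K_a)}, can be
#' supplied literally (for example the reference single-chemical law
#' \eqn{\alpha = 1.059, \beta = -2.504}, or the mixture law
#' \eqn{\alpha = -0.093, \beta = -1.101}) instead of being refit from raw
#' dose-response intercepts, which tabulated summaries do not always allow.
#'
#' @param alpha Intercept of the law.
#' @param beta Slope of the law (coefficient on \eqn{\lg(K_c/K_a)}).
#' @return Object of class `intercept_ratio_law`.
#' @export
intercept_ratio_law <- function(alpha = 1.059, beta = -2.504) {
  structure(list(coefficients = c(`(Intercept)` = alpha,
                                  log_slope_ratio = beta)),
            class = "intercept_ratio_law")
}

#' Refit the intercept-ratio law from a dataset
#'
#' Regresses \eqn{\lg[(50 - b_a)/(50 - b_c)]} on \eqn{\lg(K_c/K_a)}. For a
#' `toxicity_dataset` both quantities are reconstructed from the tabulated
#' potencies and slopes through the potency-ratio identity; for a mixture
#' descriptor table the columns are used directly.
#'
#' @param x A `toxicity_dataset`, or a data.frame with columns
#'   `log_slope_ratio_mix` and `intercept_log_ratio_mix`.
#' @return A `qstr_fit` with single regressor `log_slope_ratio`.
#' @export
fit_intercept_ratio_model <- function(x) {
  if (inherits(x, "toxicity_dataset")) {
    lsr <- log_slope_ratio(x)
    ilr <- intercept_log_ratio(x)
  } else {
    stopifnot(all(c("log_slope_ratio_mix", "intercept_log_ratio_mix") %in%
                    names(x)))
    lsr <- x$log_slope_ratio_mix
    ilr <- x$intercept_log_ratio_mix
  }
  fit_qstr(data.frame(log_slope_ratio = lsr), ilr,
           response = "lg((50-b_a)/(50-b_c))")
}

.law_coefficients <- function(intercept_model) {
  if (inherits(intercept_model, "intercept_ratio_law"))
    return(intercept_model$coefficients)
  if (inherits(intercept_model, "qstr_fit")) {
    if (length(intercept_model$coefficients) != 2)
      stop("intercept-ratio model must have exactly one regressor",
           call. = FALSE)
    return(intercept_model$coefficients)
  }
  stop("intercept model must be an intercept_ratio_law or a qstr_fit",
       call. = FALSE)
}

#' Compose the closed-form acute-to-chronic extrapolation model
#'
#' Chains two fitted sub-models through the potency-ratio identity
#' \deqn{\lg(-\lg EC_{50}^a) - \lg(-\lg EC_{50}^c) = \lg(K_c/K_a) +
#'   \lg\frac{50 - b_a}{50 - b_c}}
#' by exact symbolic substitution. With the intercept-ratio law
#' \eqn{y = \alpha + \beta x} and the slope-ratio model
#' \eqn{x = c_0 + \sum_k c_k E_k}, the composite is
#' \deqn{\lg(-\lg EC_{50}^c) = \lg(-\lg EC_{50}^a) - [\alpha + (1+\beta)c_0]
#'   - \sum_k (1+\beta)c_k E_k,}
#' i.e. the acute potency enters with coefficient exactly 1 and every energy
#' coefficient is an arithmetic function of the two sources. The same algebra
#' serves the single-chemical model (two energy regressors) and the mixture
#' model (four weighted regressors).
#'
#' @param slope_ratio_model A `qstr_fit` for \eqn{\lg(K_c/K_a)} (single
#'   chemicals) or \eqn{\lg(K_c^m/K_a^m)} (mixtures).
#' @param intercept_model An [intercept_ratio_law()] (coefficients supplied
#'   literally) or a `qstr_fit` with the single regressor
#'   \eqn{\lg(K_c/K_a)}.
#' @param kind `"single"` or `"mixture"`; purely descriptive metadata.
#' @return Object of class `acr_model` with elements `coefficients` (named:
#'   `lg_neg_log_ec50_acute` = 1, the energy terms, `constant`), `kind`, and
#'   `provenance` (the two source coefficient sets).
#' @examples
#' m1  <- fit_slope_ratio_model(antibiotic_toxicity(), "luc_litr")
#' law <- intercept_ratio_law(1.059, -2.504)
#' compose_extrapolation(m1, law)
#' @export
compose_extrapolation <- function(slope_ratio_model, intercept_model,
                                  kind = c("single", "mixture")) {
  kind <- match.arg(kind)
  if (!inherits(slope_ratio_model, "qstr_fit") &&
      !(is.list(slope_ratio_model) && !is.null(slope_ratio_model$coefficients)))
    stop("slope_ratio_model must provide named coefficients", call. = FALSE)
  sc <- slope_ratio_model$coefficients
  law <- .law_coefficients(intercept_model)
  alpha <- unname(law[1])
  beta <- unname(law[2])
  scale <- 1 + beta
  energy <- -scale * sc[-1]
  coef <- c(lg_neg_log_ec50_acute = 1, energy,
            constant = -(alpha + scale * unname(sc[1])))
  structure(list(
    coefficients = coef,
    kind = kind,
    provenance = list(slope_ratio = sc, intercept_ratio = c(alpha = alpha,
                                                            beta = beta))
  ), class = "acr_model")
}

#' Compose the mixture extrapolation model
#'
#' [compose_extrapolation()] specialised to the mixture pipeline: the
#' slope-ratio model must carry the four concentration-proportion-weighted
#' energy regressors.
#'
#' @param mix_slope_model A `qstr_fit` from [fit_mixture_model()].
#' @param mix_intercept_model An [intercept_ratio_law()] (e.g.
#'   `intercept_ratio_law(-0.093, -1.101)`) or a single-regressor `qstr_fit`.
#' @return An `acr_model` with `kind = "mixture"`.
#' @export
compose_mixture_extrapolation <- function(mix_slope_model,
                                          mix_intercept_model =
                                            intercept_ratio_law(-0.093, -1.101)) {
  need <- c("wa_e_luc_a", "wa_e_luc_b", "wc_e_litr_a", "wc_e_litr_b")
  have <- names(mix_slope_model$coefficients)[-1]
  if (!setequal(have, need))
    stop("mixture slope model must have the four weighted-energy regressors",
         call. = FALSE)
  compose_extrapolation(mix_slope_model, mix_intercept_model, kind = "mixture")
}

#' @export
print.acr_model <- function(x, digits = 4, ...) {
  co <- x$coefficients
  mid <- co[setdiff(names(co), c("lg_neg_log_ec50_acute", "constant"))]
  terms <- vapply(seq_along(mid), function(i) {
    sprintf(" %s %s %s", if (mid[i] < 0) "-" else "+",
            format(abs(mid[i]), digits = digits), names(mid)[i])
  }, character(1))
  cat(sprintf("Acute-to-chronic extrapolation model (%s):\n", x$kind))
  cat(sprintf("lg(-lgEC50_c) = lg(-lgEC50_a)%s %s %s\n",
              paste(terms, collapse = ""),
              if (co[["constant"]] < 0) "-" else "+",
              format(abs(co[["constant"]]), digits = digits)))
  invisible(x)
}

#' Predict chronic potency from acute potency and descriptors
#'
#' Evaluates a composed extrapolation model:
#' \eqn{\lg(-\lg EC_{50}^c)} is the acute \eqn{\lg(-\lg EC_{50}^a)} plus the
#' energy terms and the constant; the chronic potency is then
#' \eqn{-\lg EC_{50}^c = 10^{\lg(-\lg EC_{50}^c)}} and the chronic EC50 is
#' \eqn{10^{-(-\lg EC_{50}^c)}} mol/L.
#'
#' @param model An `acr_model`.
#' @param acute_neg_log_ec50 Acute potency(ies) \eqn{-\lg EC_{50}^a > 0}.
#' @param descriptors Data.frame (or named list) with one column per energy
#'   term of the model; recycled rows must match `acute_neg_log_ec50`.
#' @return Data.frame with `lg_neg_log_ec50_chronic`, `neg_log_ec50_chronic`,
#'   `ec50_chronic_mol_per_l`.
#' @examples
#' m <- compose_extrapolation(fit_slope_ratio_model(antibiotic_toxicity()),
#'                            intercept_ratio_law())
#' predict_chronic(m, 3.03, data.frame(e_luc = -31.80, e_litr = -25.46))
#' @export
predict_chronic <- function(model, acute_neg_log_ec50, descriptors) {
  if (any(!is.finite(acute_neg_log_ec50)) || any(acute_neg_log_ec50 <= 0))
    stop("acute -lgEC50 must be positive (its log must exist)", call. = FALSE)
  co <- model$coefficients
  terms <- setdiff(names(co), c("lg_neg_log_ec50_acute", "constant"))
  descriptors <- as.data.frame(descriptors)
  missing <- setdiff(terms, names(descriptors))
  if (length(missing))
    stop("descriptors lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lg_nlc <- log10(acute_neg_log_ec50) +
    drop(as.matrix(descriptors[terms]) %*% co[terms]) + co[["constant"]]
  nlc <- 10^lg_nlc
  data.frame(lg_neg_log_ec50_chronic = lg_nlc,
             neg_log_ec50_chronic = nlc,
             ec50_chronic_mol_per_l = 10^(-nlc))
}
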