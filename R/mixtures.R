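#' Equitoxic mixing ratio for a binary mixture
#'
#' Binary mixtures are prepared at the equitoxic ratio: the molar
#' concentration ratio of the two components equals the ratio of their
#' individual EC50s, so each contributes the same number of toxic units at any
#' point of the shared dilution series.
#'
#' @param ec50_a,ec50_b Individual EC50s (mol/L, > 0) of components A and B.
#' @return Named numeric vector of the two mixing proportions (shares of total
#'   molar concentration), summing to 1: `c(prop_a, prop_b)`.
#' @examples
#' equitoxic_ratio(2e-4, 1e-4)  # A dosed at twice B's concentration
#' @export
equitoxic_ratio <- function(ec50_a, ec50_b) {
  if (any(!is.finite(c(ec50_a, ec50_b))) || any(c(ec50_a, ec50_b) <= 0))
    stop("EC50s must be positive", call. = FALSE)
  tot <- ec50_a + ec50_b
  c(prop_a = ec50_a / tot, prop_b = ec50_b / tot)
}

#' Toxic units of a mixture at its 50% effect level
#'
#' \eqn{TU = \sum_i C_i / EC_{50,i}}, where \eqn{C_i} is the concentration of
#' component i when the mixture as a whole produces 50% inhibition and
#' \eqn{EC_{50,i}} is the component's individual EC50. TU = 1 is the
#' concentration-addition reference.
#'
#' @param conc_at_50 Numeric vector of component concentrations (mol/L) at the
#'   mixture's 50% effect level.
#' @param ec50_individual Numeric vector of the matching individual EC50s
#'   (mol/L), same length.
#' @return The toxic-unit sum (dimensionless, > 0).
#' @export
toxic_unit <- function(conc_at_50, ec50_individual) {
  if (length(conc_at_50) != length(ec50_individual))
    stop("component concentration and EC50 vectors differ in length",
         call. = FALSE)
  if (any(!is.finite(c(conc_at_50, ec50_individual))) ||
      any(c(conc_at_50, ec50_individual) <= 0))
    stop("concentrations and EC50s must be positive", call. = FALSE)
  sum(conc_at_50 / ec50_individual)
}

#' Classify the joint effect of a mixture from its toxic units
#'
#' TU below 0.8 indicates synergism (the mixture is more toxic than
#' concentration addition predicts), TU in the closed band 0.8--1.2 an
#' additive joint effect, and TU above 1.2 antagonism.
#'
#' @param tu Numeric toxic-unit value(s), > 0.
#' @return Character vector: `"synergism"`, `"additive"` or `"antagonism"`.
#' @examples
#' classify_joint_effect(c(0.37, 1.0, 4.5))
#' @export
classify_joint_effect <- function(tu) {
  if (any(!is.finite(tu)) || any(tu <= 0))
    stop("tu must be positive", call. = FALSE)
  ifelse(tu < 0.8, "synergism", ifelse(tu > 1.2, "antagonism", "additive"))
}

#' Concentration-proportion-weighted descriptors for a binary mixture
#'
#' Builds the four regressors of the mixture QSTR model: each component's
#' luciferase energy weighted by its *acute* apparent concentration proportion
#' and each component's LitR energy weighted by its *chronic* proportion. The
#' apparent proportion of component i is its share of the total molar
#' concentration in the equitoxic mixture for that assay, i.e.
#' \eqn{EC_{50,i}/(EC_{50,A}+EC_{50,B})} with the assay-matching individual
#' EC50s; the two proportions within an assay sum to 1.
#'
#' @param comp_a,comp_b Abbreviations of the two components (keys into
#'   `chems$abbr`).
#' @param chems A `toxicity_dataset` holding both components.
#' @return One-row data.frame with `comp_a`, `comp_b`, the acute/chronic
#'   proportions of A, and the weighted regressors `wa_e_luc_a`, `wa_e_luc_b`,
#'   `wc_e_litr_a`, `wc_e_litr_b` (kcal/mol).
#' @export
mixture_descriptors <- function(comp_a, comp_b, chems) {
  ia <- match(comp_a, chems$abbr)
  ib <- match(comp_b, chems$abbr)
  if (is.na(ia) || is.na(ib))
    stop("component(s) not found in the chemical dataset: ",
         paste(c(comp_a, comp_b)[is.na(c(ia, ib))], collapse = ", "),
         call. = FALSE)
  ec50a_a <- 10^(-chems$neg_log_ec50_acute[ia])
  ec50a_b <- 10^(-chems$neg_log_ec50_acute[ib])
  ec50c_a <- 10^(-chems$neg_log_ec50_chronic[ia])
  ec50c_b <- 10^(-chems$neg_log_ec50_chronic[ib])
  pa_a <- ec50a_a / (ec50a_a + ec50a_b)  # acute proportion of A
  pc_a <- ec50c_a / (ec50c_a + ec50c_b)  # chronic proportion of A
  data.frame(
    comp_a = comp_a, comp_b = comp_b,
    prop_a_acute = pa_a, prop_a_chronic = pc_a,
    wa_e_luc_a  = pa_a * chems$e_luc[ia],
    wa_e_luc_b  = (1 - pa_a) * chems$e_luc[ib],
    wc_e_litr_a = pc_a * chems$e_litr[ia],
    wc_e_litr_b = (1 - pc_a) * chems$e_litr[ib],
    stringsAsFactors = FALSE
  )
}

#' Regression table for a mixture panel
#'
#' Assembles, from a long mixture table (one acute and one chronic row per
#' pair, `mixtures` schema) and the single-chemical dataset, the one-row-per-
#' mixture table used by [fit_mixture_model()]: the four weighted-energy
#' regressors plus the response \eqn{\lg(K_c^m/K_a^m)}.
#'
#' @param panel Mixture table in the `mixtures` schema (e.g. from
#'   [generate_mixture_panel()] or [read_toxicity_data()]).
#' @param chems A `toxicity_dataset` with all components.
#' @return Data.frame with columns `comp_a`, `comp_b`, the four weighted
#'   regressors and `log_slope_ratio_mix`.
#' @export
mixture_descriptor_table <- function(panel, chems) {
  ac <- panel[panel$assay == "acute", ]
  ch <- panel[panel$assay == "chronic", ]
  m <- match(paste(ac$comp_a, ac$comp_b), paste(ch$comp_a, ch$comp_b))
  if (anyNA(m))
    stop("mixture panel is missing chronic rows for some pairs", call. = FALSE)
  ch <- ch[m, ]
  desc <- do.call(rbind, Map(mixture_descriptors, ac$comp_a, ac$comp_b,
                             list(chems)))
  desc$log_slope_ratio_mix <- log10(ch$slope_K / ac$slope_K)
  rownames(desc) <- NULL
  desc
}
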