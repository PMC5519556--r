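#' Configuration for the synthetic assay-data generator
#'
#' Bundles every knob of the generator with defaults that mirror the study
#' conditions of the reference panel: class-conditional interaction-energy and
#' acute-slope ranges spanning the observed 15 antibiotics, the reference
#' slope-ratio law (intercept 0.275, -0.004 on the luciferase energy, -0.011
#' on the LitR energy; residual scale 0.05), the intercept-ratio law
#' (1.059, -2.504), the mixture slope-ratio law and its intercept-ratio link
#' (-0.093, -1.101), an 81-pair mixture panel, and toxic-unit ranges per
#' class pair (additive 0.8-1.19 for SA-SA, synergistic 0.37-0.55 for SA-SAP,
#' antagonistic 1.2-4.5 for mixtures involving tetracyclines).
#'
#' @param n_per_class Named counts of chemicals per class.
#' @param energy_ranges Per-class list of kcal/mol intervals for `e_luc`,
#'   `e_target`, `e_litr`.
#' @param slope_ratio_coef Generating coefficients of \eqn{\lg(K_c/K_a)} on
#'   (1, e_luc, e_litr).
#' @param slope_ratio_noise_sd Gaussian noise sd added to \eqn{\lg(K_c/K_a)}.
#' @param ka_ranges Per-class sampling interval of the acute slope Ka.
#' @param acute_potency_range Interval for the acute \eqn{-\lg EC_{50}}.
#' @param intercept_ratio `c(alpha, beta)` of the single-chemical
#'   intercept-ratio law.
#' @param dose_n Number of concentrations per dose-response series.
#' @param dose_margin Margin beyond the 0--100% crossing interval, as a
#'   fraction of that interval's log-concentration width.
#' @param dose_noise_sd Gaussian observation noise on inhibition (%).
#' @param hormesis Add low-dose stimulatory (negative-inhibition) points to
#'   chronic series.
#' @param mixture_coef Generating coefficients of \eqn{\lg(K_c^m/K_a^m)} on
#'   (1, wa_e_luc_a, wa_e_luc_b, wc_e_litr_a, wc_e_litr_b).
#' @param mixture_noise_sd Gaussian noise sd on \eqn{\lg(K_c^m/K_a^m)}.
#' @param mixture_intercept_ratio `c(alpha, beta)` of the mixture
#'   intercept-ratio law.
#' @param mixture_ka_range Sampling interval of the mixture acute slope.
#' @param tu_laws Named list of acute toxic-unit sampling intervals per class
#'   pair (`"SA-SA"`, `"SA-SAP"`, `"SA-TC"`, `"SAP-TC"`).
#' @param n_mixtures Maximum number of binary pairs in a panel.
#' @param seed Default seed used by the generators when none is passed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_per_class = c(SA = 8, SAP = 2, TC = 5),
    energy_ranges = list(
      SA  = list(e_luc = c(-40, -27), e_target = c(-35, -24),
                 e_litr = c(-32, -25)),
      SAP = list(e_luc = c(-39, -37), e_target = c(-39, -35),
                 e_litr = c(-32, -28)),
      TC  = list(e_luc = c(-61, -50), e_target = c(-41, -32),
                 e_litr = c(-42, -38))
    ),
    slope_ratio_coef = c(`(Intercept)` = 0.275, e_luc = -0.004,
                         e_litr = -0.011),
    slope_ratio_noise_sd = 0.05,
    ka_ranges = list(SA = c(37, 72), SAP = c(169, 177), TC = c(89, 156)),
    acute_potency_range = c(2.7, 4.5),
    intercept_ratio = c(alpha = 1.059, beta = -2.504),
    dose_n = 9,
    dose_margin = 0.25,
    dose_noise_sd = 2,
    hormesis = TRUE,
    mixture_coef = c(`(Intercept)` = 1.009, wa_e_luc_a = -0.007,
                     wa_e_luc_b = -2.056e-4, wc_e_litr_a = 0.021,
                     wc_e_litr_b = 0.012),
    mixture_noise_sd = 0.03,
    mixture_intercept_ratio = c(alpha = -0.093, beta = -1.101),
    mixture_ka_range = c(40, 180),
    tu_laws = list(`SA-SA` = c(0.8, 1.19), `SA-SAP` = c(0.37, 0.55),
                   `SA-TC` = c(1.2, 4.5), `SAP-TC` = c(1.2, 4.5)),
    n_mixtures = 81,
    seed = NULL) {
  cfg <- list(n_per_class = n_per_class, energy_ranges = energy_ranges,
              slope_ratio_coef = slope_ratio_coef,
              slope_ratio_noise_sd = slope_ratio_noise_sd,
              ka_ranges = ka_ranges,
              acute_potency_range = acute_potency_range,
              intercept_ratio = intercept_ratio,
              dose_n = dose_n, dose_margin = dose_margin,
              dose_noise_sd = dose_noise_sd, hormesis = hormesis,
              mixture_coef = mixture_coef,
              mixture_noise_sd = mixture_noise_sd,
              mixture_intercept_ratio = mixture_intercept_ratio,
              mixture_ka_range = mixture_ka_range,
              tu_laws = tu_laws, n_mixtures = n_mixtures, seed = seed)
  stopifnot(all(names(cfg$n_per_class) %in% names(.class_targets)),
            slope_ratio_noise_sd >= 0, mixture_noise_sd >= 0,
            dose_noise_sd >= 0, dose_n >= 2,
            diff(acute_potency_range) >= 0)
  for (rg in cfg$tu_laws) stopifnot(length(rg) == 2, rg[1] > 0, rg[2] >= rg[1])
  class(cfg) <- "generator_config"
  cfg
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate a synthetic single-chemical toxicity dataset
#'
#' Draws interaction energies uniformly within the class-conditional ranges,
#' generates \eqn{\lg(K_c/K_a)} from the configured slope-ratio law plus
#' Gaussian noise, samples the acute slope and potency within their ranges,
#' and derives the chronic slope and potency so the dataset is exactly
#' self-consistent under the potency-ratio identity: \eqn{K_c = K_a \cdot
#' 10^{\lg(K_c/K_a)}} and \eqn{\lg(-\lg EC_{50}^c) = \lg(-\lg EC_{50}^a) -
#' \lg(K_c/K_a) - [\alpha + \beta\,\lg(K_c/K_a)]}.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed (defaults to `cfg$seed`); fixes the full output.
#' @return A validated `toxicity_dataset`.
#' @examples
#' chems <- generate_chemicals(generator_config(), seed = 1)
#' fit_slope_ratio_model(chems, "luc_litr")
#' @export
generate_chemicals <- function(cfg = generator_config(), seed = cfg$seed) {
  .with_seed(seed, {
    rows <- lapply(names(cfg$n_per_class), function(cl) {
      k <- cfg$n_per_class[[cl]]
      if (k == 0) return(NULL)
      er <- cfg$energy_ranges[[cl]]
      e_luc <- stats::runif(k, er$e_luc[1], er$e_luc[2])
      e_target <- stats::runif(k, er$e_target[1], er$e_target[2])
      e_litr <- stats::runif(k, er$e_litr[1], er$e_litr[2])
      lgr <- cfg$slope_ratio_coef[[1]] +
        cfg$slope_ratio_coef[["e_luc"]] * e_luc +
        cfg$slope_ratio_coef[["e_litr"]] * e_litr +
        stats::rnorm(k, 0, cfg$slope_ratio_noise_sd)
      ka <- stats::runif(k, cfg$ka_ranges[[cl]][1], cfg$ka_ranges[[cl]][2])
      nla <- stats::runif(k, cfg$acute_potency_range[1],
                          cfg$acute_potency_range[2])
      ilr <- cfg$intercept_ratio[["alpha"]] +
        cfg$intercept_ratio[["beta"]] * lgr
      nlc <- 10^(log10(nla) - lgr - ilr)
      data.frame(
        abbr = sprintf("%s%02d", cl, seq_len(k)),
        name = sprintf("synthetic %s %02d", cl, seq_len(k)),
        chem_class = cl,
        neg_log_ec50_acute = nla, slope_acute = ka,
        neg_log_ec50_chronic = nlc, slope_chronic = ka * 10^lgr,
        e_luc = e_luc, e_target = e_target, e_litr = e_litr,
        target_protein = .class_targets[[cl]],
        stringsAsFactors = FALSE
      )
    })
    validate_chemicals(do.call(rbind, rows))
  })
}

#' Generate a synthetic dose-response series
#'
#' Concentrations are evenly log-spaced across the interval where the
#' chemical's linear model crosses 0% and 100% inhibition, widened on both
#' sides by `dose_margin` times that interval's width (so steep chronic
#' curves, whose full response spans a fraction of a decade, are sampled as
#' densely as shallow acute ones). Inhibition is the line value plus Gaussian
#' noise, truncated at 100%. For chronic series with `hormesis = TRUE`, two
#' low-dose points with stimulatory (negative) inhibition are appended; they
#' fall outside the default fitting window of [fit_dose_response()].
#'
#' @param record One row of a `toxicity_dataset`.
#' @param assay `"acute"` or `"chronic"`.
#' @param cfg A [generator_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return Data.frame in the `dose_response` schema.
#' @export
generate_dose_response <- function(record, assay = c("acute", "chronic"),
                                   cfg = generator_config(),
                                   seed = cfg$seed) {
  assay <- match.arg(assay)
  K <- if (assay == "acute") record$slope_acute else record$slope_chronic
  nl <- if (assay == "acute") record$neg_log_ec50_acute else
    record$neg_log_ec50_chronic
  b <- potency_intercept(K, nl)
  lg0 <- -b / K            # 0% crossing
  lg100 <- (100 - b) / K   # 100% crossing
  width <- lg100 - lg0
  .with_seed(seed, {
    lgc <- seq(lg0 - cfg$dose_margin * width, lg100 + cfg$dose_margin * width,
               length.out = cfg$dose_n)
    inh <- pmin(100, K * lgc + b + stats::rnorm(cfg$dose_n, 0,
                                                cfg$dose_noise_sd))
    if (isTRUE(cfg$hormesis) && assay == "chronic") {
      lgc <- c(lg0 - c(1.5, 0.75) * width, lgc)
      inh <- c(-stats::runif(2, 2, 15), inh)
    }
    data.frame(chem_abbr = record$abbr, assay = assay,
               concentration_mol_per_l = 10^lgc,
               inhibition_percent = inh,
               stringsAsFactors = FALSE)
  })
}

# All unordered component pairs whose class pair has a TU law, component A
# carrying the first class of the pair label.
.default_pair_plan <- function(chems, tu_laws) {
  pairs <- list()
  for (lab in names(tu_laws)) {
    cls <- strsplit(lab, "-", fixed = TRUE)[[1]]
    a_set <- chems$abbr[chems$chem_class == cls[1]]
    b_set <- chems$abbr[chems$chem_class == cls[2]]
    if (cls[1] == cls[2]) {
      if (length(a_set) >= 2) {
        cmb <- utils::combn(a_set, 2)
        pairs[[lab]] <- data.frame(comp_a = cmb[1, ], comp_b = cmb[2, ],
                                   class_pair = lab, stringsAsFactors = FALSE)
      }
    } else if (length(a_set) && length(b_set)) {
      grid <- expand.grid(comp_a = a_set, comp_b = b_set,
                          stringsAsFactors = FALSE)
      grid$class_pair <- lab
      pairs[[lab]] <- grid
    }
  }
  do.call(rbind, c(pairs, list(make.row.names = FALSE)))
}

#' Generate a synthetic equitoxic binary-mixture panel
#'
#' For each component pair: the acute toxic unit is drawn from the class-pair
#' law and fixes the acute mixture EC50 on the total molar concentration
#' scale, \eqn{EC_{50m}^a = TU^a (EC_{50,A}^a + EC_{50,B}^a)/2} (a consequence
#' of the equitoxic design); the mixture slope ratio \eqn{\lg(K_c^m/K_a^m)} is
#' generated from the configured mixture law on the four proportion-weighted
#' energies plus noise; and the chronic mixture EC50 is derived through the
#' mixture intercept-ratio law and the potency-ratio identity, so the whole
#' chain from descriptors to chronic potency is exercised end-to-end. The
#' chronic toxic unit is then computed from the resulting chronic EC50s.
#'
#' @param chems A `toxicity_dataset` supplying the components.
#' @param cfg A [generator_config()].
#' @param pairs Optional data.frame with columns `comp_a`, `comp_b`,
#'   `class_pair`; defaults to all pairs covered by `cfg$tu_laws`, truncated
#'   to `cfg$n_mixtures`.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return Data.frame in the `mixtures` schema: one acute and one chronic row
#'   per pair.
#' @examples
#' chems <- generate_chemicals(generator_config(), seed = 1)
#' panel <- generate_mixture_panel(chems, seed = 2)
#' table(panel$assay, panel$joint_effect)
#' @export
generate_mixture_panel <- function(chems, cfg = generator_config(),
                                   pairs = NULL, seed = cfg$seed) {
  if (is.null(pairs)) {
    pairs <- .default_pair_plan(chems, cfg$tu_laws)
    if (nrow(pairs) > cfg$n_mixtures) pairs <- pairs[seq_len(cfg$n_mixtures), ]
  }
  if (!all(pairs$class_pair %in% names(cfg$tu_laws)))
    stop("pair plan references class pair(s) without a TU law: ",
         paste(setdiff(pairs$class_pair, names(cfg$tu_laws)), collapse = ", "),
         call. = FALSE)
  if (!all(c(pairs$comp_a, pairs$comp_b) %in% chems$abbr))
    stop("pair plan references unknown chemical(s)", call. = FALSE)
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- chems[chems$abbr == pairs$comp_a[i], ]
      b <- chems[chems$abbr == pairs$comp_b[i], ]
      ec50a <- c(10^(-a$neg_log_ec50_acute), 10^(-b$neg_log_ec50_acute))
      ec50c <- c(10^(-a$neg_log_ec50_chronic), 10^(-b$neg_log_ec50_chronic))
      prop_a <- ec50a / sum(ec50a)   # acute equitoxic proportions
      prop_c <- ec50c / sum(ec50c)   # chronic equitoxic proportions
      desc <- mixture_descriptors(a$abbr, b$abbr, chems)
      lgr <- sum(cfg$mixture_coef * c(1, desc$wa_e_luc_a, desc$wa_e_luc_b,
                                      desc$wc_e_litr_a, desc$wc_e_litr_b)) +
        stats::rnorm(1, 0, cfg$mixture_noise_sd)
      tu_range <- cfg$tu_laws[[pairs$class_pair[i]]]
      tu_a <- stats::runif(1, tu_range[1], tu_range[2])
      ec50m_a <- tu_a * sum(ec50a) / 2
      nl_a <- -log10(ec50m_a)
      ilr <- cfg$mixture_intercept_ratio[["alpha"]] +
        cfg$mixture_intercept_ratio[["beta"]] * lgr
      nl_c <- 10^(log10(nl_a) - lgr - ilr)
      ec50m_c <- 10^(-nl_c)
      tu_c <- toxic_unit(ec50m_c * prop_c, ec50c)
      ka_m <- stats::runif(1, cfg$mixture_ka_range[1], cfg$mixture_ka_range[2])
      kc_m <- ka_m * 10^lgr
      data.frame(
        comp_a = a$abbr, comp_b = b$abbr,
        assay = c("acute", "chronic"),
        slope_K = c(ka_m, kc_m),
        intercept_b = c(potency_intercept(ka_m, nl_a),
                        potency_intercept(kc_m, nl_c)),
        neg_log_ec50_mix = c(nl_a, nl_c),
        conc_a_at_50 = c(ec50m_a * prop_a[1], ec50m_c * prop_c[1]),
        conc_b_at_50 = c(ec50m_a * prop_a[2], ec50m_c * prop_c[2]),
        tu = c(tu_a, tu_c),
        joint_effect = classify_joint_effect(c(tu_a, tu_c)),
        stringsAsFactors = FALSE
      )
    })
    validate_mixtures(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  })
}
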