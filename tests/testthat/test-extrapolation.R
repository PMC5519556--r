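printed_single_law <- intercept_ratio_law(1.059, -2.504)

test_that("substituting the reference sub-models reproduces the printed composite", {
  slope_model <- list(coefficients = c(`(Intercept)` = 0.275, e_luc = -0.004,
                                       e_litr = -0.011))
  m <- compose_extrapolation(slope_model, printed_single_law)
  co <- m$coefficients
  expect_equal(unname(co["lg_neg_log_ec50_acute"]), 1)
  expect_equal(unname(co["constant"]), -(1.059 + (1 - 2.504) * 0.275),
               tolerance = 1e-12)
  # rounded to the printed precision: -0.645, -0.006, -0.017
  expect_equal(round(unname(co["constant"]), 3), -0.645)
  expect_equal(round(unname(co["e_luc"]), 3), -0.006)
  expect_equal(round(unname(co["e_litr"]), 3), -0.017)
  expect_equal(unname(co["e_luc"]), -0.006016, tolerance = 1e-12)
  expect_equal(unname(co["e_litr"]), -0.016544, tolerance = 1e-12)
})

test_that("mixture composition reproduces the printed mixture composite", {
  mix_slope <- list(coefficients = c(`(Intercept)` = 1.009,
                                     wa_e_luc_a = -0.007,
                                     wa_e_luc_b = -2.056e-4,
                                     wc_e_litr_a = 0.021,
                                     wc_e_litr_b = 0.012))
  m <- compose_extrapolation(mix_slope, intercept_ratio_law(-0.093, -1.101),
                             kind = "mixture")
  co <- m$coefficients
  expect_equal(round(unname(co["constant"]), 3), 0.195)
  expect_equal(unname(co["wa_e_luc_a"]), -7.07e-4, tolerance = 1e-8)
  expect_equal(unname(co["wa_e_luc_b"]), -2.07656e-5, tolerance = 1e-8)
  expect_equal(round(unname(co["wc_e_litr_a"]), 3), 0.002)
  expect_equal(round(unname(co["wc_e_litr_b"]), 3), 0.001)
})

test_that("composition degenerates correctly at the algebraic limits", {
  slope_model <- list(coefficients = c(`(Intercept)` = 0.4, e_luc = -0.01,
                                       e_litr = 0.02))
  # beta = -1: all energy terms cancel
  m <- compose_extrapolation(slope_model, intercept_ratio_law(0.3, -1))
  expect_equal(unname(m$coefficients["e_luc"]), 0)
  expect_equal(unname(m$coefficients["e_litr"]), 0)
  expect_equal(unname(m$coefficients["constant"]), -0.3)

  # zero everywhere: identity extrapolation, chronic = acute
  ident <- compose_extrapolation(
    list(coefficients = c(`(Intercept)` = 0, e_luc = 0, e_litr = 0)),
    intercept_ratio_law(0, 0))
  pred <- predict_chronic(ident, c(2.5, 3.8),
                          data.frame(e_luc = c(-30, -40), e_litr = c(-25, -35)))
  expect_equal(pred$neg_log_ec50_chronic, c(2.5, 3.8), tolerance = 1e-12)
})

test_that("composite evaluation equals chaining the two sub-models", {
  cfg <- generator_config()
  chems <- generate_chemicals(cfg, seed = 31)
  slope_fit <- fit_slope_ratio_model(chems, "luc_litr")
  ilr_fit <- fit_intercept_ratio_model(chems)
  m <- compose_extrapolation(slope_fit, ilr_fit)

  X <- data.frame(e_luc = chems$e_luc, e_litr = chems$e_litr)
  one_shot <- predict_chronic(m, chems$neg_log_ec50_acute,
                              X)$lg_neg_log_ec50_chronic
  # two-stage route through the potency-ratio identity
  lgr_hat <- predict(slope_fit, X)
  ilr_hat <- predict(ilr_fit, data.frame(log_slope_ratio = lgr_hat))
  two_stage <- log10(chems$neg_log_ec50_acute) - lgr_hat - ilr_hat
  expect_equal(one_shot, two_stage, tolerance = 1e-12)
})

test_that("noiseless synthetic systems are extrapolated exactly end-to-end", {
  cfg <- noiseless_config()
  chems <- generate_chemicals(cfg, seed = 41)
  m <- compose_extrapolation(fit_slope_ratio_model(chems, "luc_litr"),
                             fit_intercept_ratio_model(chems))
  pred <- predict_chronic(m, chems$neg_log_ec50_acute,
                          data.frame(e_luc = chems$e_luc,
                                     e_litr = chems$e_litr))
  expect_equal(pred$neg_log_ec50_chronic, chems$neg_log_ec50_chronic,
               tolerance = 1e-6)

  # mixture chain
  panel <- generate_mixture_panel(chems, cfg, seed = 42)
  dt <- mixture_descriptor_table(panel, chems)
  mix_fit <- fit_mixture_model(dt)
  mm <- compose_mixture_extrapolation(mix_fit,
                                      intercept_ratio_law(-0.093, -1.101))
  ac <- panel[panel$assay == "acute", ]
  ch <- panel[panel$assay == "chronic", ]
  predm <- predict_chronic(mm, ac$neg_log_ec50_mix,
                           dt[c("wa_e_luc_a", "wa_e_luc_b",
                                "wc_e_litr_a", "wc_e_litr_b")])
  expect_equal(predm$neg_log_ec50_chronic, ch$neg_log_ec50_mix,
               tolerance = 1e-6)
})

test_that("evaluating the printed composite on a reference chemical", {
  # rounded printed coefficients, applied to SD's acute data
  printed <- structure(list(coefficients = c(lg_neg_log_ec50_acute = 1,
                                             e_luc = -0.006, e_litr = -0.017,
                                             constant = -0.645)),
                       class = "acr_model")
  pred <- predict_chronic(printed, 3.03,
                          data.frame(e_luc = -31.80, e_litr = -25.46))
  expect_equal(pred$lg_neg_log_ec50_chronic, 0.4601, tolerance = 1e-4)
  expect_equal(pred$neg_log_ec50_chronic, 2.884, tolerance = 1e-3)
})

test_that("predictions are monotone in acute potency and reject bad input", {
  m <- compose_extrapolation(
    list(coefficients = c(`(Intercept)` = 0.275, e_luc = -0.004,
                          e_litr = -0.011)), printed_single_law)
  desc <- data.frame(e_luc = -35, e_litr = -30)
  acute <- seq(0.5, 6, by = 0.25)
  pred <- predict_chronic(m, acute, desc[rep(1, length(acute)), ])
  expect_true(all(diff(pred$neg_log_ec50_chronic) > 0))
  expect_error(predict_chronic(m, -1, desc), "positive")
  expect_error(predict_chronic(m, 3, data.frame(e_luc = -35)), "e_litr")
})

test_that("composition validates the shapes of its inputs", {
  slope_model <- list(coefficients = c(`(Intercept)` = 0.275, e_luc = -0.004,
                                       e_litr = -0.011))
  two_reg <- fit_qstr(data.frame(a = rnorm(10), b = rnorm(10)), rnorm(10))
  expect_error(compose_extrapolation(slope_model, two_reg), "one regressor")
  mix_bad <- fit_qstr(data.frame(a = rnorm(10), b = rnorm(10)), rnorm(10))
  expect_error(compose_mixture_extrapolation(mix_bad), "weighted-energy")
})
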