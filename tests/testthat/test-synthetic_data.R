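test_that("generation is deterministic under a fixed config and seed", {
  cfg <- generator_config(seed = 99)
  a <- generate_chemicals(cfg)
  b <- generate_chemicals(cfg)
  expect_identical(a, b)
  pa <- generate_mixture_panel(a, cfg)
  pb <- generate_mixture_panel(b, cfg)
  expect_identical(pa, pb)
  da <- generate_dose_response(a[1, ], "chronic", cfg)
  expect_identical(da, generate_dose_response(a[1, ], "chronic", cfg))
  expect_false(identical(a, generate_chemicals(cfg, seed = 100)))
})

test_that("generated chemicals respect class structure and record invariants", {
  cfg <- generator_config()
  chems <- generate_chemicals(cfg, seed = 7)  # validated on construction
  expect_equal(as.vector(table(chems$chem_class)[c("SA", "SAP", "TC")]),
               c(8L, 2L, 5L))
  for (cl in c("SA", "SAP", "TC")) {
    sub <- chems[chems$chem_class == cl, ]
    er <- cfg$energy_ranges[[cl]]
    expect_true(all(sub$e_luc >= er$e_luc[1] & sub$e_luc <= er$e_luc[2]))
    expect_true(all(sub$slope_acute >= cfg$ka_ranges[[cl]][1] &
                      sub$slope_acute <= cfg$ka_ranges[[cl]][2]))
  }
  expect_true(all(chems$slope_chronic > chems$slope_acute))
})

test_that("noiseless generation makes the slope-ratio law identifiable", {
  chems <- generate_chemicals(noiseless_config(), seed = 13)
  fit <- fit_slope_ratio_model(chems, "luc_litr")
  expect_equal(unname(fit$coefficients), c(0.275, -0.004, -0.011),
               tolerance = 1e-8)
})

test_that("the potency-ratio identity holds exactly on generated data", {
  for (seed in c(3, 17)) {
    chems <- generate_chemicals(generator_config(), seed = seed)
    lgr <- log_slope_ratio(chems)
    lhs <- log10(chems$neg_log_ec50_acute) - log10(chems$neg_log_ec50_chronic)
    rhs <- lgr + intercept_log_ratio(chems)
    expect_equal(lhs, rhs, tolerance = 1e-12)

    panel <- generate_mixture_panel(chems, generator_config(), seed = seed + 1)
    ac <- panel[panel$assay == "acute", ]
    ch <- panel[panel$assay == "chronic", ]
    lhs_m <- log10(ac$neg_log_ec50_mix) - log10(ch$neg_log_ec50_mix)
    rhs_m <- log10(ch$slope_K / ac$slope_K) +
      log10((50 - ac$intercept_b) / (50 - ch$intercept_b))
    expect_equal(lhs_m, rhs_m, tolerance = 1e-12)
  }
})

test_that("default-noise panels land in the generating fit-quality regime", {
  r2 <- vapply(1:200, function(s) {
    fit_slope_ratio_model(generate_chemicals(generator_config(), seed = s),
                          "luc_litr")$r2
  }, numeric(1))
  expect_gt(median(r2), 0.6)
  expect_lt(median(r2), 0.95)
})

test_that("generating coefficients are recovered within 3 SE at default noise", {
  hits <- vapply(1:200, function(s) {
    chems <- generate_chemicals(generator_config(), seed = s)
    d <- single_chemical_descriptors(chems, "luc_litr")
    fm <- lm(d$y ~ ., data = d$X)
    se <- coef(summary(fm))[, 2]
    all(abs(coef(fm) - c(0.275, -0.004, -0.011)) <= 3 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dose-response series reproduce their generating curve", {
  cfg <- noiseless_config()
  chems <- generate_chemicals(cfg, seed = 5)
  for (assay in c("acute", "chronic")) {
    dr <- generate_dose_response(chems[3, ], assay, cfg, seed = 6)
    fit <- fit_dose_response(dr)
    K_true <- if (assay == "acute") chems$slope_acute[3] else
      chems$slope_chronic[3]
    nl_true <- if (assay == "acute") chems$neg_log_ec50_acute[3] else
      chems$neg_log_ec50_chronic[3]
    expect_equal(fit$slope_K, K_true, tolerance = 1e-9)
    expect_equal(neg_log_ec50(fit), nl_true, tolerance = 1e-9)
  }
})

test_that("noisy dose-response series recover potency within 0.1 log units", {
  cfg <- generator_config()  # inhibition noise sd 2%
  rec <- generate_chemicals(cfg, seed = 1)[1, ]
  hits <- vapply(1:500, function(s) {
    dr <- generate_dose_response(rec, "acute", cfg, seed = s)
    abs(neg_log_ec50(fit_dose_response(dr)) - rec$neg_log_ec50_acute) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("hormetic points are negative and excluded by the default window", {
  cfg <- generator_config(hormesis = TRUE)
  rec <- generate_chemicals(cfg, seed = 8)[1, ]
  dr <- generate_dose_response(rec, "chronic", cfg, seed = 9)
  expect_true(any(dr$inhibition_percent < 0))
  fit <- fit_dose_response(dr)
  expect_gte(fit$n_excluded, sum(dr$inhibition_percent < 0))
  # acute series carry no hormetic points
  dra <- generate_dose_response(rec, "acute", cfg, seed = 9)
  expect_equal(nrow(dra), cfg$dose_n)
})

test_that("mixture panels follow the class-pair joint-effect plan", {
  cfg <- generator_config()
  chems <- generate_chemicals(cfg, seed = 15)
  panel <- generate_mixture_panel(chems, cfg, seed = 16)
  expect_equal(nrow(panel), 2 * cfg$n_mixtures)
  expect_true(all(panel$tu > 0))

  ac <- panel[panel$assay == "acute", ]
  cls <- setNames(chems$chem_class, chems$abbr)
  pair_lab <- paste(cls[ac$comp_a], cls[ac$comp_b], sep = "-")
  # acute TU draws respect each class pair's configured law
  expect_true(all(ac$joint_effect[pair_lab == "SA-SAP"] == "synergism"))
  expect_true(all(ac$joint_effect[pair_lab == "SA-SA"] == "additive"))
  expect_true(all(ac$joint_effect[pair_lab == "SA-TC"] == "antagonism"))
  expect_error(generate_mixture_panel(chems, cfg,
                                      pairs = data.frame(comp_a = "SA01",
                                                         comp_b = "TC01",
                                                         class_pair = "TC-TC")),
               "TU law")
})

test_that("external predictivity of generated panels matches the design regime", {
  cfg <- generator_config()
  q2 <- vapply(1:20, function(s) {
    chems <- generate_chemicals(cfg, seed = s)
    panel <- generate_mixture_panel(chems, cfg, seed = s + 1000)
    dt <- mixture_descriptor_table(panel, chems)
    sp <- split_train_test(nrow(dt), 0.8, seed = s + 2000)
    fit <- fit_mixture_model(dt[sp$train, ])
    external_q2f1(fit, dt[sp$test, c("wa_e_luc_a", "wa_e_luc_b",
                                     "wc_e_litr_a", "wc_e_litr_b")],
                  dt$log_slope_ratio_mix[sp$test])$q2_f1
  }, numeric(1))
  expect_gt(median(q2), 0.6)
  expect_lt(median(q2), 0.95)
})
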