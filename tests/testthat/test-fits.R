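# Model-fitting behavior at reduced sampler settings; the full-size
# convergence and recovery properties live in test-acceptance.R.

test_that("the defense fit is reproducible and correctly structured", {
  juv <- simulate_main_experiment(generator_config(seed = 51))
  sub <- juv[juv$instar == 2, ]
  cfg <- fast_config(seed = 5)
  fit <- fit_defense_model(sub, config = cfg)
  expect_s3_class(fit, "defense_fit")
  # fixed effects in design order; no separate pedestal intercept
  expect_identical(fit$fixed[1], "N_(Intercept)")
  expect_false("P_(Intercept)" %in% parameters(fit$draws))
  expect_equal(length(fit$fixed), 7 + 6)
  expect_equal(dim(fit$draws$draws)[1:2], c(200, 2))
  expect_true(all(pooled_draws(fit$draws, "sigma_N") > 0))
  tau1 <- pooled_draws(fit$draws, "tau[1]")
  tau2 <- pooled_draws(fit$draws, "tau[2]")
  expect_true(all(tau1 < tau2))
  fit2 <- fit_defense_model(sub, config = cfg)
  expect_identical(fit$draws$draws, fit2$draws$draws)
  fit3 <- fit_defense_model(sub, config = fast_config(seed = 6))
  expect_false(identical(fit$draws$draws, fit3$draws$draws))
})

test_that("the defense fit recovers strong generating signals", {
  juv <- simulate_main_experiment(generator_config(seed = 52))
  fit <- fit_defense_model(juv[juv$instar == 2, ],
                           config = fast_config(seed = 7, iters = 600))
  # kairomone induces instar-2 neckteeth (true coefficient +2.4)
  ci <- credible_interval(fit$draws, "N_kairomone1", 0.95)
  expect_gt(ci[1], 0)
  expect_lt(abs(median(pooled_draws(fit$draws, "N_kairomone1")) - 2.4), 1.2)
  # kairomone raises the pedestal (true +2.5)
  expect_gt(credible_interval(fit$draws, "P_kairomone1", 0.95)[1], 0)
})

test_that("the morphometric fit recovers coefficients, scales and correlations", {
  juv <- simulate_main_experiment(generator_config(seed = 53))
  cfg <- fast_config(seed = 8, iters = 600)
  fit <- fit_morpho_model(juv, config = cfg)
  expect_s3_class(fit, "morpho_fit")
  expect_equal(length(fit$fixed), 3 * 15)
  med <- function(p) median(pooled_draws(fit$draws, p))
  expect_equal(med("BL_(Intercept)"), 0.67, tolerance = 0.02)
  expect_equal(med("BL_instar2"), 0.20, tolerance = 0.1)
  expect_lt(med("BL_uvr1"), 0)
  expect_equal(med("sd[BL]"), 0.035, tolerance = 0.25)
  expect_gt(med("cor[BL,BW]"), 0.5)
  fit2 <- fit_morpho_model(juv, config = cfg)
  expect_identical(fit$draws$draws, fit2$draws$draws)
})

test_that("the morphometric fit augments missing trait components", {
  juv <- simulate_main_experiment(generator_config(seed = 54))
  set.seed(99)
  holes <- sample(nrow(juv), 60)
  juv$body_width_mm[holes[1:30]] <- NA
  juv$spina_length_mm[holes[31:60]] <- NA
  fit <- fit_morpho_model(juv, config = fast_config(seed = 9))
  expect_equal(median(pooled_draws(fit$draws, "BL_(Intercept)")), 0.67,
               tolerance = 0.02)
  # all-missing records are dropped with a message
  juv2 <- juv
  juv2[1, c("body_length_mm", "body_width_mm", "spina_length_mm")] <- NA
  expect_message(fit_morpho_model(juv2, config = fast_config(seed = 9)),
                 "dropped")
})

test_that("the pooled effectivity model finds kairomone but no UVR degradation", {
  eff <- simulate_effectivity_experiment(generator_config(seed = 55))
  fit <- fit_effectivity_model(eff, config = fast_config(seed = 10,
                                                         iters = 600))
  hyp <- effectivity_hypotheses(fit)
  expect_equal(nrow(hyp), 4)
  kvc <- hyp[hyp$hypothesis == "kairomone_vs_control", ]
  expect_true(all(kvc$strong))
  expect_true(all(kvc$median > 0))
  uvp <- hyp[hyp$hypothesis == "uvr_vs_par", ]
  expect_false(any(uvp$strong))
  # evidence ratios point the right way: for the null (no UVR-PAR
  # difference) above 1, against the null for kairomone induction below 1
  expect_true(all(uvp$evidence_ratio > 1))
  expect_true(all(kvc$evidence_ratio < 1))
})

test_that("forest plots render from fits without error", {
  juv <- simulate_main_experiment(generator_config(seed = 56))
  fit <- fit_defense_model(juv[juv$instar == 1, ], config = fast_config(11))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, width = 600, height = 400)
  out <- plot_effect_summary(fit)
  grDevices::dev.off()
  expect_s3_class(out, "effect_summary")
  expect_true(file.size(path) > 0)
})
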