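test_that("Savage-Dickey ratio is near 1 when posterior equals prior", {
  set.seed(41)
  prior_draws <- rnorm(20000, 0, 10)
  er <- savage_dickey_ratio(prior_draws)
  expect_equal(er$evidence_ratio, 1, tolerance = 0.1)
  expect_equal(er$prior_density_at_point, dnorm(0, 0, 10))
})

test_that("Savage-Dickey ratio vanishes when posterior mass leaves the null", {
  set.seed(42)
  er <- savage_dickey_ratio(rnorm(5000, 5, 0.1))
  expect_lt(er$evidence_ratio, 1e-6)
  expect_error(savage_dickey_ratio(rnorm(50)), "100 draws")
})

test_that("kernel Savage-Dickey matches the conjugate analytic ratio within 5%", {
  # y ~ N(mu, 1), mu ~ N(0, 10^2): closed-form posterior density at 0
  set.seed(43)
  y <- rnorm(30, 0.4, 1)
  prior_sd <- 10
  post_var <- 1 / (length(y) + 1 / prior_sd^2)
  post_mean <- post_var * sum(y)
  analytic <- dnorm(0, post_mean, sqrt(post_var)) / dnorm(0, 0, prior_sd)
  draws <- rnorm(2e5, post_mean, sqrt(post_var))
  er <- savage_dickey_ratio(draws)
  expect_lt(abs(er$evidence_ratio - analytic) / analytic, 0.05)
  # the normal-approximation fallback agrees too
  er_norm <- savage_dickey_ratio(draws, method = "normal")
  expect_lt(abs(er_norm$evidence_ratio - analytic) / analytic, 0.05)
})

test_that("evidence accumulates with data toward the true hypothesis", {
  # conjugate model: as n grows with a true coefficient of 0 the ratio
  # increases; with a large true coefficient it tends to 0
  ratio_at <- function(true_mu, n, seed) {
    set.seed(seed)
    y <- rnorm(n, true_mu, 1)
    post_var <- 1 / (n + 1 / 100)
    post_mean <- post_var * sum(y)
    draws <- rnorm(5e4, post_mean, sqrt(post_var))
    savage_dickey_ratio(draws)$evidence_ratio
  }
  null_ratios <- vapply(c(10, 100, 1000), function(n) ratio_at(0, n, 44),
                        numeric(1))
  expect_true(all(diff(null_ratios) > 0))
  alt_ratios <- vapply(c(5, 20, 80), function(n) ratio_at(0.5, n, 45),
                       numeric(1))
  expect_true(all(diff(alt_ratios) < 0))
  expect_lt(alt_ratios[3], 0.01)
})

test_that("strong effects are exactly the parameters whose 95% CI excludes 0", {
  set.seed(46)
  arr <- array(c(runif(1000, 0.2, 0.9),            # strictly positive
                 runif(1000, -0.1, 0.4),           # straddles 0
                 c(rep(0, 200), runif(800, 0.1, 0.4))),  # endpoint at 0
               dim = c(500, 2, 3),
               dimnames = list(NULL, NULL, c("pos", "straddle", "boundary")))
  pd <- posterior_draws(arr, sampler_config(2, 1000, 500))
  flags <- classify_strong_effects(pd)
  expect_true(flags[["pos"]])
  expect_false(flags[["straddle"]])
  # 2.5% quantile of "boundary" is exactly 0: counts as including 0
  expect_equal(unname(credible_interval(pd, "boundary", 0.95)[1]), 0)
  expect_false(flags[["boundary"]])

  # internal consistency with credible_interval for every parameter
  for (p in parameters(pd)) {
    ci <- credible_interval(pd, p, 0.95)
    expect_identical(unname(flags[p]), ci[1] > 0 || ci[2] < 0)
  }
})

test_that("effect summary tables are structured, ordered and deterministic", {
  set.seed(47)
  arr <- array(rnorm(500 * 2 * 3, mean = rep(c(1, 0, -2), each = 1000)),
               dim = c(500, 2, 3),
               dimnames = list(NULL, NULL, c("b1", "b2", "b3")))
  pd <- posterior_draws(arr, sampler_config(2, 1000, 500))
  tbl <- effect_summary_table(pd, parameters = c("b1", "b2", "b3"))
  expect_equal(nrow(tbl), 3)
  expect_identical(tbl$parameter, c("b1", "b2", "b3"))
  expect_true(all(c("median", "ci50_low", "ci95_high", "strong",
                    "evidence_ratio") %in% names(tbl)))
  expect_true(tbl$strong[3])
  expect_false(tbl$strong[2])
  tbl2 <- effect_summary_table(pd, parameters = c("b1", "b2", "b3"))
  expect_identical(tbl, tbl2)

  # degenerate parameter: point mass
  arr0 <- array(0.3, dim = c(200, 2, 1), dimnames = list(NULL, NULL, "c"))
  pd0 <- posterior_draws(arr0, sampler_config(2, 400, 200))
  tbl0 <- effect_summary_table(pd0, parameters = "c")
  expect_equal(tbl0$median, 0.3)
  expect_equal(tbl0$ci95_low, 0.3)
  expect_equal(tbl0$ci95_high, 0.3)
  expect_true(tbl0$strong)
})

test_that("linear contrasts carry the implied normal prior", {
  set.seed(48)
  arr <- array(rnorm(2000 * 2, sd = 0.3) + rep(c(1, 2), each = 2000),
               dim = c(1000, 2, 2), dimnames = list(NULL, NULL, c("p1", "p2")))
  pd <- posterior_draws(arr, sampler_config(2, 2000, 1000))
  ct <- contrast_draws(pd, c(p1 = -1, p2 = 1))
  expect_equal(ct$prior_sd, 10 * sqrt(2))
  expect_equal(mean(ct$draws), 1, tolerance = 0.05)
})
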