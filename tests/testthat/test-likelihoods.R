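simple_design <- design_spec(list(g = c("0", "1")), 1)

one_record <- function(neckteeth, pedestal, uid = "m1") {
  data.frame(g = "0", mother_uid = uid, neckteeth = neckteeth,
             pedestal = pedestal, stringsAsFactors = FALSE)
}

zero_defense <- function(tau = c(-1, 1)) {
  defense_params(beta_N = c(0, 0), beta_P = c(0, 0), tau = tau,
                 u_N = c(m1 = 0), u_P = c(m1 = 0))
}

test_that("cumulative-logit category probabilities match closed forms", {
  p <- ordinal_category_probs(0, c(-1, 1))
  expect_equal(unname(p[1, ]), c(0.26894, 0.46212, 0.26894), tolerance = 1e-4)
  expect_equal(rowSums(ordinal_category_probs(c(-2, 0.7, 3), c(-0.3, 1.2))),
               rep(1, 3))
  p_inf <- ordinal_category_probs(50, c(-1, 1))
  expect_equal(unname(p_inf[1, ]), c(0, 0, 1), tolerance = 1e-12)
  # increasing eta moves mass toward C
  pc <- ordinal_category_probs(seq(-3, 3, by = 0.5), c(-1, 1))[, "C"]
  expect_true(all(diff(pc) > 0))
  expect_error(ordinal_category_probs(0, c(1, -1)), "tau")
})

test_that("binomial neckteeth log-likelihood matches closed forms", {
  expect_equal(binomial_count_loglik(5, 0), log(1 / 32), tolerance = 1e-4)
  expect_equal(binomial_count_loglik(2, 0), log(10 / 32), tolerance = 1e-4)
  expect_equal(binomial_count_loglik(5, log(3)), 5 * log(0.75),
               tolerance = 1e-4)
  expect_error(binomial_count_loglik(6, 0), "0..5")
})

test_that("the bivariate defense likelihood is the sum of both trait terms", {
  ll <- defense_joint_loglik(one_record(5, "C"), zero_defense(),
                             simple_design)
  expect_equal(ll, log(1 / 32) + log(0.26894), tolerance = 1e-4)
  expect_equal(ll, -4.7791, tolerance = 1e-4)

  # total probability over all 18 outcomes, via the likelihood itself
  total <- sum(vapply(0:5, function(k) {
    sum(vapply(c("A", "B", "C"), function(ped) {
      exp(defense_joint_loglik(one_record(k, ped), zero_defense(),
                               simple_design))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)

  # additivity: doubling the dataset doubles the log-likelihood
  rec <- one_record(3, "B")
  expect_equal(defense_joint_loglik(rbind(rec, rec), zero_defense(),
                                    simple_design),
               2 * defense_joint_loglik(rec, zero_defense(), simple_design))
  expect_error(defense_joint_loglik(one_record(3, "B", uid = "unknown"),
                                    zero_defense(), simple_design),
               "mother_uid")
})

test_that("enumerated joint outcome probabilities sum to one for random parameters", {
  set.seed(99)
  for (rep in 1:20) {
    eta_N <- rnorm(1, 0, 3)
    eta_P <- rnorm(1, 0, 3)
    tau <- sort(rnorm(2, 0, 2))
    if (tau[1] == tau[2]) next
    probs <- defense_outcome_probs(eta_N, eta_P, tau)
    expect_equal(dim(probs), c(6, 3))
    expect_true(all(probs >= 0))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("truncated multivariate normal density matches closed forms", {
  # univariate: orthant probability 1/2
  expect_equal(truncated_mvn_loglik(1, 0, matrix(1)), log(2 * dnorm(1)),
               tolerance = 1e-8)
  # bivariate independent: orthant probability 1/4
  expect_equal(truncated_mvn_loglik(c(1, 1), c(0, 0), diag(2)),
               2 * dnorm(1, log = TRUE) + log(4), tolerance = 1e-8)
  # outside the positive orthant
  expect_equal(truncated_mvn_loglik(c(-1, 1), c(0, 0), diag(2)), -Inf)
  expect_error(truncated_mvn_loglik(c(1, 1), c(0, 0),
                                    matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  # normalizing constant approaches 1 deep inside the orthant
  mu <- c(5, 5, 5)
  S <- diag(3)
  expect_equal(truncated_mvn_loglik(c(5, 5, 5), mu, S),
               truncated_mvn_loglik(c(5, 5, 5), mu, S,
                                    assume_negligible_truncation = TRUE),
               tolerance = 1e-5)
})

test_that("correlated orthant probability agrees with a Monte-Carlo oracle", {
  sds <- c(1, 0.8, 1.3)
  R <- matrix(c(1, 0.5, 0.2,
                0.5, 1, -0.3,
                0.2, -0.3, 1), 3, 3)
  S <- tcrossprod(sds) * R
  mu <- c(0.3, -0.2, 0.5)
  p <- mvn_orthant_prob(mu, S)
  set.seed(123)
  n_mc <- 2e5
  Z <- matrix(rnorm(3 * n_mc), ncol = 3) %*% chol(S)
  hits <- rowSums(sweep(Z, 2, mu, "+") > 0) == 3
  p_mc <- mean(hits)
  se <- sd(hits) / sqrt(n_mc)
  expect_lt(abs(p - p_mc), 3 * se)
  # bivariate case against its own Monte-Carlo oracle
  p2 <- mvn_orthant_prob(mu[1:2], S[1:2, 1:2])
  hits2 <- rowSums(sweep(Z[, 1:2], 2, mu[1:2], "+") > 0) == 2
  expect_lt(abs(p2 - mean(hits2)), 3 * sd(hits2) / sqrt(n_mc))
})

test_that("the morphometric likelihood handles full, partial and empty records", {
  des <- simple_design
  mp <- morpho_params(B = matrix(0, 2, 3), U = matrix(0, 1, 3,
                                                      dimnames = list("m1", NULL)),
                      sigma_u = rep(0.01, 3), Sigma = diag(3))
  rec <- data.frame(g = "0", mother_uid = "m1", body_length_mm = 1,
                    body_width_mm = 1, spina_length_mm = 1,
                    stringsAsFactors = FALSE)
  expect_equal(morpho_loglik(rec, mp, des),
               3 * (dnorm(1, log = TRUE) + log(2)), tolerance = 1e-8)
  expect_equal(morpho_loglik(rec, mp, des), -2.1774, tolerance = 1e-4)

  # marginal sub-vector density for a partially observed record
  rec_partial <- rec
  rec_partial$body_width_mm <- NA
  rec_partial$spina_length_mm <- NA
  expect_equal(morpho_loglik(rec_partial, mp, des),
               dnorm(1, log = TRUE) + log(2), tolerance = 1e-8)

  # record with nothing observed is skipped with a message
  rec_empty <- rec
  rec_empty[, c("body_length_mm", "body_width_mm", "spina_length_mm")] <- NA
  expect_message(val <- morpho_loglik(rbind(rec, rec_empty), mp, des),
                 "skipped")
  expect_equal(val, morpho_loglik(rec, mp, des), tolerance = 1e-10)

  # permutation invariance
  recs <- rbind(rec,
                transform(rec, body_length_mm = 0.8, spina_length_mm = 1.4),
                transform(rec, body_width_mm = 1.2))
  expect_equal(morpho_loglik(recs, mp, des),
               morpho_loglik(recs[c(3, 1, 2), ], mp, des), tolerance = 1e-10)
})

test_that("log priors use Normal(0,10) coefficients and ordered thresholds", {
  expect_equal(log_prior(0), -log(10 * sqrt(2 * pi)), tolerance = 1e-4)
  expect_equal(log_prior(0), -3.2215, tolerance = 1e-4)
  expect_equal(log_prior(10), -3.7215, tolerance = 1e-4)
  dp <- zero_defense()
  dp$tau <- c(1, -1)  # violates ordering after construction
  expect_equal(log_prior(dp), -Inf)
  # half-normal scale term present for defense params
  dp_ok <- zero_defense()
  expect_true(is.finite(log_prior(dp_ok)))
  mp <- morpho_params(B = matrix(0, 2, 3), Sigma = diag(0.001, 3))
  expect_true(is.finite(log_prior(mp)))
})
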