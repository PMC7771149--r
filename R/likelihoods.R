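#' Weakly informative prior specification
#'
#' All fixed-effect coefficients (and the two ordinal thresholds, subject to
#' their ordering constraint) get independent Normal(0, 10) priors; these are
#' deliberately weak on the log-odds and mm scales yet regularizing enough to
#' avoid the divergence problems flat priors cause for these models.
#' Random-intercept scales get half-Normal(0, 10) priors. The residual
#' covariance of the morphometric model gets a weakly informative
#' inverse-Wishart prior (df `cov_df`, scale matrix `cov_scale * I`), chosen
#' so the data dominate at the observed sample sizes.
#'
#' @param coef_mean,coef_sd Mean and sd of the coefficient prior.
#' @param threshold_sd Sd of the (ordered) threshold prior.
#' @param ranef_scale_sd Scale of the half-Normal prior on random-effect sds.
#' @param cov_df,cov_scale Inverse-Wishart df and diagonal scale for the 3x3
#'   residual covariance.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean = 0, coef_sd = 10, threshold_sd = 10,
                       ranef_scale_sd = 10, cov_df = 4, cov_scale = 1e-3) {
  stopifnot(coef_sd > 0, threshold_sd > 0, ranef_scale_sd > 0, cov_df > 3,
            cov_scale > 0)
  structure(list(coef_mean = coef_mean, coef_sd = coef_sd,
                 threshold_sd = threshold_sd, ranef_scale_sd = ranef_scale_sd,
                 cov_df = cov_df, cov_scale = cov_scale),
            class = "prior_spec")
}

#' Parameters of the bivariate defense-trait model
#'
#' The two linear predictors share a design matrix: `eta_N = X beta_N +
#' u_N[mother]` drives the neckteeth count (binomial with 5 trials, logit
#' link) and `eta_P = X beta_P + u_P[mother]` the pedestal class
#' (cumulative-logit with ordered thresholds `tau[1] < tau[2]`). Mother
#' random intercepts are independent between the two responses.
#'
#' @param beta_N,beta_P Named coefficient vectors (design-matrix columns).
#' @param tau Length-2 increasing threshold vector.
#' @param u_N,u_P Named per-mother random intercepts (names = mother UIDs).
#' @param sigma_N,sigma_P Positive random-effect scales.
#' @return An object of class `defense_params`.
#' @export
defense_params <- function(beta_N, beta_P, tau, u_N = numeric(0),
                           u_P = numeric(0), sigma_N = 1, sigma_P = 1) {
  if (length(tau) != 2 || !(tau[1] < tau[2])) {
    stop("tau must be two increasing thresholds (tau1 < tau2)", call. = FALSE)
  }
  if (sigma_N <= 0 || sigma_P <= 0) {
    stop("random-effect scales must be positive", call. = FALSE)
  }
  if (length(beta_N) != length(beta_P)) {
    stop("beta_N and beta_P must have equal length (shared design)",
         call. = FALSE)
  }
  structure(list(beta_N = beta_N, beta_P = beta_P, tau = as.numeric(tau),
                 u_N = u_N, u_P = u_P, sigma_N = sigma_N, sigma_P = sigma_P),
            class = "defense_params")
}

#' Parameters of the trivariate morphometric model
#'
#' @param B Coefficient matrix, one column per trait (body length, body
#'   width, spina length), rows named by design-matrix columns.
#' @param U Per-mother random-intercept matrix (mothers x 3), rows named by
#'   mother UID.
#' @param sigma_u Length-3 positive vector of random-effect scales.
#' @param Sigma 3x3 symmetric positive-definite residual covariance.
#' @return An object of class `morpho_params`.
#' @export
morpho_params <- function(B, U = NULL, sigma_u = rep(0.01, 3), Sigma) {
  B <- as.matrix(B)
  if (ncol(B) != 3) stop("B must have three trait columns", call. = FALSE)
  Sigma <- as.matrix(Sigma)
  check_spd(Sigma)
  if (is.null(U)) U <- matrix(0, 0, 3)
  if (any(sigma_u <= 0)) stop("sigma_u must be positive", call. = FALSE)
  structure(list(B = B, U = U, sigma_u = as.numeric(sigma_u), Sigma = Sigma),
            class = "morpho_params")
}

check_spd <- function(S) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance matrix must be positive definite",
                         call. = FALSE)
  invisible(TRUE)
}

#' Cumulative-logit category probabilities
#'
#' With ordered thresholds `tau[1] < tau[2]`, the cumulative probabilities
#' are `P(class <= k) = plogis(tau[k] - eta)`, giving three category
#' probabilities over A < B < C. Increasing `eta` shifts mass toward C.
#'
#' @param eta Linear predictor (vectorized).
#' @param tau Length-2 increasing thresholds.
#' @return Matrix with one row per `eta` value and columns `A`, `B`, `C`.
#' @export
ordinal_category_probs <- function(eta, tau) {
  if (length(tau) != 2 || !(tau[1] < tau[2])) {
    stop("tau must satisfy tau1 < tau2", call. = FALSE)
  }
  c1 <- stats::plogis(tau[1] - eta)
  c2 <- stats::plogis(tau[2] - eta)
  cbind(A = c1, B = c2 - c1, C = 1 - c2)
}

# log P(class = k) for integer classes 1..3, vectorized; numerically direct.
ordinal_class_loglik <- function(class_idx, eta, tau) {
  p <- ordinal_category_probs(eta, tau)
  log(pmax(p[cbind(seq_along(eta), class_idx)], 1e-300))
}

#' Binomial neckteeth log-likelihood
#'
#' Neckteeth counts take values 0..5 and are modelled as a quintuple
#' binomial trial with success probability `plogis(eta)`.
#'
#' @param k Observed counts (vectorized).
#' @param eta Linear predictor.
#' @param trials Number of trials (default 5).
#' @return Log-density, vectorized over `k`/`eta`.
#' @export
binomial_count_loglik <- function(k, eta, trials = NECKTEETH_TRIALS) {
  k <- as.integer(k)
  if (any(k < 0L | k > trials)) {
    stop("counts must lie in 0..", trials, call. = FALSE)
  }
  stats::dbinom(k, size = trials, prob = stats::plogis(eta), log = TRUE)
}

#' Joint outcome probabilities of one juvenile's defense traits
#'
#' Enumerates the 6 x 3 = 18 joint (neckteeth, pedestal) outcomes of a
#' single record given both linear predictors; the two traits are
#' conditionally independent given the predictors. Used as the enumeration
#' oracle: the entries always sum to one.
#'
#' @param eta_N,eta_P Scalar linear predictors.
#' @param tau Thresholds.
#' @param trials Binomial trials (default 5).
#' @return 6 x 3 matrix (rows: counts 0..5; columns A/B/C).
#' @export
defense_outcome_probs <- function(eta_N, eta_P, tau, trials = NECKTEETH_TRIALS) {
  pN <- stats::dbinom(0:trials, trials, stats::plogis(eta_N))
  pP <- ordinal_category_probs(eta_P, tau)[1, ]
  outer(pN, pP)
}

#' Joint log-likelihood of the bivariate defense model
#'
#' Sum over records of the cumulative-logit pedestal log-probability
#' (`eta_P = X beta_P + u_P[mother]`) and the binomial neckteeth
#' log-probability (`eta_N = X beta_N + u_N[mother]`). With
#' `include_ranef = TRUE` the Normal(0, sigma) log-densities of the mother
#' effects are added, giving the joint density of data and random effects.
#'
#' @param records Data frame with `neckteeth`, `pedestal`, `mother_uid` and
#'   the design factors.
#' @param params A [defense_params] whose `u_N`/`u_P` are named by mother UID.
#' @param design A [design_spec].
#' @param include_ranef Add the random-effect log-densities? Default FALSE
#'   (data likelihood only).
#' @return Scalar log-likelihood.
#' @export
defense_joint_loglik <- function(records, params, design,
                                 include_ranef = FALSE) {
  stopifnot(inherits(params, "defense_params"))
  X <- build_design_matrix(records, design)
  if (ncol(X) != length(params$beta_N)) {
    stop("coefficient length ", length(params$beta_N),
         " does not match design matrix with ", ncol(X), " columns",
         call. = FALSE)
  }
  uid <- as.character(records$mother_uid)
  midx <- match(uid, names(params$u_N))
  if (anyNA(midx)) {
    stop("unknown mother_uid: ", uid[which(is.na(midx))[1]], call. = FALSE)
  }
  eta_N <- drop(X %*% params$beta_N) + unname(params$u_N[midx])
  eta_P <- drop(X %*% params$beta_P) + unname(params$u_P)[
    match(uid, names(params$u_P))]
  class_idx <- as.integer(factor(as.character(records$pedestal),
                                 levels = PEDESTAL_LEVELS))
  ll <- sum(binomial_count_loglik(records$neckteeth, eta_N)) +
    sum(ordinal_class_loglik(class_idx, eta_P, params$tau))
  if (include_ranef) {
    ll <- ll + sum(stats::dnorm(params$u_N, 0, params$sigma_N, log = TRUE)) +
      sum(stats::dnorm(params$u_P, 0, params$sigma_P, log = TRUE))
  }
  ll
}

## ---- multivariate normal utilities ----------------------------------------

dmvnorm_log <- function(y, mu, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Standard bivariate normal CDF Phi2(h, k; rho) by conditioning on the first
# coordinate and adaptive quadrature; |rho| ~ 1 handled by the degenerate
# limits.
std_bvn_cdf <- function(h, k, rho) {
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(stats::pnorm(k))
    if (k == Inf) return(stats::pnorm(h))
  }
  if (rho > 1 - 1e-12) return(stats::pnorm(min(h, k)))
  if (rho < -1 + 1e-12) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) * stats::pnorm((k - rho * z) / s)
  stats::integrate(f, -Inf, h, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Positive-orthant probability of a multivariate normal
#'
#' `P(Y_1 > 0, ..., Y_d > 0)` for `Y ~ N(mu, Sigma)` with d up to 3 -- the
#' normalizing constant of the zero-truncated Gaussian trait model. Computed
#' deterministically: the closed form in one dimension, adaptive quadrature
#' over the conditioning variable in two and three dimensions (absolute
#' accuracy well below 1e-6).
#'
#' @param mu Mean vector (length 1-3).
#' @param Sigma Covariance matrix.
#' @return Scalar probability.
#' @export
mvn_orthant_prob <- function(mu, Sigma) {
  Sigma <- as.matrix(Sigma)
  d <- length(mu)
  stopifnot(nrow(Sigma) == d, ncol(Sigma) == d)
  check_spd(Sigma)
  sds <- sqrt(diag(Sigma))
  a <- mu / sds  # P(Z_i > -a_i) = Phi_d(a; R) by central symmetry
  if (d == 1) return(stats::pnorm(a))
  R <- Sigma / tcrossprod(sds)
  if (d == 2) return(std_bvn_cdf(a[1], a[2], R[1, 2]))
  if (d > 3) stop("orthant probability implemented for up to 3 dimensions",
                  call. = FALSE)
  s2 <- sqrt(1 - R[1, 2]^2)
  s3 <- sqrt(1 - R[1, 3]^2)
  rho_cond <- (R[2, 3] - R[1, 2] * R[1, 3]) / (s2 * s3)
  rho_cond <- max(-1, min(1, rho_cond))
  f <- function(z) {
    vapply(z, function(zi) {
      stats::dnorm(zi) * std_bvn_cdf((a[2] - R[1, 2] * zi) / s2,
                                     (a[3] - R[1, 3] * zi) / s3, rho_cond)
    }, numeric(1))
  }
  stats::integrate(f, -Inf, a[1], rel.tol = 1e-9, abs.tol = 1e-10)$value
}

#' Zero-truncated multivariate normal log-density
#'
#' `log phi_d(y; mu, Sigma) - log P(Y > 0 componentwise)` for `y` in the
#' positive orthant; `-Inf` outside. With `assume_negligible_truncation =
#' TRUE` the normalizing constant is taken as 1, which is exact to numerical
#' precision at the observed trait scales (means several sd above zero).
#'
#' @param y Observation vector (length 1-3).
#' @param mu Mean vector.
#' @param Sigma Covariance matrix.
#' @param assume_negligible_truncation Skip the orthant correction?
#' @return Scalar log-density.
#' @export
truncated_mvn_loglik <- function(y, mu, Sigma,
                                 assume_negligible_truncation = FALSE) {
  Sigma <- as.matrix(Sigma)
  check_spd(Sigma)
  if (any(y <= 0)) return(-Inf)
  ll <- dmvnorm_log(y, mu, Sigma)
  if (!assume_negligible_truncation) {
    ll <- ll - log(mvn_orthant_prob(mu, Sigma))
  }
  ll
}

MORPHO_TRAITS <- c("body_length_mm", "body_width_mm", "spina_length_mm")

#' Log-likelihood of the trivariate morphometric model
#'
#' One zero-truncated trivariate Gaussian per record with mean
#' `t(B) x + U[mother, ]`. Records with missing trait components contribute
#' the marginal (sub-vector) truncated density over their observed
#' components; records with all three traits missing are skipped (a message
#' reports how many).
#'
#' @param records Data frame with the three trait columns, `mother_uid` and
#'   the design factors.
#' @param params A [morpho_params] with `U` rows named by mother UID.
#' @param design A [design_spec].
#' @param assume_negligible_truncation Treat the truncation constant as 1.
#' @return Scalar log-likelihood.
#' @export
morpho_loglik <- function(records, params, design,
                          assume_negligible_truncation = FALSE) {
  stopifnot(inherits(params, "morpho_params"))
  X <- build_design_matrix(records, design)
  if (ncol(X) != nrow(params$B)) {
    stop("B has ", nrow(params$B), " rows but design matrix has ", ncol(X),
         " columns", call. = FALSE)
  }
  Y <- as.matrix(records[, MORPHO_TRAITS])
  uid <- as.character(records$mother_uid)
  midx <- match(uid, rownames(params$U))
  if (anyNA(midx)) {
    stop("unknown mother_uid: ", uid[which(is.na(midx))[1]], call. = FALSE)
  }
  Mu <- X %*% params$B + params$U[midx, , drop = FALSE]
  obs <- !is.na(Y)
  skipped <- sum(rowSums(obs) == 0)
  if (skipped > 0) {
    message(skipped, " record(s) with no observed traits skipped")
  }
  total <- 0
  norm_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(Y))) {
    o <- obs[i, ]
    if (!any(o)) next
    mu_i <- Mu[i, o]
    S_i <- params$Sigma[o, o, drop = FALSE]
    ll <- dmvnorm_log(Y[i, o], mu_i, S_i)
    if (!assume_negligible_truncation) {
      key <- paste(signif(mu_i, 12), which(o), collapse = "|")
      nc <- norm_cache[[key]]
      if (is.null(nc)) {
        nc <- log(mvn_orthant_prob(mu_i, S_i))
        norm_cache[[key]] <- nc
      }
      ll <- ll - nc
    }
    if (any(Y[i, o] <= 0)) ll <- -Inf
    total <- total + ll
  }
  unname(total)
}

## ---- priors ----------------------------------------------------------------

half_normal_logpdf <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

lmvgamma <- function(a, d) {
  (d * (d - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

inv_wishart_logpdf <- function(Sigma, df, S) {
  d <- nrow(Sigma)
  (df / 2) * determinant(S, logarithm = TRUE)$modulus -
    (df * d / 2) * log(2) - lmvgamma(df / 2, d) -
    ((df + d + 1) / 2) * determinant(Sigma, logarithm = TRUE)$modulus -
    0.5 * sum(diag(S %*% solve(Sigma)))
}

#' Log prior density of a parameter set
#'
#' Coefficients and thresholds get Normal(0, 10) terms (thresholds return
#' `-Inf` when the ordering `tau1 < tau2` is violated); random-effect scales
#' get half-Normal terms; the morphometric residual covariance gets its
#' inverse-Wishart term. Works on [defense_params], [morpho_params], or a
#' bare numeric coefficient vector.
#'
#' @param params Parameters to evaluate.
#' @param priors A [prior_spec].
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  stopifnot(inherits(priors, "prior_spec"))
  dcoef <- function(b) sum(stats::dnorm(b, priors$coef_mean, priors$coef_sd,
                                        log = TRUE))
  if (is.numeric(params) && is.null(attr(params, "class"))) {
    return(dcoef(params))
  }
  if (inherits(params, "defense_params")) {
    if (!(params$tau[1] < params$tau[2])) return(-Inf)
    return(dcoef(params$beta_N) + dcoef(params$beta_P) +
             sum(stats::dnorm(params$tau, 0, priors$threshold_sd, log = TRUE)) +
             half_normal_logpdf(params$sigma_N, priors$ranef_scale_sd) +
             half_normal_logpdf(params$sigma_P, priors$ranef_scale_sd))
  }
  if (inherits(params, "morpho_params")) {
    d <- ncol(params$B)
    return(dcoef(as.vector(params$B)) +
             sum(half_normal_logpdf(params$sigma_u, priors$ranef_scale_sd)) +
             as.numeric(inv_wishart_logpdf(params$Sigma, priors$cov_df,
                                           diag(priors$cov_scale, d))))
  }
  stop("unsupported parameter object", call. = FALSE)
}
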