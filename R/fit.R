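## Model fitting: blocked MCMC samplers for the two model families.
## The bivariate defense model runs a compiled scan (src/defense_sampler.cpp)
## of univariate slice updates on QR-orthogonalized coefficients, thresholds
## (center/gap plus a directional move), non-centered per-mother effects and
## scales; the morphometric model uses a conjugate blocked Gibbs sampler in R
## (Gaussian coefficient/random-effect draws, inverse-Wishart covariance).

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Fit the bivariate defense-trait model
#'
#' Joint Bayesian model of neckteeth counts (binomial, 5 trials, logit
#' link) and ordinal pedestal scores (cumulative logit, two ordered
#' thresholds) sharing a fixed-effect design, with independent per-mother
#' random intercepts for each response. Priors: Normal(0, 10) on all
#' coefficients and thresholds (subject to `tau1 < tau2`), half-Normal(0,
#' 10) on the random-effect scales.
#'
#' Parameters are named `N_<column>` / `P_<column>` for the two linear
#' predictors, `tau[1]`/`tau[2]`, `sigma_N`/`sigma_P`, and
#' `u_N[<mother>]`/`u_P[<mother>]`. Following the standard cumulative-logit
#' parameterization, the pedestal predictor carries no separate intercept:
#' the two thresholds act as its intercepts (a separate intercept would sit
#' on an exact likelihood ridge with them).
#'
#' @param records Data frame with `neckteeth`, `pedestal`, `mother_uid` and
#'   the design factors (either juvenile records filtered to one instar, or
#'   effectivity records).
#' @param design A [design_spec]; defaults to [defense_design_spec].
#' @param priors A [prior_spec].
#' @param config A [sampler_config].
#' @param scans Internal update scans per stored iteration (thinning; the
#'   default 3 makes stored draws close to independent at the prescribed
#'   chain lengths).
#' @return An object of class `defense_fit` containing the
#'   [posterior_draws], the fixed-effect names in design order, and the
#'   inputs needed to reproduce the fit.
#' @export
fit_defense_model <- function(records, design = defense_design_spec(),
                              priors = prior_spec(),
                              config = sampler_preset("main"),
                              scans = 3L) {
  scans <- as.integer(scans)
  stopifnot(scans >= 1)
  X <- build_design_matrix(records, design)
  n <- nrow(X)
  k <- as.integer(records$neckteeth)
  stopifnot(all(k >= 0), all(k <= NECKTEETH_TRIALS))
  class_idx <- as.integer(factor(as.character(records$pedestal),
                                 levels = PEDESTAL_LEVELS))
  uids <- sort(unique(as.character(records$mother_uid)))
  M <- length(uids)
  midx <- match(as.character(records$mother_uid), uids)
  lchk <- lchoose(NECKTEETH_TRIALS, k)

  # the cumulative-logit response carries no separate intercept: the two
  # thresholds are its intercepts (dropping the column removes an exact
  # likelihood ridge between intercept and thresholds)
  Xn <- X
  icol <- which(colnames(X) == "(Intercept)")
  Xp <- if (length(icol)) X[, -icol, drop = FALSE] else X
  pn_cols <- colnames(Xn)
  pp_cols <- colnames(Xp)
  pN <- ncol(Xn)
  pP <- ncol(Xp)

  # QR reparameterization of both design matrices: sampling runs on the
  # orthogonalized coefficients gamma = R beta (near-independent full
  # conditionals even for correlated treatment-coded columns); draws are
  # reported on the original beta scale via beta = R^-1 gamma
  csd <- priors$coef_sd
  qr_N <- qr(Xn)
  Qn <- qr.Q(qr_N)
  Rn <- qr.R(qr_N)
  qr_P <- qr(Xp)
  Qp <- qr.Q(qr_P)
  Rp <- qr.R(qr_P)
  # gamma prior precision: beta ~ N(0, csd^2 I) => gamma ~ N(0, csd^2 R R')
  An <- chol2inv(chol(tcrossprod(Rn))) / csd^2
  Ap <- chol2inv(chol(tcrossprod(Rp))) / csd^2
  pn <- c(paste0("N_", pn_cols), paste0("P_", pp_cols),
          "tau[1]", "tau[2]", "sigma_N", "sigma_P",
          paste0("u_N[", uids, "]"), paste0("u_P[", uids, "]"))
  n_keep <- config$n_iterations - config$warmup
  out <- array(NA_real_, dim = c(n_keep, config$n_chains, length(pn)),
               dimnames = list(NULL, NULL, pn))
  # translation direction for the likelihood-invariant ridge moves: adding
  # sigma*delta to every random effect while subtracting it from the linear
  # predictor (via the intercept for N, via both thresholds for P) leaves
  # the likelihood unchanged; the conditional of delta is exactly Gaussian
  qt1_N <- drop(crossprod(Qn, rep(1, n)))
  Aq_N <- drop(An %*% qt1_N)
  qAq_N <- sum(qt1_N * Aq_N)
  # dominant pedestal ridge: moving the thresholds together with the
  # (projected) overall level of the pedestal predictor; 1 is not in the
  # column space of Xp, so the projection Qp Qp' 1 is used and the move is
  # a directional slice on the joint conditional
  qt1_P <- drop(crossprod(Qp, rep(1, n)))
  p1 <- drop(Qp %*% qt1_P)
  Aq_P <- drop(Ap %*% qt1_P)
  qAq_P <- sum(qt1_P * Aq_P)

  # records grouped by mother for the per-mother updates (0-based for C++)
  ord <- order(midx)
  mrec <- as.integer(ord - 1L)
  mstart <- as.integer(c(0L, cumsum(tabulate(midx, nbins = M))))

  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain - 1L)
    gN <- drop(Rn %*% stats::rnorm(pN, 0, 0.1))
    gP <- drop(Rp %*% stats::rnorm(pP, 0, 0.1))
    tau <- sort(stats::rnorm(2, c(-0.5, 0.5), 0.1))
    zN <- stats::rnorm(M, 0, 0.5)
    zP <- stats::rnorm(M, 0, 0.5)
    sN <- exp(stats::rnorm(1, log(0.5), 0.2))
    sP <- exp(stats::rnorm(1, log(0.5), 0.2))
    res <- .defense_chain_cpp(Qn, Qp, An, Ap, qt1_N, Aq_N, qAq_N, qt1_P, p1,
                              Aq_P, qAq_P, as.integer(k), lchk,
                              as.integer(class_idx), as.integer(midx - 1L),
                              mstart, mrec, NECKTEETH_TRIALS,
                              config$n_iterations, config$warmup, scans,
                              priors$threshold_sd, priors$ranef_scale_sd,
                              gN, gP, tau, zN, zP, sN, sP)
    # back-transform the orthogonalized coefficients to the design scale
    bN_draws <- t(backsolve(Rn, t(res[, seq_len(pN), drop = FALSE])))
    bP_draws <- t(backsolve(Rp, t(res[, pN + seq_len(pP), drop = FALSE])))
    out[, chain, ] <- cbind(bN_draws, bP_draws,
                            res[, pN + pP + seq_len(4 + 2 * M), drop = FALSE])
  }
  draws <- posterior_draws(out, config)
  structure(list(draws = draws,
                 fixed = c(paste0("N_", pn_cols), paste0("P_", pp_cols)),
                 design = design, priors = priors, config = config,
                 mothers = uids, n_records = n),
            class = "defense_fit")
}

#' @export
print.defense_fit <- function(x, ...) {
  cat("Bivariate defense-trait model fit:", x$n_records, "records,",
      length(x$mothers), "mothers\n")
  print(x$draws)
  invisible(x)
}

#' Fit the pooled kairomone-effectivity model
#'
#' The bivariate defense model with a single 3-level treatment factor
#' (`control`, `PAR`, `UVR`; exposure durations pooled) and per-mother
#' random intercepts.
#'
#' @param records Effectivity records (see [validate_effectivity_table]).
#' @inheritParams fit_defense_model
#' @return A `defense_fit`.
#' @export
fit_effectivity_model <- function(records, priors = prior_spec(),
                                  config = sampler_preset("effectivity")) {
  fit_defense_model(records, design = effectivity_design_spec(),
                    priors = priors, config = config)
}

MORPHO_CODES <- c(BL = "body_length_mm", BW = "body_width_mm",
                  SL = "spina_length_mm")

#' Fit the trivariate morphometric model
#'
#' Body length, body width and spina length modelled jointly as a
#' zero-truncated trivariate Gaussian with a shared fixed-effect design,
#' per-mother per-trait random intercepts and an unstructured 3x3 residual
#' covariance. The sampler is a conjugate blocked Gibbs scheme (Gaussian
#' draws for coefficients and random effects, inverse-Wishart draws for the
#' covariance, slice updates for the random-effect scales); the truncation
#' constant is treated as 1 during sampling, which is exact to numerical
#' precision at the observed trait scales (all means many residual sds above
#' zero). Missing trait components are handled by data augmentation: each
#' iteration draws them from their conditional Gaussian given the observed
#' components, which integrates them out exactly. Records with all three
#' traits missing are dropped with a message.
#'
#' Parameters are named `<code>_<column>` with trait codes `BL`, `BW`, `SL`,
#' plus `sigma_u[<code>]`, residual sds `sd[<code>]` and correlations
#' `cor[<c1>,<c2>]`, and random effects `u_<code>[<mother>]`.
#'
#' @param records Juvenile records (both instars; the design includes the
#'   instar factor).
#' @param design A [design_spec]; defaults to [morpho_design_spec].
#' @inheritParams fit_defense_model
#' @return An object of class `morpho_fit`.
#' @export
fit_morpho_model <- function(records, design = morpho_design_spec(),
                             priors = prior_spec(),
                             config = sampler_preset("main")) {
  Yfull <- as.matrix(records[, MORPHO_TRAITS])
  all_missing <- rowSums(!is.na(Yfull)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " record(s) with no observed traits dropped")
    records <- records[!all_missing, , drop = FALSE]
    Yfull <- Yfull[!all_missing, , drop = FALSE]
  }
  X <- build_design_matrix(records, design)
  p <- ncol(X)
  n <- nrow(X)
  obs <- !is.na(Yfull)
  any_missing <- !all(obs)
  uids <- sort(unique(as.character(records$mother_uid)))
  M <- length(uids)
  midx <- match(as.character(records$mother_uid), uids)
  XtX <- crossprod(X)
  # stacked design [X | mother indicators] for the joint (B, U) draw
  Wm <- matrix(0, n, M)
  Wm[cbind(seq_len(n), midx)] <- 1
  W <- cbind(X, Wm)
  WtW <- crossprod(W)
  S0 <- diag(priors$cov_scale, 3)
  nu0 <- priors$cov_df
  codes <- names(MORPHO_CODES)

  # missingness patterns for the augmentation step
  pat_key <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  patterns <- split(seq_len(n), pat_key)

  pn <- c(as.vector(t(outer(codes, colnames(X), paste, sep = "_"))),
          paste0("sigma_u[", codes, "]"),
          paste0("sd[", codes, "]"),
          "cor[BL,BW]", "cor[BL,SL]", "cor[BW,SL]",
          as.vector(t(outer(codes, uids,
                            function(a, b) paste0("u_", a, "[", b, "]")))))
  # note: B stored trait-major (all BL coefficients, then BW, then SL)
  n_keep <- config$n_iterations - config$warmup
  out <- array(NA_real_, dim = c(n_keep, config$n_chains, length(pn)),
               dimnames = list(NULL, NULL, pn))

  col_means <- colMeans(Yfull, na.rm = TRUE)
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain - 1L)
    Y <- Yfull
    for (t in 1:3) Y[!obs[, t], t] <- col_means[t]
    B <- qr.solve(qr(X), Y) + matrix(stats::rnorm(p * 3, 0, 0.002), p, 3)
    U <- matrix(stats::rnorm(M * 3, 0, 0.005), M, 3)
    sigma_u <- exp(stats::rnorm(3, log(0.01), 0.2))
    E <- Y - X %*% B
    Sigma <- crossprod(E) / n + diag(1e-6, 3)

    for (iter in seq_len(config$n_iterations)) {
      Sinv <- chol2inv(chol(Sigma))

      # 1. data augmentation of missing components
      if (any_missing) {
        Mu <- X %*% B + U[midx, , drop = FALSE]
        for (key in names(patterns)) {
          o <- as.integer(strsplit(key, "")[[1]]) == 1L
          if (all(o)) next
          idx <- patterns[[key]]
          mo <- !o
          if (!any(o)) {
            L <- chol(Sigma)
            Z <- matrix(stats::rnorm(length(idx) * 3), ncol = 3) %*% L
            Y[idx, ] <- Mu[idx, , drop = FALSE] + Z
            next
          }
          Soo_inv <- solve(Sigma[o, o, drop = FALSE])
          A <- Sigma[mo, o, drop = FALSE] %*% Soo_inv
          Cc <- Sigma[mo, mo, drop = FALSE] -
            A %*% Sigma[o, mo, drop = FALSE]
          Lc <- chol((Cc + t(Cc)) / 2)
          dev <- Yfull[idx, o, drop = FALSE] - Mu[idx, o, drop = FALSE]
          cond_mean <- Mu[idx, mo, drop = FALSE] + dev %*% t(A)
          Z <- matrix(stats::rnorm(length(idx) * sum(mo)),
                      ncol = sum(mo)) %*% Lc
          Y[idx, mo] <- cond_mean + Z
        }
      }

      # 2.+3. coefficients and mother intercepts: one joint conjugate
      # Gaussian draw of the stacked (B, U) block per trait triple --
      # alternating the two blocks mixes slowly because they are strongly
      # correlated a posteriori, the joint draw is exact
      prec <- kronecker(Sinv, WtW)
      diag_add <- c(vapply(1:3, function(t) {
        c(rep(1 / priors$coef_sd^2, p), rep(1 / sigma_u[t]^2, M))
      }, numeric(p + M)))
      diag(prec) <- diag(prec) + diag_add
      rhs <- as.vector(crossprod(W, Y %*% Sinv))
      Lp <- chol(prec)
      mean_b <- backsolve(Lp, backsolve(Lp, rhs, transpose = TRUE))
      theta <- mean_b + backsolve(Lp, stats::rnorm(3 * (p + M)))
      Theta <- matrix(theta, p + M, 3)
      B <- Theta[seq_len(p), , drop = FALSE]
      U <- Theta[p + seq_len(M), , drop = FALSE]
      E <- Y - X %*% B

      # 4. random-effect scales
      for (t in 1:3) {
        ut <- U[, t]
        fs <- function(ls) sum(stats::dnorm(ut, 0, exp(ls), log = TRUE)) +
          half_normal_logpdf(exp(ls), priors$ranef_scale_sd) + ls
        sigma_u[t] <- exp(slice_update(log(sigma_u[t]), fs, w = 0.5)$x)
      }

      # 4b. interweaving moves (ancillary parameterizations): both the
      # (sigma_u, U) pair and the (intercept, mean of U) pair sit on soft
      # ridges whose conditionals are exactly Gaussian, so they get exact
      # Gibbs updates that the centered blocks alone traverse slowly
      for (t in 1:3) {
        # non-centered rescale: z = U/sigma fixed, draw sigma from its
        # truncated-Gaussian conditional (the likelihood is linear in
        # sigma when z is held fixed)
        z_t <- U[, t] / sigma_u[t]
        zrec <- z_t[midx]
        Cc <- E - U[midx, , drop = FALSE]
        Cc[, t] <- E[, t]  # trait-t mother effect removed
        a_t <- Sinv[t, t] * sum(zrec^2) + 1 / priors$ranef_scale_sd^2
        b_t <- sum(zrec * (Cc %*% Sinv[, t]))
        m_t <- b_t / a_t
        sd_t <- 1 / sqrt(a_t)
        lo <- stats::pnorm(0, m_t, sd_t)
        s_new <- stats::qnorm(stats::runif(1, lo, 1), m_t, sd_t)
        if (is.finite(s_new) && s_new > 1e-8) {
          sigma_u[t] <- s_new
          U[, t] <- s_new * z_t
        }
      }
      E <- Y - X %*% B

      # 5. residual covariance: inverse-Wishart draw
      E2 <- E - U[midx, , drop = FALSE]
      Spost <- S0 + crossprod(E2)
      Wish <- drop(stats::rWishart(1, nu0 + n, chol2inv(chol(Spost))))
      Sigma <- chol2inv(chol(Wish))
      Sigma <- (Sigma + t(Sigma)) / 2

      if (iter > config$warmup) {
        sds <- sqrt(diag(Sigma))
        cors <- Sigma / tcrossprod(sds)
        out[iter - config$warmup, chain, ] <-
          c(as.vector(B), sigma_u, sds,
            cors[1, 2], cors[1, 3], cors[2, 3], as.vector(U))
      }
    }
  }
  draws <- posterior_draws(out, config)
  structure(list(draws = draws,
                 fixed = as.vector(t(outer(codes, colnames(X), paste,
                                           sep = "_"))),
                 design = design, priors = priors, config = config,
                 mothers = uids, n_records = n),
            class = "morpho_fit")
}

#' @export
print.morpho_fit <- function(x, ...) {
  cat("Trivariate morphometric model fit:", x$n_records, "records,",
      length(x$mothers), "mothers\n")
  print(x$draws)
  invisible(x)
}
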