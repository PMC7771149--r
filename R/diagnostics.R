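## Convergence diagnostics: rank-normalized split-Rhat and bulk effective
## sample size, following the reference formulas of Vehtari, Gelman, Simpson,
## Carpenter & Buerkner (2021).

split_chain_matrix <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1L, n), , drop = FALSE])
}

rank_normalize <- function(mat) {
  S <- length(mat)
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(mat), ncol = ncol(mat))
}

rhat_basic <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  chain_means <- colMeans(mat)
  chain_vars <- apply(mat, 2, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(chain_means)
  if (W < 1e-300) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

is_constant_draws <- function(mat) {
  max(mat) - min(mat) < .Machine$double.eps * 100 * max(1, abs(mat[1]))
}

#' Rank-normalized split-Rhat
#'
#' Chains are split in half, all split-chain draws are jointly
#' rank-normalized (normal scores), and the classical potential-scale-
#' reduction factor is computed on the normalized draws; the result is the
#' maximum of this bulk diagnostic and the same computation on the folded
#' draws (absolute deviations from the median, sensitive to tail/scale
#' disagreement). Values near 1 indicate mixing; > 1.05 is treated as
#' unidentifiable by the model-reduction workflow and < 1.01 as converged.
#'
#' @param draws A [posterior_draws] (>= 2 chains, >= 4 draws per chain) or an
#'   iterations x chains matrix.
#' @param parameter Parameter name (when `draws` is a `posterior_draws`).
#' @return Scalar Rhat (defined as 1, with a warning, for a parameter that
#'   is constant across all draws).
#' @export
split_rhat <- function(draws, parameter = NULL) {
  mat <- as_chain_matrix(draws, parameter)
  if (ncol(mat) < 2 || nrow(mat) < 4) {
    stop("split-Rhat needs at least 2 chains of at least 4 draws", call. = FALSE)
  }
  if (is_constant_draws(mat)) {
    warning("parameter is constant across all draws; Rhat defined as 1")
    return(1)
  }
  if (all(mat == mat[, 1])) return(1)  # identical chains: no between-chain variance
  sp <- split_chain_matrix(mat)
  bulk <- rhat_basic(rank_normalize(sp))
  folded <- rhat_basic(rank_normalize(abs(sp - stats::median(sp))))
  max(bulk, folded)
}

as_chain_matrix <- function(draws, parameter) {
  if (inherits(draws, "posterior_draws")) {
    stopifnot(!is.null(parameter))
    draws_matrix(draws, parameter)
  } else {
    as.matrix(draws)
  }
}

# Per-chain autocovariance (biased, denominator n) up to lag n - 1, via FFT.
chain_autocov <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2 * n)
  f <- stats::fft(c(xc, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
}

#' Bulk effective sample size
#'
#' Effective number of independent draws, computed on rank-normalized split
#' chains: combined-chain autocorrelations are estimated from per-chain
#' autocovariances, summed with Geyer's initial positive/monotone sequence,
#' and the total draw count divided by the resulting integrated
#' autocorrelation time. For iid chains ESS is close to the number of
#' retained draws; strong positive autocorrelation drives it down.
#'
#' @inheritParams split_rhat
#' @return Scalar ESS (`NA` with a warning for constant draws).
#' @export
effective_sample_size <- function(draws, parameter = NULL) {
  mat <- as_chain_matrix(draws, parameter)
  if (ncol(mat) < 2 || nrow(mat) < 4) {
    stop("ESS needs at least 2 chains of at least 4 draws", call. = FALSE)
  }
  if (is_constant_draws(mat)) {
    warning("parameter is constant across all draws; ESS is degenerate")
    return(NA_real_)
  }
  z <- rank_normalize(split_chain_matrix(mat))
  n <- nrow(z)
  m <- ncol(z)
  acov <- apply(z, 2, chain_autocov)
  # acov[t+1, chain] is the lag-t autocovariance with denominator n
  chain_vars <- acov[1, ] * n / (n - 1)
  W <- mean(chain_vars)
  var_plus <- (n - 1) / n * W + stats::var(colMeans(z))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer initial positive sequence on paired sums, then monotone
  max_pairs <- floor(n / 2) - 1
  P <- numeric(0)
  for (k in 0:max_pairs) {
    i1 <- 2 * k + 1
    i2 <- 2 * k + 2
    if (i2 > length(rho)) break
    pk <- rho[i1] + rho[i2]
    if (k > 0 && pk < 0) break
    P <- c(P, max(pk, 0))
  }
  if (length(P) > 1) P <- cummin(P)
  tau <- -1 + 2 * sum(P)
  tau <- max(tau, 1 / log10(n * m + 10))
  n * m / tau
}

#' Identifiability screen over all parameters
#'
#' The model-reduction workflow drops the highest-order interaction and
#' refits whenever this screen fails. A parameter fails when its
#' rank-normalized split-Rhat strictly exceeds the threshold (default 1.05;
#' a value exactly at the threshold passes).
#'
#' @param draws A [posterior_draws].
#' @param rhat_threshold Failure threshold on Rhat.
#' @return List with `pass` (logical), `offending` (named Rhat values of
#'   failing parameters) and `rhat` (all values).
#' @export
check_identifiability <- function(draws, rhat_threshold = 1.05) {
  stopifnot(inherits(draws, "posterior_draws"))
  rhats <- vapply(parameters(draws),
                  function(p) suppressWarnings(split_rhat(draws, p)),
                  numeric(1))
  offending <- rhats[rhats > rhat_threshold]
  list(pass = length(offending) == 0, offending = offending, rhat = rhats)
}

#' Central credible interval
#'
#' Equal-tailed interval from the empirical quantiles of the pooled
#' post-warmup draws, using the linear-interpolation quantile convention
#' (type 7); the convention matters because interval endpoints near zero
#' decide "strong effect" calls.
#'
#' @param draws A [posterior_draws] or numeric vector of draws.
#' @param parameter Parameter name (for `posterior_draws` input).
#' @param level Interval probability in (0, 1), e.g. 0.95.
#' @return Numeric `c(low, high)`.
#' @export
credible_interval <- function(draws, parameter = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  x <- if (inherits(draws, "posterior_draws")) {
    pooled_draws(draws, parameter)
  } else {
    as.numeric(draws)
  }
  if (length(x) == 0) stop("no draws available", call. = FALSE)
  alpha <- (1 - level) / 2
  unname(stats::quantile(x, c(alpha, 1 - alpha), type = 7))
}

#' Per-parameter convergence summary
#'
#' @param draws A [posterior_draws].
#' @return Data frame with parameter, split-Rhat, and bulk ESS.
#' @export
convergence_summary <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  pn <- parameters(draws)
  data.frame(
    parameter = pn,
    rhat = vapply(pn, function(p) suppressWarnings(split_rhat(draws, p)),
                  numeric(1)),
    ess_bulk = vapply(pn, function(p)
      suppressWarnings(effective_sample_size(draws, p)), numeric(1)),
    row.names = NULL)
}
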