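#' Savage-Dickey density-ratio evidence
#'
#' For a point null hypothesis H0: parameter = `point` nested in the model
#' with its continuous prior, the Bayes factor of H0 against the
#' unrestricted alternative equals the posterior density divided by the
#' prior density at the point. The posterior density is estimated from the
#' pooled post-warmup draws by Gaussian kernel density estimation with
#' Silverman's bandwidth (a normal-approximation fallback is available);
#' the prior density is analytic. Ratios above 1 favor H0 (no effect),
#' ratios below 1 favor the alternative.
#'
#' @param draws A [posterior_draws] or a numeric vector of draws (at least
#'   100; kernel estimates from fewer are unreliable and raise an error).
#' @param parameter Parameter name (for `posterior_draws` input).
#' @param prior A [prior_spec]; the coefficient prior Normal(`coef_mean`,
#'   `coef_sd`) applies unless `prior_mean`/`prior_sd` override it (e.g. for
#'   linear contrasts of coefficients, whose implied prior sd differs).
#' @param point Test point of H0 (default 0).
#' @param prior_mean,prior_sd Optional explicit normal prior for the tested
#'   quantity.
#' @param method `"kernel"` (default) or `"normal"` (moment-matched normal
#'   approximation of the posterior).
#' @return An object of class `evidence_result` with the evidence ratio and
#'   both densities at the point.
#' @export
savage_dickey_ratio <- function(draws, parameter = NULL, prior = prior_spec(),
                                point = 0, prior_mean = NULL, prior_sd = NULL,
                                method = c("kernel", "normal")) {
  method <- match.arg(method)
  x <- if (inherits(draws, "posterior_draws")) {
    pooled_draws(draws, parameter)
  } else {
    as.numeric(draws)
  }
  if (length(x) < 100) {
    stop("need at least 100 draws for a reliable density estimate",
         call. = FALSE)
  }
  if (is.null(prior_mean)) prior_mean <- prior$coef_mean
  if (is.null(prior_sd)) prior_sd <- prior$coef_sd
  prior_density <- stats::dnorm(point, prior_mean, prior_sd)
  if (prior_density <= 0) {
    stop("prior density at the test point must be positive", call. = FALSE)
  }
  posterior_density <- if (method == "kernel") {
    bw <- stats::bw.nrd0(x)
    mean(stats::dnorm(point, x, bw))
  } else {
    stats::dnorm(point, mean(x), stats::sd(x))
  }
  structure(list(parameter = if (is.null(parameter)) NA_character_ else parameter,
                 evidence_ratio = posterior_density / prior_density,
                 posterior_density_at_point = posterior_density,
                 prior_density_at_point = prior_density,
                 point = point, n_draws = length(x), method = method),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf(
    "Savage-Dickey evidence ratio for %s = %g: %.4g (posterior %.4g / prior %.4g at point)\n",
    x$parameter, x$point, x$evidence_ratio, x$posterior_density_at_point,
    x$prior_density_at_point))
  invisible(x)
}

#' Classify strong effects from credible intervals
#'
#' An effect is "strong" when its 95% central credible interval does not
#' include 0; an interval endpoint exactly at 0 counts as including 0
#' (conservative convention).
#'
#' @param draws A [posterior_draws] or model fit (`defense_fit`,
#'   `morpho_fit`).
#' @param parameters Parameters to classify; for fits, defaults to the
#'   fixed effects in design order.
#' @param level Credible level (default 0.95).
#' @return Named logical vector.
#' @export
classify_strong_effects <- function(draws, parameters = NULL, level = 0.95) {
  if (inherits(draws, c("defense_fit", "morpho_fit"))) {
    if (is.null(parameters)) parameters <- draws$fixed
    draws <- draws$draws
  }
  if (is.null(parameters)) parameters <- parameters(draws)
  vapply(parameters, function(p) {
    ci <- credible_interval(draws, p, level)
    ci[1] > 0 || ci[2] < 0
  }, logical(1))
}

#' Posterior effect summary table
#'
#' One row per fixed-effect parameter, in design-matrix column order:
#' posterior median, 50% and 95% central credible intervals, the
#' strong-effect flag (95% CI excluding 0) and the Savage-Dickey evidence
#' ratio for the point null at 0. Mirrors the content of a forest plot of
#' the fixed effects; [plot_effect_summary] renders it as one.
#'
#' @param fit A `defense_fit` or `morpho_fit` (or a [posterior_draws] plus
#'   explicit `parameters`).
#' @param parameters Optional explicit parameter subset/ordering.
#' @param priors Prior used for evidence ratios; defaults to the fit's.
#' @return Data frame of class `effect_summary`.
#' @export
effect_summary_table <- function(fit, parameters = NULL, priors = NULL) {
  if (inherits(fit, c("defense_fit", "morpho_fit"))) {
    if (is.null(parameters)) parameters <- fit$fixed
    if (is.null(priors)) priors <- fit$priors
    draws <- fit$draws
  } else {
    draws <- fit
    if (is.null(parameters)) parameters <- parameters(draws)
    if (is.null(priors)) priors <- prior_spec()
  }
  rows <- lapply(parameters, function(p) {
    x <- pooled_draws(draws, p)
    ci50 <- credible_interval(x, level = 0.5)
    ci95 <- credible_interval(x, level = 0.95)
    er <- if (stats::sd(x) < 1e-12) NA_real_ else {
      savage_dickey_ratio(x, prior = priors)$evidence_ratio
    }
    data.frame(parameter = p, median = stats::median(x),
               ci50_low = ci50[1], ci50_high = ci50[2],
               ci95_low = ci95[1], ci95_high = ci95[2],
               strong = ci95[1] > 0 || ci95[2] < 0,
               evidence_ratio = er, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Forest plot of an effect summary
#'
#' Thick segments are 50% credible intervals, thin segments 95% intervals,
#' points the posterior medians; strong effects (95% CI excluding 0) are
#' drawn in red, the rest in black. Plots on the active graphics device.
#'
#' @param summary An `effect_summary` table (or a fit, which is summarized
#'   first).
#' @param main Plot title.
#' @return Invisibly, the summary table.
#' @export
plot_effect_summary <- function(summary, main = "Posterior fixed effects") {
  if (!inherits(summary, "effect_summary")) {
    summary <- effect_summary_table(summary)
  }
  n <- nrow(summary)
  ys <- rev(seq_len(n))
  xlim <- range(c(summary$ci95_low, summary$ci95_high, 0))
  op <- graphics::par(mar = c(4, 11, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Effect (log-odds / mm)", ylab = "", main = main)
  graphics::abline(v = 0, lty = 2, col = "grey60")
  cols <- ifelse(summary$strong, "red", "black")
  graphics::segments(summary$ci95_low, ys, summary$ci95_high, ys,
                     col = cols, lwd = 1)
  graphics::segments(summary$ci50_low, ys, summary$ci50_high, ys,
                     col = cols, lwd = 3)
  graphics::points(summary$median, ys, pch = 16, col = cols)
  graphics::axis(2, at = ys, labels = summary$parameter, las = 2,
                 cex.axis = 0.7)
  invisible(summary)
}

#' Linear contrast of posterior draws
#'
#' Pooled draws of `sum(weights * parameters)` along with the implied
#' normal prior sd of the contrast under independent Normal(0, coef_sd)
#' coefficient priors (`coef_sd * sqrt(sum(weights^2))`), as needed for
#' Savage-Dickey tests of contrasts.
#'
#' @param draws A [posterior_draws].
#' @param weights Named numeric vector (names = parameters).
#' @param priors A [prior_spec].
#' @return List with `draws` (numeric vector) and `prior_sd`.
#' @export
contrast_draws <- function(draws, weights, priors = prior_spec()) {
  stopifnot(!is.null(names(weights)))
  mats <- vapply(names(weights), function(p) pooled_draws(draws, p),
                 numeric(n_retained_draws(draws)))
  list(draws = drop(mats %*% weights),
       prior_sd = priors$coef_sd * sqrt(sum(weights^2)))
}

#' Hypothesis tests for the kairomone-effectivity model
#'
#' Two planned contrasts per response (neckteeth `N`, pedestal `P`): the
#' average of the two kairomone treatments against the control
#' (`(PAR + UVR) / 2 = 0` on the log-odds scale, i.e. "does the kairomone
#' extract induce defenses?") and UVR against PAR (`UVR - PAR = 0`, "does
#' UVR exposure degrade the kairomone?"). Each row reports the posterior
#' median and 95% CI of the contrast, the strong-effect flag and the
#' Savage-Dickey evidence ratio (above 1: evidence for no difference).
#'
#' @param fit A `defense_fit` of effectivity records.
#' @return Data frame with one row per contrast.
#' @export
effectivity_hypotheses <- function(fit) {
  stopifnot(inherits(fit, "defense_fit"))
  out <- list()
  for (resp in c("N", "P")) {
    par_p <- paste0(resp, "_treatmentPAR")
    par_u <- paste0(resp, "_treatmentUVR")
    specs <- list(
      kairomone_vs_control = stats::setNames(c(0.5, 0.5), c(par_p, par_u)),
      uvr_vs_par = stats::setNames(c(-1, 1), c(par_p, par_u)))
    for (h in names(specs)) {
      ct <- contrast_draws(fit$draws, specs[[h]], fit$priors)
      ci <- credible_interval(ct$draws, level = 0.95)
      er <- savage_dickey_ratio(ct$draws, prior = fit$priors,
                                prior_sd = ct$prior_sd)
      out[[length(out) + 1L]] <- data.frame(
        response = resp, hypothesis = h, median = stats::median(ct$draws),
        ci95_low = ci[1], ci95_high = ci[2],
        strong = ci[1] > 0 || ci[2] < 0,
        evidence_ratio = er$evidence_ratio, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
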