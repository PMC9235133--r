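#' Deviance information criterion from a deviance trace
#'
#' `Dbar = mean(trace)`, `pD = Dbar - D(theta_bar)`,
#' `DIC = Dbar + pD = 2 Dbar - D(theta_bar)`.
#'
#' @param deviance_trace per-iteration deviances (post burn-in).
#' @param deviance_at_posterior_mean deviance evaluated at the posterior
#'   means of the focus parameters.
#' @param model optional label (`"lmm"` or `"zip"`).
#' @return a `vr_dic` list with `dic`, `dbar`, `pd`, `model`.
#' @export
compute_dic <- function(deviance_trace, deviance_at_posterior_mean,
                        model = NULL) {
  if (!length(deviance_trace)) stop("empty deviance trace")
  if (any(!is.finite(deviance_trace)) ||
      !is.finite(deviance_at_posterior_mean))
    stop("non-finite deviance values")
  dbar <- mean(deviance_trace)
  pd <- dbar - deviance_at_posterior_mean
  structure(list(dic = dbar + pd, dbar = dbar, pd = pd, model = model),
            class = "vr_dic")
}

#' Model choice by DIC
#'
#' The lower DIC wins; differences below 1e-9 are reported as a tie (and
#' resolved in favor of the linear model).
#'
#' @param dic_lmm,dic_zip `vr_dic` objects.
#' @return list with `choice` (`"lmm"` or `"zip"`), `delta`
#'   (`dic_lmm - dic_zip`) and `tie`.
#' @export
select_model <- function(dic_lmm, dic_zip) {
  d1 <- dic_lmm$dic; d2 <- dic_zip$dic
  if (!is.finite(d1) || !is.finite(d2)) stop("non-finite DIC")
  tie <- abs(d1 - d2) < 1e-9
  list(choice = if (tie || d1 <= d2) "lmm" else "zip",
       delta = d1 - d2, tie = tie)
}

# Spectral density at frequency zero estimated through an autoregressive
# fit (the estimator coda's geweke.diag uses via spectrum0.ar).
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  v <- var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    ar(x, aic = TRUE, order.max = min(length(x) - 1L, floor(10 * log10(length(x))))),
    error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the means of the first `first_frac` and last `last_frac`
#' segments of a chain:
#' `z = (m1 - m2) / sqrt(s1/n1 + s2/n2)` with `s` the spectral density of
#' each segment at frequency zero.  Under convergence z is asymptotically
#' standard normal.
#'
#' @param chain numeric vector of draws (length >= 100).
#' @param first_frac,last_frac fractions defining the two segments
#'   (defaults 0.1 and 0.5; must not overlap).
#' @return the z statistic, or `NA` for a zero-variance segment.
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic")
  if (first_frac + last_frac > 1) stop("segments overlap")
  x1 <- chain[seq_len(floor(first_frac * n))]
  x2 <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  if (s1 <= 0 || s2 <= 0) return(NA_real_)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

#' Posterior summary of a scalar chain
#'
#' Arithmetic mean, sample standard deviation and the posterior
#' probability of exceeding a threshold (default 0.10, the bound used to
#' flag meaningfully non-null variance ratios).
#'
#' @param values numeric draws.
#' @param threshold exceedance threshold.
#' @return list with `mean`, `sd`, `prob_exceeds`.
#' @export
posterior_summary <- function(values, threshold = 0.10) {
  if (!length(values)) stop("empty chain")
  list(mean = mean(values), sd = sd(values),
       prob_exceeds = mean(values > threshold))
}

# Deviance of the linear model at the posterior means of
# (beta, ratios, sigma2_P).
lmm_deviance_at_mean <- function(chain, y, X, kernels) {
  rbar <- pmax(colMeans(chain$ratios), 0)
  if (sum(rbar) > 1) rbar <- rbar / (sum(rbar) + 1e-12)
  V <- build_V(rbar, mean(chain$sigma2), kernels)
  bbar <- if (ncol(chain$beta)) colMeans(chain$beta) else numeric(0)
  -2 * lmm_log_likelihood(y, bbar, V, X)
}

# Conditional-focus ZIP deviance at the posterior means of (lambda*, p*).
zip_deviance_at_mean <- function(chain, y) {
  -2 * zip_log_likelihood(y, chain$lamstar_mean, mean(chain$pstar))
}

# Population-focus ZIP deviance at the posterior means of
# (beta, ratios, sigma2_P, p*), lambda* integrated observation-wise.
zip_marginal_deviance_at_mean <- function(chain, y, X, kernels,
                                          gh_points = 31) {
  rbar <- pmax(colMeans(chain$ratios), 0)
  if (sum(rbar) > 1) rbar <- rbar / (sum(rbar) + 1e-12)
  s2 <- mean(chain$sigma2)
  Kdiag <- rbar[1] * diag(kernels$K_A) + rbar[2] + rbar[3] + (1 - sum(rbar))
  bbar <- if (ncol(chain$beta)) colMeans(chain$beta) else numeric(0)
  mu <- if (length(bbar)) drop(X %*% bbar) else rep(0, length(y))
  gh <- gauss_hermite(gh_points)
  zip_marginal_deviance_cpp(as.numeric(y), mu, sqrt(s2 * Kdiag),
                            mean(chain$pstar), gh$nodes, gh$log_weights)
}

#' DIC of a fitted chain
#'
#' For the linear model the deviance is `-2 log MVN(y | X beta, V)` with
#' focus `(beta, h2, l2, c2, sigma2_P)`.  For the ZIP model two foci are
#' available: `"conditional"` uses `-2 log p(y | lambda*, p*)` with focus
#' `(lambda*, p*)`; `"marginal"` integrates `lambda*` out
#' observation-wise (Gauss-Hermite) so that the focus
#' `(beta, ratios, sigma2_P, p*)` parallels the linear model's.  The
#' marginal focus is the default used for LMM-vs-ZIP comparison; see the
#' package vignette for the rationale.
#'
#' @param chain a `vr_chain`.
#' @param y the observed trait values the chain was fitted to.
#' @param X,kernels the design and kernels used for the fit.
#' @param zip_focus `"marginal"` or `"conditional"`.
#' @return a `vr_dic`.
#' @export
chain_dic <- function(chain, y, X, kernels,
                      zip_focus = c("marginal", "conditional")) {
  zip_focus <- match.arg(zip_focus)
  if (chain$model == "lmm") {
    compute_dic(chain$deviance, lmm_deviance_at_mean(chain, y, X, kernels),
                model = "lmm")
  } else if (zip_focus == "conditional") {
    compute_dic(chain$deviance, zip_deviance_at_mean(chain, y), model = "zip")
  } else {
    compute_dic(chain$deviance_marginal,
                zip_marginal_deviance_at_mean(chain, y, X, kernels),
                model = "zip")
  }
}
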