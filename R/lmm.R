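#' Multivariate-normal log-likelihood of the linear mixed model
#'
#' Log density of `y` under MVN(X beta, V), evaluated through the
#' Cholesky factor of V.
#'
#' @param y numeric response vector.
#' @param beta systematic-effect vector (length `ncol(X)`; may be empty).
#' @param V covariance matrix.
#' @param X design matrix (n x p; p may be 0).
#' @return log-likelihood value.
#' @export
lmm_log_likelihood <- function(y, beta, V, X) {
  n <- length(y)
  if (!all(dim(V) == n)) stop("non-conforming V")
  L <- tryCatch(t(chol(V)), error = function(e)
    stop("V is not positive definite (Cholesky failed)"))
  e <- if (length(beta)) y - drop(X %*% beta) else y
  w <- forwardsolve(L, e)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(w^2)
}

#' Gibbs draw of the systematic effects
#'
#' Draws beta from its conditional posterior under a flat prior:
#' MVN with mean `(X'V^-1X)^-1 X'V^-1 y` and covariance `(X'V^-1X)^-1`.
#'
#' @inheritParams lmm_log_likelihood
#' @return a draw of beta.
#' @export
gibbs_update_beta <- function(y, X, V) {
  L <- t(chol(V))
  W <- forwardsolve(L, X)
  wy <- forwardsolve(L, y)
  G <- crossprod(W)
  Rg <- tryCatch(chol(G), error = function(e) stop("singular X'V^-1X"))
  mean <- backsolve(Rg, forwardsolve(t(Rg), crossprod(W, wy)))
  drop(mean + backsolve(Rg, rnorm(ncol(X))))
}

#' Gibbs draw of the phenotypic variance
#'
#' With `K(ratios)` the bracketed covariance kernel and
#' `S = (y - X beta)' K^-1 (y - X beta)`, the flat positive prior on
#' sigma2_P gives a conditional proportional to
#' `(sigma2)^(-n/2) exp(-S / (2 sigma2))`, i.e. inverse-gamma with shape
#' `n/2 - 1` and scale `S/2`.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param beta current systematic effects.
#' @param ratios current `(h2, l2, c2)`.
#' @param kernels `vr_kernels` list.
#' @return a draw of sigma2_P.
#' @export
gibbs_update_sigma2 <- function(y, X, beta, ratios, kernels) {
  n <- length(y)
  if (n <= 4) stop("n too small for a proper sigma2_P conditional")
  K <- build_V(ratios, 1, kernels)
  e <- if (length(beta)) y - drop(X %*% beta) else y
  w <- forwardsolve(t(chol(K)), e)
  S <- sum(w^2)
  if (S <= 0) stop("non-positive quadratic form S")
  (S / 2) / rgamma(1, shape = n / 2 - 1, rate = 1)
}

reflect_interval <- function(x, lo, hi) {
  L <- hi - lo
  if (L <= 0) return(lo)
  z <- (x - lo) %% (2 * L)
  z <- ifelse(z > L, 2 * L - z, z)
  lo + z
}

#' Metropolis update of one variance ratio
#'
#' Reflected Gaussian random-walk proposal on the conditional support
#' `[0, 1 - sum(other ratios)]`; the flat simplex prior cancels, so the
#' acceptance ratio is the ratio of MVN densities.
#'
#' @param which one of `"h2"`, `"l2"`, `"c2"`.
#' @param ratios current `(h2, l2, c2)`.
#' @param sigma2_P current phenotypic variance.
#' @param e residual vector (`y - X beta`, or `lambda* - X beta`).
#' @param kernels `vr_kernels`.
#' @param step proposal standard deviation (> 0).
#' @return list with `ratios` (possibly updated) and `accepted` flag.
#' @export
mh_update_ratio <- function(which = c("h2", "l2", "c2"), ratios, sigma2_P,
                            e, kernels, step) {
  which <- match.arg(which)
  if (step <= 0) stop("step must be > 0")
  j <- match(which, c("h2", "l2", "c2"))
  r <- check_simplex(ratios)
  b <- 1 - (sum(r) - r[j])
  prop <- reflect_interval(r[j] + step * rnorm(1), 0, b)
  rp <- r; rp[j] <- prop
  logpost <- function(rr) {
    K <- build_V(rr, 1, kernels)
    L <- tryCatch(t(chol(K)), error = function(err) NULL)
    if (is.null(L)) return(-Inf)
    w <- forwardsolve(L, e)
    -sum(log(diag(L))) - sum(w^2) / (2 * sigma2_P)
  }
  acc <- log(runif(1)) < logpost(rp) - logpost(r)
  list(ratios = if (acc) rp else r, accepted = acc)
}

default_settings <- function() {
  list(n_iter = 10000L, burnin = 1000L,
       steps = c(h2 = 0.05, l2 = 0.05, c2 = 0.05),
       step_lambda = 0.3, step_pstar = 0.5,
       grid_size = 129L, density_grid = TRUE, adapt = TRUE)
}

check_chain_inputs <- function(y, X, kernels, n_iter, burnin) {
  n <- length(y)
  if (n < 5) stop("need at least 5 observations")
  if (nrow(X) != n) stop("X has wrong number of rows")
  if (!all(dim(kernels$K_A) == n)) stop("kernels do not match data length")
  if (burnin >= n_iter) stop("burnin must be smaller than n_iter")
  invisible(NULL)
}

new_chain <- function(raw, model, n_iter, burnin, settings, seed) {
  for (nm in c("sigma2", "deviance", "deviance_marginal", "pstar",
               "lamstar_mean", "accept", "step"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- drop(raw[[nm]])
  colnames(raw$ratios) <- c("h2", "l2", "c2")
  colnames(raw$log_dens0) <- c("h2", "l2", "c2")
  out <- c(raw, list(model = model, n_kept = n_iter - burnin,
                     n_burnin = burnin, settings = settings, seed = seed))
  class(out) <- "vr_chain"
  out
}

#' Run the linear-mixed-model sampler
#'
#' Metropolis-within-Gibbs chain for the model `y ~ MVN(X beta, V)` with
#' `V = sigma2_P [K_A h2 + K_L l2 + K_C c2 + I(1 - h2 - l2 - c2)]`, flat
#' priors on beta and sigma2_P and the uniform simplex prior on the
#' ratios.  Update order per iteration: beta, sigma2_P (Gibbs), then h2,
#' l2, c2 (one reflected random-walk Metropolis try each).  The chain
#' stores, for every kept iteration, the draws, the deviance
#' `-2 log MVN(y | X beta, V)` and (if `density_grid`) the log normalized
#' conditional density of each ratio at zero, the per-iteration quantity
#' averaged by the Savage-Dickey Bayes factor.
#'
#' @param y numeric response (the transformed trait).
#' @param X systematic-effects design matrix (may have 0 columns).
#' @param kernels `vr_kernels` from [make_kernels()].
#' @param n_iter total chain length (default 10000).
#' @param burnin discarded initial iterations (default 1000).
#' @param steps initial Metropolis steps for (h2, l2, c2).
#' @param grid_size odd number of Simpson points for the conditional
#'   density grid (default 129).
#' @param density_grid compute the per-iteration density-at-zero traces
#'   (default TRUE; disable for pure parameter-recovery runs).
#' @param update logical length-3: which ratios are sampled (others stay
#'   at their initial value).
#' @param adapt adapt proposal steps during burn-in only (frozen after).
#' @param init optional list with `ratios`, `sigma2`, `beta`.
#' @param seed optional integer seed; the chain is deterministic given it.
#' @return a `vr_chain` object.
#' @export
run_lmm_mcmc <- function(y, X, kernels, n_iter = 10000, burnin = 1000,
                         steps = c(0.05, 0.05, 0.05), grid_size = 129,
                         density_grid = TRUE, update = c(TRUE, TRUE, TRUE),
                         adapt = TRUE, init = NULL, seed = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  check_chain_inputs(y, X, kernels, n_iter, burnin)
  if (grid_size %% 2 == 0) grid_size <- grid_size + 1
  init <- init %||% list()
  r0 <- init$ratios %||% {
    r <- c(0.1, 0.1, 0.1); r[!update] <- 0; r
  }
  b0 <- init$beta %||% if (ncol(X)) qr.coef(qr(X), y) else numeric(0)
  s0 <- init$sigma2 %||% max(var(y), 1e-8)
  raw <- with_seed(seed, chain_lmm_cpp(
    y, X, kernels$K_A, kernels$K_L, kernels$K_C,
    as.integer(n_iter), as.integer(burnin), as.numeric(steps),
    as.integer(grid_size), density_grid, as.logical(update), adapt,
    check_simplex(r0), s0, as.numeric(b0)))
  settings <- list(n_iter = n_iter, burnin = burnin, steps = steps,
                   grid_size = grid_size, density_grid = density_grid,
                   update = update, adapt = adapt)
  new_chain(raw, "lmm", n_iter, burnin, settings, seed)
}

#' Dump a chain as delimited text
#'
#' Writes one row per kept iteration with the ratio draws, sigma2_P,
#' systematic effects, deviance trace(s), the per-ratio log conditional
#' densities at zero (when recorded) and, for the ZIP model, the p* trace
#' — the format shared by both samplers for external diagnostics.
#'
#' @param chain a `vr_chain`.
#' @param path output file; tab-separated with a header row.
#' @return invisibly, the data.frame written.
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(iteration = seq_len(chain$n_kept) + chain$n_burnin,
                   chain$ratios, sigma2_P = chain$sigma2)
  if (ncol(chain$beta)) {
    b <- chain$beta
    colnames(b) <- paste0("beta", seq_len(ncol(b)))
    df <- cbind(df, b)
  }
  if (chain$model == "zip") df$pstar <- chain$pstar
  df$deviance <- chain$deviance
  if (!is.null(chain$deviance_marginal))
    df$deviance_marginal <- chain$deviance_marginal
  ld <- chain$log_dens0
  colnames(ld) <- paste0("log_dens0_", colnames(chain$ratios))
  df <- cbind(df, ld)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @export
print.vr_chain <- function(x, ...) {
  cat("Variance-ratio MCMC chain (", toupper(x$model), " model)\n", sep = "")
  cat("  kept iterations:", x$n_kept, " (burn-in ", x$n_burnin, ")\n", sep = "")
  pm <- colMeans(x$ratios)
  cat(sprintf("  posterior means: h2 = %.3f, l2 = %.3f, c2 = %.3f\n",
              pm[1], pm[2], pm[3]))
  cat(sprintf("  sigma2_P mean: %.4g\n", mean(x$sigma2)))
  if (x$model == "zip")
    cat(sprintf("  zero-inflation p mean: %.3f\n", mean(plogis(x$pstar))))
  invisible(x)
}
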