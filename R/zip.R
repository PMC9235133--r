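#' Zero-inflated Poisson log-likelihood in the star parameterization
#'
#' With `lambda* = log(lambda)` and `p* = logit(p)`, the contribution of
#' a zero count is `log[(1/(1+e^p*)) (e^p* + e^(-exp(lambda*_i)))]` and of
#' a positive count `log[(1/(1+e^p*)) e^(-exp(lambda*_i) + lambda*_i y_i) / y_i!]`,
#' all evaluated in log space.
#'
#' @param y non-negative integer vector.
#' @param lambda_star log Poisson means, one per observation.
#' @param p_star logit of the structural-zero probability.
#' @return log-likelihood value.
#' @export
zip_log_likelihood <- function(y, lambda_star, p_star) {
  if (any(y < 0) || any(y != floor(y)))
    stop("y must contain non-negative integers")
  if (length(lambda_star) != length(y)) stop("non-conforming lengths")
  zip_loglik_cpp(as.numeric(y), as.numeric(lambda_star), p_star)
}

#' Link transformations of the ZIP parameters
#'
#' `lambda = exp(lambda*)` and `p = exp(p*) / (1 + exp(p*))`.
#'
#' @param lambda_star log Poisson mean(s).
#' @param p_star logit zero-inflation parameter(s).
#' @return for `link_lambda`, the Poisson mean(s); for `link_p`, the
#'   structural-zero probability(ies).
#' @export
link_lambda <- function(lambda_star) exp(lambda_star)

#' @rdname link_lambda
#' @export
link_p <- function(p_star) plogis(p_star)

#' Metropolis update of one latent log Poisson mean
#'
#' Gaussian random-walk update of `lambda*_i` targeting the product of
#' its single-observation ZIP data term and its conditional normal given
#' `lambda*_{-i}` under MVN(mu, V), parameterized through the precision
#' matrix `Omega = V^-1`.
#'
#' @param i observation index.
#' @param lambda_star current latent vector.
#' @param y observed counts.
#' @param mu second-stage mean vector (`X beta`).
#' @param Omega precision matrix `V^-1`.
#' @param p_star current logit zero-inflation.
#' @param step proposal sd.
#' @return list with updated `lambda_star` and `accepted`.
#' @export
mh_update_lambda_star <- function(i, lambda_star, y, mu, Omega, p_star, step) {
  rv_i <- drop(Omega[i, ] %*% (lambda_star - mu))
  v <- 1 / Omega[i, i]
  m <- lambda_star[i] - rv_i * v
  cur <- lambda_star[i]
  prop <- cur + step * rnorm(1)
  term <- function(ls) {
    lam <- if (ls < 690) exp(ls) else Inf
    if (y[i] == 0) {
      mx <- max(p_star, -lam)
      mx + log(exp(p_star - mx) + exp(-lam - mx))
    } else if (!is.finite(lam)) -Inf else -lam + ls * y[i]
  }
  d <- term(prop) - term(cur) - (prop - m)^2 / (2 * v) + (cur - m)^2 / (2 * v)
  acc <- log(runif(1)) < d
  if (acc) lambda_star[i] <- prop
  list(lambda_star = lambda_star, accepted = acc)
}

#' Metropolis update of the zero-inflation parameter
#'
#' Reflected random-walk update of `p*` within its uniform prior bounds
#' \[-5, 5\], targeting the ZIP likelihood as a function of `p*`.
#'
#' @param p_star current value.
#' @param y observed counts.
#' @param lambda_star current latent vector.
#' @param step proposal sd.
#' @return list with updated `p_star` and `accepted`.
#' @export
mh_update_pstar <- function(p_star, y, lambda_star, step) {
  prop <- reflect_interval(p_star + step * rnorm(1), -5, 5)
  d <- zip_log_likelihood(y, lambda_star, prop) -
    zip_log_likelihood(y, lambda_star, p_star)
  acc <- log(runif(1)) < d
  list(p_star = if (acc) prop else p_star, accepted = acc)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal
# Jacobi matrix); returns log weights for stable mixing into logsumexp.
gauss_hermite <- function(q) {
  k <- seq_len(q - 1)
  J <- matrix(0, q, q)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  eg <- eigen(J, symmetric = TRUE)
  x <- eg$values
  w <- sqrt(pi) * eg$vectors[1, ]^2
  ord <- order(x)
  list(nodes = x[ord], log_weights = log(w[ord]))
}

#' Run the zero-inflated Poisson sampler
#'
#' Full hierarchy: ZIP data level on the counts, normal second stage
#' MVN(X beta, V) on the latent log means `lambda*`, uniform \[-5, 5\]
#' prior on `p*`.  Per iteration: elementwise Metropolis sweep over
#' `lambda*`, reflected Metropolis on `p*`, then the second-stage updates
#' of beta, sigma2_P and the three ratios exactly as in the linear model
#' but with `lambda*` playing the role of the data.  Structural-zero
#' indicators are never augmented; the marginalized likelihood is used
#' throughout.  The deviance trace stores `-2 log p(y | lambda*, p*)`; a
#' second trace stores the population-focus deviance with `lambda*`
#' integrated out observation-wise by Gauss-Hermite quadrature (see the
#' model-comparison helpers).
#'
#' @inheritParams run_lmm_mcmc
#' @param y non-negative integer counts.
#' @param step_lambda proposal sd for the `lambda*` sweep (default 0.3).
#' @param step_pstar proposal sd for `p*` (default 0.5).
#' @param gh_points Gauss-Hermite nodes for the marginal deviance trace.
#' @return a `vr_chain` object (model `"zip"`), additionally carrying the
#'   `p*` trace, the posterior mean of `lambda*` and both deviance traces.
#' @export
run_zip_mcmc <- function(y, X, kernels, n_iter = 10000, burnin = 1000,
                         steps = c(0.05, 0.05, 0.05), step_lambda = 0.3,
                         step_pstar = 0.5, grid_size = 129,
                         density_grid = TRUE, update = c(TRUE, TRUE, TRUE),
                         adapt = TRUE, init = NULL, seed = NULL,
                         gh_points = 31) {
  if (any(y < 0) || any(y != floor(y)))
    stop("ZIP model requires non-negative integer trait values")
  y <- as.numeric(y)
  X <- as.matrix(X)
  check_chain_inputs(y, X, kernels, n_iter, burnin)
  if (grid_size %% 2 == 0) grid_size <- grid_size + 1
  init <- init %||% list()
  ls0 <- init$lambda_star %||% ifelse(y > 0, log(y + 0.5), log(0.5))
  p0 <- init$p_star %||% min(5, max(-5, qlogis(max(0.8 * mean(y == 0), 0.01))))
  r0 <- init$ratios %||% {
    r <- c(0.1, 0.1, 0.1); r[!update] <- 0; r
  }
  b0 <- init$beta %||% if (ncol(X)) qr.coef(qr(X), ls0) else numeric(0)
  s0 <- init$sigma2 %||% max(var(ls0), 1e-8)
  gh <- gauss_hermite(gh_points)
  raw <- with_seed(seed, chain_zip_cpp(
    y, X, kernels$K_A, kernels$K_L, kernels$K_C,
    as.integer(n_iter), as.integer(burnin), as.numeric(steps),
    step_lambda, step_pstar, as.integer(grid_size), density_grid,
    as.logical(update), adapt, check_simplex(r0), s0, as.numeric(b0),
    as.numeric(ls0), p0, gh$nodes, gh$log_weights))
  settings <- list(n_iter = n_iter, burnin = burnin, steps = steps,
                   step_lambda = step_lambda, step_pstar = step_pstar,
                   grid_size = grid_size, density_grid = density_grid,
                   update = update, adapt = adapt, gh_points = gh_points)
  new_chain(raw, "zip", n_iter, burnin, settings, seed)
}
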