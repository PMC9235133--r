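test_that("MVN log-likelihood matches closed forms", {
  expect_equal(lmm_log_likelihood(0.7, 0.7, matrix(1), matrix(1)),
               -0.5 * log(2 * pi))
  X <- matrix(0, 2, 0)
  expect_equal(lmm_log_likelihood(c(1, 0), numeric(0), diag(2), X),
               -log(2 * pi) - 0.5)
  # location invariance
  X1 <- matrix(1, 3, 1)
  y <- c(0.3, -1, 2)
  V <- diag(3) + 0.3
  expect_equal(lmm_log_likelihood(y + 5, 5, V, X1),
               lmm_log_likelihood(y, 0, V, X1))
  expect_error(lmm_log_likelihood(c(1, 1), numeric(0),
                                  matrix(c(1, 2, 2, 1), 2), X), "positive definite")
})

test_that("beta Gibbs draw targets the GLS posterior", {
  withr::local_seed(14)
  n <- 30
  X <- cbind(1, rnorm(n))
  V <- 0.7 * outer(rep(1, n), rep(1, n)) * 0 + diag(n)
  V[1:15, 1:15] <- V[1:15, 1:15] + 0.4; diag(V) <- diag(V) + 0.1
  y <- drop(X %*% c(2, -1)) + drop(t(chol(V)) %*% rnorm(n))
  # identity case: posterior mean equals y
  expect_equal(mean(replicate(200, gibbs_update_beta(y[1], matrix(1), diag(1)))),
               y[1], tolerance = 0.2)
  Vi <- solve(V)
  gls <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  draws <- replicate(3000, gibbs_update_beta(y, X, V))
  Sig <- solve(crossprod(X, Vi %*% X))
  for (j in 1:2)
    expect_lt(abs(mean(draws[j, ]) - gls[j]),
              3 * sqrt(Sig[j, j] / 3000) + 1e-9)
  # V = s2 I scales the posterior covariance by s2
  d1 <- withr::with_seed(1, replicate(2000, gibbs_update_beta(y, X, diag(n))))
  d4 <- withr::with_seed(2, replicate(2000, gibbs_update_beta(y, X, 4 * diag(n))))
  expect_equal(var(d4[2, ]) / var(d1[2, ]), 4, tolerance = 0.5)
})

test_that("sigma2 Gibbs draw is the documented inverse gamma", {
  withr::local_seed(3)
  n <- 40
  kern <- structure(list(K_A = diag(n), K_L = diag(n), K_C = diag(n)),
                    class = "vr_kernels")
  X <- matrix(1, n, 1)
  y <- rnorm(n, 5, 2)
  S <- sum((y - mean(y))^2)
  draws <- replicate(1e4, gibbs_update_sigma2(y, X, mean(y), c(0, 0, 0), kern))
  expect_equal(mean(draws), S / (n - 4), tolerance = 0.05 * S / (n - 4))
  # doubling the residuals quadruples the scale
  d2 <- replicate(2000, gibbs_update_sigma2(2 * y, X, 2 * mean(y),
                                            c(0, 0, 0), kern))
  expect_equal(mean(d2) / mean(draws), 4, tolerance = 0.4)
})

test_that("ratio Metropolis update reflects and accepts flat targets", {
  # reflection keeps any proposal inside [0, bound]
  expect_true(all(vrbayes:::reflect_interval(seq(-3, 3, by = 0.01), 0, 0.4) >= 0))
  expect_true(all(vrbayes:::reflect_interval(seq(-3, 3, by = 0.01), 0, 0.4) <= 0.4))
  expect_equal(vrbayes:::reflect_interval(-0.1, 0, 1), 0.1)
  expect_equal(vrbayes:::reflect_interval(1.15, 0, 1), 0.85)
  # zero-variance kernel: V does not depend on h2, acceptance rate 1
  n <- 8
  kernI <- structure(list(K_A = diag(n), K_L = diag(n), K_C = diag(n)),
                    class = "vr_kernels")
  y <- withr::with_seed(2, rnorm(n))
  acc <- withr::with_seed(7, replicate(200, mh_update_ratio(
    "h2", c(0.3, 0, 0), 1, y, kernI, 0.05)$accepted))
  expect_true(all(acc))
  expect_error(mh_update_ratio("h2", c(0.1, 0, 0), 1, y, kernI, 0), "step")
})

test_that("toy chain marginal matches deterministic grid quadrature", {
  kern <- toy_sib_kernels(3)            # n = 6
  y <- toy_sib_data(kern, h2 = 0.6, s2 = 2, seed = 21)
  ch <- run_lmm_mcmc(y, matrix(0, 6, 0), kern, n_iter = 4e4, burnin = 2000,
                     update = c(TRUE, FALSE, FALSE), seed = 13)
  m <- toy_marginal_lik(y, kern$K_A)
  Z <- integrate(m, 0, 1, rel.tol = 1e-10)$value
  br <- seq(0, 1, by = 0.05)
  pq <- diff(vapply(br, function(b)
    if (b == 0) 0 else integrate(m, 0, b, rel.tol = 1e-9)$value,
    numeric(1))) / Z
  pc <- as.numeric(table(cut(ch$ratios[, "h2"], br, include.lowest = TRUE))) /
    nrow(ch$ratios)
  expect_lt(0.5 * sum(abs(pq - pc)), 0.05)
})

test_that("chains are deterministic given a seed and respect the simplex", {
  sim <- test_study(16, c(0.3, 0.2, 0.1), seed = 2)
  y <- sim$traits$trait1
  a <- run_lmm_mcmc(y, sim$design$X, sim$kernels, n_iter = 220, burnin = 60,
                    seed = 9)
  b <- run_lmm_mcmc(y, sim$design$X, sim$kernels, n_iter = 220, burnin = 60,
                    seed = 9)
  expect_identical(a$ratios, b$ratios)
  expect_identical(a$log_dens0, b$log_dens0)
  expect_true(all(a$ratios >= 0))
  expect_true(all(rowSums(a$ratios) <= 1))
  expect_true(all(a$sigma2 > 0))
  expect_equal(a$n_kept, 160)
  # deviance trace consistent with the likelihood at stored draws
  k <- 37
  V <- build_V(a$ratios[k, ], a$sigma2[k], sim$kernels)
  expect_equal(a$deviance[k],
               -2 * lmm_log_likelihood(y, a$beta[k, ], V, sim$design$X),
               tolerance = 1e-6)
})

test_that("null synthetic data keep ratio posteriors near zero", {
  for (s in 1:2) {
    sim <- test_study(40, c(0, 0, 0), seed = 60 + s)
    ch <- run_lmm_mcmc(sim$traits$trait1, sim$design$X, sim$kernels,
                       n_iter = 500, burnin = 200, density_grid = FALSE,
                       seed = s)
    expect_true(all(colMeans(ch$ratios) < 0.2))
  }
})
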