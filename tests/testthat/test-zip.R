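test_that("ZIP log-likelihood matches direct evaluation", {
  # y = 0, p* = 0, lambda* = 0: log(0.5 (1 + e^-1)) = log 0.68394
  expect_equal(zip_log_likelihood(0, 0, 0), log(0.5 * (1 + exp(-1))))
  # p* = -5 is numerically the plain Poisson for all-positive data
  y <- c(3, 7, 1, 12)
  ls <- log(y)
  pois <- sum(stats::dpois(y, y, log = TRUE))
  zl <- zip_log_likelihood(y, ls, -5)
  expect_lt(abs(zl - pois), 0.007 * length(y))
  # normalization over counts
  for (ps in c(-2, 0, 1.5)) {
    pk <- vapply(0:400, function(k) exp(zip_log_likelihood(k, 1.3, ps)),
                 numeric(1))
    expect_equal(sum(pk), 1, tolerance = 1e-10)
  }
  # zero-probability identity: both likelihood forms agree
  for (ps in c(-3, 0, 2)) {
    p <- link_p(ps); lam <- link_lambda(0.8)
    expect_equal(exp(zip_log_likelihood(0, 0.8, ps)),
                 p + (1 - p) * exp(-lam), tolerance = 1e-12)
  }
  expect_error(zip_log_likelihood(c(-1, 2), c(0, 0), 0), "non-negative")
  expect_error(zip_log_likelihood(c(1.5, 2), c(0, 0), 0), "non-negative")
})

test_that("link transforms invert the star parameterization", {
  expect_equal(link_p(0), 0.5)
  expect_equal(link_lambda(0), 1)
  expect_equal(link_p(5), exp(5) / (1 + exp(5)))  # ~ 0.99331
  expect_equal(round(link_p(5), 5), 0.99331)
})

test_that("lambda* update drifts to log(y) and matches 1-D quadrature", {
  # large count, diffuse prior: accepted moves climb toward log(y)
  y <- 150
  Om <- matrix(1 / 25, 1, 1)  # prior sd 5
  ls <- 0
  withr::local_seed(8)
  path <- numeric(400)
  for (k in 1:400) {
    st <- mh_update_lambda_star(1, ls, y, 0, Om, -5, 0.4)
    ls <- st$lambda_star
    path[k] <- ls
  }
  expect_lt(abs(ls - log(y)), 0.5)
  expect_gt(mean(path[300:400]), mean(path[1:50]))

  # stationary marginal vs grid quadrature of the Poisson-lognormal posterior
  y <- 4; m0 <- 1; v0 <- 0.6
  Om <- matrix(1 / v0, 1, 1)
  grid <- seq(-3, 5, length.out = 2001)
  lp <- stats::dpois(y, exp(grid), log = TRUE) +
    stats::dnorm(grid, m0, sqrt(v0), log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  draws <- numeric(3e4); ls <- log(y)
  for (k in seq_along(draws)) {
    ls <- mh_update_lambda_star(1, ls, y, m0, Om, -5, 0.8)$lambda_star
    draws[k] <- ls
  }
  br <- seq(-3, 5, by = 0.25)
  pq <- diff(vapply(br, function(b) sum(w[grid <= b]), numeric(1)))
  pc <- as.numeric(table(cut(draws[-(1:1000)], br))) / (length(draws) - 1000)
  expect_lt(0.5 * sum(abs(pq / sum(pq) - pc)), 0.05)
})

test_that("p* update respects its bounds and finds the zero fraction", {
  # all-positive data push p* to the lower bound
  y <- c(5, 9, 2, 14, 7)
  ls <- log(y)
  ps <- 0
  withr::local_seed(5)
  for (k in 1:800) ps <- mh_update_pstar(ps, y, ls, 0.6)$p_star
  expect_lt(ps, -2.5)
  # half structural zeros with large lambda: p concentrates near 0.5
  n <- 400
  y2 <- rep(50L, n); y2[1:(n / 2)] <- 0L
  ls2 <- rep(log(50), n)
  ps <- 0
  draws <- replicate(2000, {
    ps <<- mh_update_pstar(ps, y2, ls2, 0.4)$p_star
    ps
  })
  expect_lt(abs(mean(link_p(draws[-(1:200)])) - 0.5), 0.05)
  # reflection never leaves [-5, 5]
  ps <- 4.9
  for (k in 1:200) {
    ps <- mh_update_pstar(ps, y2, ls2, 3)$p_star
    expect_true(ps >= -5 && ps <= 5)
  }
})

test_that("ZIP chain is deterministic, bounded, and recovers p roughly", {
  sim <- test_study(24, c(0.3, 0.1, 0.1), model = "zip", p_structural = 0.35,
                    trait_mean = 3, seed = 77)
  y <- sim$traits$trait1
  a <- run_zip_mcmc(y, sim$design$X, sim$kernels, n_iter = 400, burnin = 150,
                    seed = 4)
  b <- run_zip_mcmc(y, sim$design$X, sim$kernels, n_iter = 400, burnin = 150,
                    seed = 4)
  expect_identical(a$ratios, b$ratios)
  expect_identical(a$pstar, b$pstar)
  expect_true(all(a$pstar >= -5 & a$pstar <= 5))
  expect_true(all(is.finite(a$lamstar_mean)))
  expect_true(all(rowSums(a$ratios) <= 1))
  expect_lt(abs(mean(link_p(a$pstar)) - 0.35), 0.12)
  # p = 0 generating process: posterior zero inflation stays small
  sim0 <- test_study(24, c(0.3, 0.1, 0.1), model = "zip", p_structural = 0,
                     trait_mean = 3, seed = 78)
  ch0 <- run_zip_mcmc(sim0$traits$trait1, sim0$design$X, sim0$kernels,
                      n_iter = 400, burnin = 150, density_grid = FALSE,
                      seed = 5)
  expect_lt(mean(link_p(ch0$pstar)), 0.1)
})
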