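test_that("pedigree generator produces the configured structure", {
  ped0 <- simulate_pedigree(10, 0, 4, seed = 1)
  expect_equal(nrow(ped0), 10)
  expect_equal(relationship_matrix(ped0), diag(10), ignore_attr = TRUE)

  ped <- simulate_pedigree(10, 2, 4, seed = 2)
  gen <- attr(ped, "generation")
  # every mating contributes exactly litter_size offspring
  expect_equal(sum(gen == 1) %% 4, 0)
  expect_equal(sum(gen == 2) %% 4, 0)
  expect_true(vrbayes:::is_sorted_pedigree(ped))
  expect_error(simulate_pedigree(7, 1), "even")

  # small closed populations become inbred after a few generations
  ped3 <- simulate_pedigree(4, 4, 4, seed = 5)
  expect_gt(max(diag(relationship_matrix(ped3))), 1)
})

test_that("gene dropping obeys founder and full-sib covariances", {
  founders <- simulate_pedigree(100, 0, 2, seed = 3)
  u <- simulate_breeding_values(founders, sigma2_a = 2, n_rep = 150,
                                seed = 4)
  expect_equal(var(as.numeric(u)), 2, tolerance = 0.06)
  # two founders, two full-sib offspring: Cov(sibs) = 0.5 sigma2_a
  ped <- read_pedigree(data.frame(animal = c("s", "d", "o1", "o2"),
                                  sire = c("0", "0", "s", "s"),
                                  dam = c("0", "0", "d", "d")))
  u <- simulate_breeding_values(sort_pedigree(ped), 1, n_rep = 1e4, seed = 6)
  expect_equal(cov(u["o1", ], u["o2", ]), 0.5, tolerance = 0.05)
  expect_equal(var(u["o1", ]), 1, tolerance = 0.05)
  expect_error(simulate_breeding_values(hand_pedigree()[c(4, 1:3, 5:6), ]),
               "sorted")
})

test_that("cage assignment respects the littermate constraint", {
  for (s in 1:20) {
    ped <- simulate_pedigree(20, 2, 6, seed = s)
    md <- assign_litters_cages(ped, cage_size = 4, max_littermates = 2,
                               seed = s)
    counts <- table(md$litter, md$cage)
    expect_lte(max(counts), 2)
    expect_lte(max(table(md$cage)), 4)
  }
  # litters of 8 in cages of 8 with the 2-littermate cap span >= 4 cages
  ped <- simulate_pedigree(8, 1, 8, seed = 3)
  md <- assign_litters_cages(ped, cage_size = 8, max_littermates = 2, seed = 1)
  spread <- tapply(md$cage, md$litter, function(x) length(unique(x)))
  expect_true(all(spread >= 4))
  # a single litter of two fits one cage
  ped1 <- simulate_pedigree(2, 1, 2, seed = 1)
  md1 <- assign_litters_cages(ped1, cage_size = 2, max_littermates = 2, seed = 1)
  expect_equal(length(unique(md1$cage)), 1)
})

test_that("linear-model traits carry the configured variance structure", {
  sim <- test_study(60, c(0, 0, 0), seed = 30)
  y <- sim$traits$trait1
  # no shared components: between-litter variance is a small fraction
  fit <- stats::aov(y ~ litter, data = data.frame(y = y,
                                                  litter = sim$metadata$litter))
  ms <- summary(fit)[[1]]$`Mean Sq`
  k <- mean(table(sim$metadata$litter))
  var_litter <- (ms[1] - ms[2]) / k
  expect_lt(abs(var_litter) / var(y), 0.12)

  # doubling sigma2_P doubles the raw-scale variance (otu kind keeps scale)
  sim1 <- test_study(60, c(0.2, 0.2, 0.2), trait_kind = "otu", sigma2_P = 1,
                     trait_mean = 10, seed = 31)
  sim2 <- test_study(60, c(0.2, 0.2, 0.2), trait_kind = "otu", sigma2_P = 2,
                     trait_mean = 10, seed = 31)
  expect_equal(var(sim2$traits$trait1) / var(sim1$traits$trait1), 2,
               tolerance = 0.25)
})

test_that("pair-class moments recover the generating ratios", {
  # Moment oracle from covariance classes across replicate traits, with
  # breeding values redrawn per replicate so that across-replicate
  # covariances have expectation sigma2 (h2 a_ij + l2 KL_ij + c2 KC_ij):
  # pairs with a = 0.25, different litter & cage  -> 0.25 h2
  # full sibs, different cage                     -> 0.5 h2 + l2
  # unrelated (a = 0), same cage                  -> c2
  sim <- test_study(80, c(0.3, 0.2, 0.1), seed = 33)
  A <- sim$kernels$K_A
  KL <- sim$kernels$K_L
  KC <- sim$kernels$K_C
  n_rep <- 250
  U <- simulate_breeding_values(sim$pedigree, 0.3, n_rep = n_rep, seed = 34)
  U <- U[sim$design$animal_ids, ]
  X0 <- matrix(0, nrow(A), 0)
  Y <- vapply(seq_len(n_rep), function(t)
    as.numeric(simulate_lmm_trait(X0, sim$design$Z_L, sim$design$Z_C,
                                  U[, t], c(0.3, 0.2, 0.1), 1,
                                  kind = "genus", seed = 1000 + t)),
    numeric(nrow(A)))
  Y <- Y - rowMeans(Y)
  Chat <- tcrossprod(Y) / (ncol(Y) - 1)
  # The standardization inside the integer transform centers each trait
  # across animals, so the expected covariance is the centered projection
  # P C P, P = I - 11'/n, of
  # C = kappa (h2 A + l2 KL + c2 KC + (1 - sum) I).
  # Least squares on the four projected kernels recovers coefficients
  # proportional to (h2, l2, c2, 1 - sum).
  n <- nrow(A)
  P <- diag(n) - 1 / n
  proj <- function(M) (P %*% M %*% P)[upper.tri(M)]
  est <- qr.coef(qr(cbind(a = proj(A), kl = proj(KL), kc = proj(KC),
                          res = proj(diag(n)))),
                 Chat[upper.tri(A)])
  est <- est / sum(est)
  expect_lt(abs(est[["a"]] - 0.3), 0.08)
  expect_lt(abs(est[["kl"]] - 0.2), 0.08)
  expect_lt(abs(est[["kc"]] - 0.1), 0.08)
  expect_lt(abs(est[["res"]] - 0.4), 0.08)
})

test_that("ZIP traits honor the structural-zero probability", {
  sim <- test_study(60, c(0.2, 0.1, 0.1), model = "zip", p_structural = 0,
                    trait_mean = 4, seed = 40, n_traits = 10)
  y <- as.matrix(sim$traits[, -1])
  expect_true(all(y >= 0))
  expect_true(all(y == floor(y)))
  expect_lt(mean(y == 0), 0.02)
  sim3 <- test_study(60, c(0.2, 0.1, 0.1), model = "zip", p_structural = 0.3,
                     trait_mean = 4, seed = 41, n_traits = 40)
  expect_equal(mean(as.matrix(sim3$traits[, -1]) == 0), 0.3,
               tolerance = 0.02 / 0.3)
})

test_that("the generator is deterministic given its configuration", {
  a <- test_study(16, c(0.3, 0.2, 0.1), model = "zip", p_structural = 0.2,
                  seed = 55)
  b <- test_study(16, c(0.3, 0.2, 0.1), model = "zip", p_structural = 0.2,
                  seed = 55)
  expect_identical(a$traits, b$traits)
  expect_identical(as.data.frame(a$pedigree), as.data.frame(b$pedigree))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$u, b$truth$u)
})
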