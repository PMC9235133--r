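# Small fixtures shared across test files; everything is built in code.

# Four unrelated full-sib pairs: block-diagonal additive kernel, n = 8.
toy_sib_kernels <- function(n_pairs = 4) {
  KA <- kronecker(diag(n_pairs), matrix(c(1, 0.5, 0.5, 1), 2))
  n <- 2 * n_pairs
  structure(list(K_A = KA, K_L = diag(n), K_C = diag(n)),
            class = "vr_kernels")
}

# Draw one MVN sample with covariance s2 * (h2 KA + (1 - h2) I).
toy_sib_data <- function(kernels, h2, s2 = 4, seed = 42) {
  n <- nrow(kernels$K_A)
  K <- h2 * kernels$K_A + (1 - h2) * diag(n)
  withr::with_seed(seed, drop(t(chol(s2 * K)) %*% rnorm(n)))
}

# Quadrature oracle for the one-ratio toy model (l2 = c2 = 0, no fixed
# effects, flat positive prior on sigma2_P integrated in closed form):
# m(h2) proportional to |K(h2)|^(-1/2) * (S(h2)/2)^(-(n/2-1)).
toy_marginal_lik <- function(y, KA) {
  n <- length(y)
  function(h) vapply(h, function(hh) {
    K <- hh * KA + (1 - hh) * diag(n)
    L <- t(chol(K))
    w <- forwardsolve(L, y)
    exp(-sum(log(diag(L))) - (n / 2 - 1) * log(sum(w^2) / 2))
  }, numeric(1))
}

# A small three-generation pedigree written as a data.frame:
# founders S, D; full sibs O1, O2; X = O1 x unrelated founder M.
hand_pedigree <- function() {
  data.frame(animal = c("S", "D", "M", "O1", "O2", "X"),
             sire = c("0", "0", "0", "S", "S", "O1"),
             dam = c("0", "0", "0", "D", "D", "M"),
             stringsAsFactors = FALSE)
}

# Study-scale metadata: 6 group levels, 5 batches, 2 weight classes.
study_scale_metadata <- function(n = 60, seed = 1) {
  withr::with_seed(seed, data.frame(
    animal = sprintf("a%02d", seq_len(n)),
    litter = factor(sample(sprintf("L%02d", 1:15), n, replace = TRUE)),
    cage = factor(sample(sprintf("C%02d", 1:20), n, replace = TRUE)),
    batch = factor(sample(paste0("B", 1:5), n, replace = TRUE)),
    group = factor(sample(paste0("G", 1:6), n, replace = TRUE)),
    weight_class = factor(sample(c("W1", "W2"), n, replace = TRUE)),
    stringsAsFactors = FALSE))
}

# Simulated study at a given scale; thin wrapper fixing the geometry used
# throughout the tests (two offspring generations, litters of four).
test_study <- function(n_founders, true_ratios, model = "lmm",
                       sigma2_P = 1, p_structural = 0, trait_kind = "genus",
                       trait_mean = NULL, seed = 1, n_traits = 1) {
  simulate_study(n_founders = n_founders, n_generations = 2,
                 litter_size = 4, cage_size = 4,
                 true_ratios = true_ratios, sigma2_P = sigma2_P,
                 p_structural = p_structural, model = model,
                 trait_kind = trait_kind, trait_mean = trait_mean,
                 n_traits = n_traits, seed = seed)
}
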