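#' Sample variance ratios from their joint prior
#'
#' Draws (h2, l2, c2) uniformly on the interior of the region
#' \{r >= 0, h2 + l2 + c2 <= 1\}, which has constant density 6.  The draw
#' uses the Dirichlet(1,1,1,1) construction (four exponentials normalized
#' to sum 1, dropping the implicit fourth coordinate), which is exact.
#'
#' @param n_draws number of draws.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return data.frame with columns `h2`, `l2`, `c2`.
#' @export
sample_ratio_prior <- function(n_draws, seed = NULL) {
  stopifnot(n_draws >= 1)
  with_seed(seed, {
    g <- matrix(rexp(4 * n_draws), n_draws, 4)
    r <- g[, 1:3, drop = FALSE] / rowSums(g)
    data.frame(h2 = r[, 1], l2 = r[, 2], c2 = r[, 3])
  })
}

#' Marginal prior density of a single variance ratio
#'
#' Under the joint uniform prior on the simplex, each ratio marginally
#' follows Beta(1, 3), with density `3 (1 - r)^2`; in particular the
#' density at 0 equals 3, the prior value entering the Savage-Dickey
#' Bayes factor.
#'
#' @param r value(s) in \[0, 1\].
#' @return density value(s).
#' @export
marginal_prior_density <- function(r) {
  if (any(r < 0 | r > 1)) stop("ratio outside [0, 1]")
  3 * (1 - r)^2
}

#' Covariance kernels for a set of observations
#'
#' Builds the three n x n kernels entering the phenotypic covariance:
#' the additive kernel `Z_A A Z_A'` (submatrix of the relationship matrix
#' for the observed animals), and the litter and cage block kernels
#' `Z_L Z_L'`, `Z_C Z_C'`.
#'
#' @param A relationship matrix ([relationship_matrix()]).
#' @param design a `vr_design` from [build_design()], or a list with
#'   `Z_L`, `Z_C`, `animal_ids`.
#' @return a `vr_kernels` list with `K_A`, `K_L`, `K_C`.
#' @export
make_kernels <- function(A, design) {
  K_A <- observation_kernel(A, design$animal_ids)
  K_L <- tcrossprod(design$Z_L)
  K_C <- tcrossprod(design$Z_C)
  dimnames(K_L) <- dimnames(K_C) <- NULL
  dimnames(K_A) <- NULL
  structure(list(K_A = K_A, K_L = K_L, K_C = K_C), class = "vr_kernels")
}

check_simplex <- function(ratios) {
  r <- as.numeric(ratios)
  if (length(r) != 3L || any(!is.finite(r)))
    stop("ratios must be three finite numbers (h2, l2, c2)")
  if (any(r < 0) || sum(r) > 1 + 1e-12)
    stop("variance ratios violate the simplex constraint (each >= 0, sum <= 1)")
  r
}

#' Phenotypic covariance matrix
#'
#' Assembles `V = sigma2_P [ K_A h2 + K_L l2 + K_C c2 + I (1 - h2 - l2 - c2) ]`.
#'
#' @param ratios numeric vector `(h2, l2, c2)` on the simplex.
#' @param sigma2_P phenotypic variance (> 0).
#' @param kernels a `vr_kernels` list.
#' @return symmetric positive semidefinite matrix.
#' @export
build_V <- function(ratios, sigma2_P, kernels) {
  r <- check_simplex(ratios)
  if (!is.finite(sigma2_P) || sigma2_P <= 0) stop("sigma2_P must be > 0")
  n <- nrow(kernels$K_A)
  if (!all(dim(kernels$K_L) == n) || !all(dim(kernels$K_C) == n))
    stop("non-conforming kernel dimensions")
  V <- r[1] * kernels$K_A + r[2] * kernels$K_L + r[3] * kernels$K_C
  diag(V) <- diag(V) + (1 - sum(r))
  sigma2_P * V
}
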