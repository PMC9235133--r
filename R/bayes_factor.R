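#' Normalized conditional density at zero
#'
#' Evaluates an unnormalized log-density on a Simpson grid over
#' `[0, upper]`, stabilizes by its maximum, integrates, and returns the
#' normalized density at zero.  The conditional support of a variance
#' ratio is `[0, 1 - sum(other ratios)]`; the density is zero beyond the
#' support, so normalizing over the support equals normalizing over
#' `[0, 1]`.
#'
#' @param log_f vectorized function returning the unnormalized log
#'   density on `[0, upper]` (`-Inf` allowed).
#' @param upper upper end of the support, in (0, 1].
#' @param grid_size number of Simpson points (>= 16; forced odd).
#' @return the normalized density at 0 (natural scale).
#' @export
conditional_density_at_zero <- function(log_f, upper, grid_size = 129) {
  if (!is.finite(upper) || upper <= 0 || upper > 1)
    stop("upper must be in (0, 1]")
  if (grid_size < 16) stop("grid_size must be >= 16")
  if (grid_size %% 2 == 0) grid_size <- grid_size + 1
  t <- seq(0, upper, length.out = grid_size)
  g <- vapply(t, log_f, numeric(1))
  m <- max(g)
  if (!is.finite(m)) stop("log_f is non-finite everywhere on the grid")
  h <- upper / (grid_size - 1)
  w <- rep(c(2, 4), length.out = grid_size)
  w[c(1, grid_size)] <- 1
  I <- sum(w * exp(g - m)) * h / 3
  exp(g[1] - m) / I
}

#' Log-sum-exp average of per-iteration densities at zero
#'
#' Computes `mean(exp(log_values))` as
#' `exp(log(sum(exp(log v - m)) / N) + m)` with `m = max(log v)`, the
#' max-stabilized form that neither overflows nor underflows for log
#' densities of any magnitude.
#'
#' @param log_values per-iteration log densities (`-Inf` allowed).
#' @return the mean density (natural scale).
#' @export
average_density_at_zero <- function(log_values) {
  if (!length(log_values)) stop("empty input")
  m <- max(log_values)
  if (!is.finite(m)) return(if (m == -Inf) 0 else NaN)
  exp(log(sum(exp(log_values - m)) / length(log_values)) + m)
}

#' Savage-Dickey Bayes factor from a mean posterior density at zero
#'
#' `BF = p(r = 0) / p(r = 0 | y)`: the marginal prior density of each
#' ratio at zero is 3 (Beta(1,3)), so `BF = 3 / mean density`.  A zero
#' mean density yields `Inf` (data maximally against the null).
#'
#' @param mean_density_at_zero posterior marginal density at zero (>= 0).
#' @param prior_density prior marginal density at zero (default 3; use 1
#'   for a single free ratio whose conditional prior is uniform).
#' @return list with `bf`, `reciprocal`, `evidence`, `null_supported`.
#' @export
compute_bf <- function(mean_density_at_zero, prior_density = 3) {
  if (is.na(mean_density_at_zero) || mean_density_at_zero < 0)
    stop("mean density must be a non-negative number")
  bf <- if (mean_density_at_zero == 0) Inf else
    prior_density / mean_density_at_zero
  list(bf = bf, reciprocal = 1 / bf, evidence = classify_evidence(bf),
       null_supported = (1 / bf) > 3.2)
}

#' Evidence category of a Bayes factor
#'
#' `BF < 3.2`: the denominator (null) model is supported (`"none"`);
#' `3.2 <= BF < 10`: `"substantial"`; `10 <= BF < 100`: `"strong"`;
#' `BF >= 100`: `"decisive"`.  The reciprocal `1/BF > 3.2` flags support
#' for the null itself.
#'
#' @param bf positive Bayes factor.
#' @return character category.
#' @export
classify_evidence <- function(bf) {
  if (is.na(bf) || bf <= 0) stop("Bayes factor must be > 0")
  if (bf < 3.2) "none"
  else if (bf < 10) "substantial"
  else if (bf < 100) "strong"
  else "decisive"
}

#' Bayes-factor table from a fitted chain
#'
#' Applies the max-stabilized average and the Savage-Dickey ratio to the
#' per-iteration conditional-density-at-zero traces of a `vr_chain`.
#'
#' @param chain a `vr_chain` with density traces
#'   (`density_grid = TRUE` when run).
#' @param prior_density prior marginal density at zero per ratio.
#' @return data.frame with one row per sampled ratio: `ratio`, `bf`,
#'   `reciprocal`, `evidence`, `null_supported`, `mean_density0`.
#' @export
bf_table <- function(chain, prior_density = 3) {
  ld <- chain$log_dens0
  if (is.null(ld) || all(is.na(ld)))
    stop("chain carries no density-at-zero trace; rerun with density_grid = TRUE")
  rows <- lapply(colnames(ld), function(nm) {
    v <- ld[, nm]
    if (all(is.na(v))) return(NULL)
    v <- v[!is.na(v)]
    res <- compute_bf(average_density_at_zero(v), prior_density)
    data.frame(ratio = nm, bf = res$bf, reciprocal = res$reciprocal,
               evidence = res$evidence, null_supported = res$null_supported,
               mean_density0 = prior_density / res$bf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
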